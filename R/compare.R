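# Accounting between the attribution-selected gene sets and the
# differential-expression results, collapsed across classes and per
# class, with direction annotation.

#' Collapsed overlap between an attribution gene set and a DE gene set
#'
#' The overlap percentage is taken relative to the attribution set (the
#' convention used when reporting how many model-selected genes an
#' orthogonal method confirms).
#'
#' @param shap_genes character vector (collapsed attribution-selected
#'   set).
#' @param de_genes character vector (collapsed DE-significant set).
#' @return list: `common`, `shap_only`, `de_only` (counts),
#'   `overlap_pct` = 100 * common / |shap|.
#' @export
overlap_collapsed <- function(shap_genes, de_genes) {
  shap_genes <- unique(shap_genes); de_genes <- unique(de_genes)
  if (!length(shap_genes) || !length(de_genes))
    stopf("both gene sets must be non-empty")
  common <- length(intersect(shap_genes, de_genes))
  list(common = common,
       shap_only = length(shap_genes) - common,
       de_only = length(de_genes) - common,
       overlap_pct = 100 * common / length(shap_genes))
}

#' Slot-level accounting between two per-class gene tallies
#'
#' Slots count genes once per class (a gene found in several classes
#' occupies several slots), unlike the collapsed sets.
#'
#' @param n_shap_slots,n_de_slots,n_common slot counts.
#' @return `list(shap_only, de_only)`.
#' @export
slot_accounting <- function(n_shap_slots, n_de_slots, n_common) {
  if (n_common > min(n_shap_slots, n_de_slots))
    stopf("n_common (%d) exceeds a slot total", n_common)
  out <- list(shap_only = n_shap_slots - n_common,
              de_only = n_de_slots - n_common)
  if (out$shap_only < 0 || out$de_only < 0) stopf("negative slot count")
  out
}

#' Annotate attribution-selected genes with their DE direction
#'
#' Each class's top genes are labelled `up` / `down` / `ns` from that
#' class's DE row; genes absent from the DE universe get `unknown` with a
#' warning.
#'
#' @param per_class named list of per-class gene vectors (see
#'   [select_top_genes()]).
#' @param de a `de_table`.
#' @return data.frame: class, gene, direction.
#' @export
annotate_direction <- function(per_class, de) {
  missing_cls <- setdiff(names(per_class), unique(de$class))
  if (length(missing_cls))
    stopf("class(es) absent from the DE table: %s",
          paste(missing_cls, collapse = ", "))
  out <- do.call(rbind, lapply(names(per_class), function(cl) {
    d <- de[de$class == cl, ]
    dir <- d$direction[match(per_class[[cl]], d$gene)]
    data.frame(class = cl, gene = per_class[[cl]],
               direction = ifelse(is.na(dir), "unknown", dir),
               stringsAsFactors = FALSE)
  }))
  if (any(out$direction == "unknown"))
    warnf("%d gene(s) missing from the DE universe labelled 'unknown'",
          sum(out$direction == "unknown"))
  out
}

#' Full overlap report
#'
#' Collapsed-set accounting, per-class overlap fractions with direction
#' breakdown, and slot-level accounting between the attribution top lists
#' and the DE-significant lists.
#'
#' @param table a `ranked_gene_table`.
#' @param de a `de_table`.
#' @param depth rank depth of the attribution lists.
#' @return an `overlap_report` list.
#' @export
overlap_report <- function(table, de, depth) {
  sel <- select_top_genes(table, depth)
  de_sets <- lapply(split(de, de$class), function(d) d$gene[d$significant])
  cls <- intersect(names(sel$per_class), names(de_sets))
  collapsed <- overlap_collapsed(sel$union,
                                 unique(unlist(de_sets, use.names = FALSE)))
  per_class <- do.call(rbind, lapply(cls, function(cl) {
    shap <- sel$per_class[[cl]]
    ds <- de[de$class == cl, ]
    hit <- shap %in% de_sets[[cl]]
    dirs <- ds$direction[match(shap, ds$gene)]
    data.frame(class = cl, n_top = length(shap), n_overlap = sum(hit),
               overlap_frac = mean(hit),
               n_up = sum(dirs == "up", na.rm = TRUE),
               n_down = sum(dirs == "down", na.rm = TRUE),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  n_shap_slots <- sum(per_class$n_top)
  n_de_slots <- sum(lengths(de_sets[cls]))
  n_common <- sum(per_class$n_overlap)
  structure(list(collapsed = collapsed, per_class = per_class,
                 slots = c(list(shap = n_shap_slots, de = n_de_slots,
                                common = n_common),
                           slot_accounting(n_shap_slots, n_de_slots, n_common))),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap_report: %.1f%% of %d selected genes DE-confirmed (%d not); slots %d/%d, %d common\n",
              x$collapsed$overlap_pct,
              x$collapsed$common + x$collapsed$shap_only,
              x$collapsed$shap_only,
              x$slots$shap, x$slots$de, x$slots$common))
  invisible(x)
}
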