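# Synthetic multi-class RNA-seq cohorts with planted class-signature genes.
#
# The generator emulates the structure of a large multi-tissue expression
# cohort: tens of imbalanced classes, negative-binomial counts with
# log-normal library-size variation, class-exclusive and shared signature
# genes in a strong and a subtle fold-change tier, and "sibling" class
# pairs that share a fraction of their signatures and are therefore
# mutually confusable.

#' Simulation configuration
#'
#' Describes one synthetic cohort. Counts are drawn
#' `NB(mean = baseline * 2^lfc * libfactor, dispersion)` with variance
#' `mu + dispersion * mu^2`; per-gene baseline means are log-normal and
#' scale with gene length (counts are proportional to transcript length at
#' equal molar expression), so TPM and TMM are meaningfully exercised.
#'
#' @param n_classes number of classes.
#' @param samples_per_class integer vector of class sizes (length
#'   `n_classes`; imbalance allowed).
#' @param n_genes total number of genes.
#' @param n_exclusive_per_class signature genes planted per class
#'   (exclusive to it, except the fraction shared inside a sibling pair).
#' @param n_shared_signatures genes shared by a random pair of classes.
#' @param strong_lfc_range,subtle_lfc_range positive, ordered log2
#'   fold-change ranges for the two signature tiers.
#' @param strong_frac fraction of signature genes in the strong tier.
#' @param down_frac fraction of signatures that are down-regulated in the
#'   owning class (negative planted lfc).
#' @param dispersion NB dispersion, scalar or per-gene vector.
#' @param libsize_sigma log-normal sigma of per-sample library factors.
#' @param sibling_pairs list of `list(classes = c(a, b), frac = f)`:
#'   classes a and b jointly own `round(f * n_exclusive_per_class)` of
#'   their signature slots.
#' @param gene_length_range gene length range in base pairs.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-kilobase baseline expression level.
#' @param signature_baseline_floor minimum baseline mean count for
#'   signature genes (markers are expressed well above detection, and a
#'   down-regulation of a gene nobody expresses would be unobservable).
#' @param seed integer seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_classes = 8,
                       samples_per_class = c(60, 75, 90, 100, 110, 120, 135, 150),
                       n_genes = 1200,
                       n_exclusive_per_class = 20,
                       n_shared_signatures = 40,
                       strong_lfc_range = c(5, 8),
                       subtle_lfc_range = c(1, 3),
                       strong_frac = 0.5,
                       down_frac = 0.25,
                       dispersion = 0.15,
                       libsize_sigma = 0.35,
                       sibling_pairs = list(list(classes = c(1L, 2L), frac = 0.5)),
                       gene_length_range = c(300, 10000),
                       baseline_meanlog = log(8),
                       baseline_sdlog = 1.2,
                       signature_baseline_floor = 30,
                       seed = 42L) {
  if (!is_count(n_classes)) stopf("n_classes must be a positive count")
  if (length(samples_per_class) != n_classes)
    stopf("samples_per_class must have length n_classes (%d)", n_classes)
  if (!all(vapply(samples_per_class, is_count, TRUE)))
    stopf("samples_per_class must be positive counts")
  if (!is_count(n_genes)) stopf("n_genes must be a positive count")
  for (r in list(strong_lfc_range, subtle_lfc_range)) {
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2])
      stopf("lfc ranges must be positive and ordered")
  }
  if (any(dispersion <= 0)) stopf("dispersion must be positive")
  if (libsize_sigma < 0) stopf("libsize_sigma must be >= 0")
  need <- n_exclusive_per_class * n_classes + n_shared_signatures
  if (need > n_genes)
    stopf("configuration error: %d signature genes requested but only %d genes",
          need, n_genes)
  for (sp in sibling_pairs) {
    if (length(sp$classes) != 2 || any(sp$classes > n_classes) ||
        sp$classes[1] == sp$classes[2])
      stopf("sibling pair must name two distinct classes <= n_classes")
    if (sp$frac < 0 || sp$frac > 1) stopf("sibling frac must be in [0,1]")
  }
  structure(as.list(environment())[names(formals(sim_config))],
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d classes (%s samples), %d genes, %d excl/class + %d shared signatures\n",
              x$n_classes, paste(range(x$samples_per_class), collapse = "-"),
              x$n_genes, x$n_exclusive_per_class, x$n_shared_signatures))
  invisible(x)
}

class_names <- function(n) sprintf("tissue%02d", seq_len(n))

#' Count matrix container
#'
#' Gene x sample integer read counts with gene ids/lengths and sample
#' labels, the native unit of every preprocessing step.
#'
#' @param counts gene x sample non-negative integer matrix with rownames
#'   (gene ids) and colnames (sample ids).
#' @param gene_lengths positive integer vector, one per gene.
#' @param labels factor of class labels, one per sample (optional).
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_lengths, labels = NULL) {
  if (!is.matrix(counts)) stopf("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts needs gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate gene ids: %s",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate sample ids: %s",
          paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0))
    stopf("counts must be finite and non-negative")
  if (length(gene_lengths) != nrow(counts))
    stopf("gene_lengths length (%d) != number of genes (%d)",
          length(gene_lengths), nrow(counts))
  if (any(gene_lengths <= 0)) stopf("gene lengths must be positive")
  if (!is.null(labels)) {
    if (length(labels) != ncol(counts))
      stopf("labels length (%d) != number of samples (%d)",
            length(labels), ncol(counts))
    labels <- as.factor(labels)
  }
  structure(list(counts = counts,
                 gene_ids = rownames(counts),
                 sample_ids = colnames(counts),
                 gene_lengths = stats::setNames(as.numeric(gene_lengths), rownames(counts)),
                 labels = labels),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples", nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$labels)) cat(sprintf(", %d classes", nlevels(x$labels)))
  cat("\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# Assign signature ownership. Returns a long data.frame with one row per
# (gene, owning class) plus one row per null gene (class NA, lfc 0).
plant_signatures <- function(cfg) {
  ng <- cfg$n_genes
  gid <- sprintf("g%04d", seq_len(ng))
  cls <- class_names(cfg$n_classes)
  pool <- seq_len(ng)  # consumed from the front
  take <- function(k) {
    if (k == 0) return(integer(0))
    idx <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    idx
  }

  rows <- list()
  sib_of <- rep(NA_integer_, cfg$n_classes)
  sib_frac <- rep(0, cfg$n_classes)
  for (sp in cfg$sibling_pairs) {
    sib_of[sp$classes[1]] <- sp$classes[2]
    sib_of[sp$classes[2]] <- sp$classes[1]
    sib_frac[sp$classes] <- sp$frac
  }

  draw_lfc <- function(n) {
    tier <- ifelse(stats::runif(n) < cfg$strong_frac, "strong", "subtle")
    mag <- ifelse(tier == "strong",
                  stats::runif(n, cfg$strong_lfc_range[1], cfg$strong_lfc_range[2]),
                  stats::runif(n, cfg$subtle_lfc_range[1], cfg$subtle_lfc_range[2]))
    sign <- ifelse(stats::runif(n) < cfg$down_frac, -1, 1)
    list(lfc = sign * mag, tier = tier)
  }

  done_sib <- logical(cfg$n_classes)
  for (k in seq_len(cfg$n_classes)) {
    n_excl <- cfg$n_exclusive_per_class
    if (!is.na(sib_of[k])) {
      n_pair <- round(sib_frac[k] * n_excl)
      n_own <- n_excl - n_pair
      if (!done_sib[k]) {  # the jointly owned genes, created once per pair
        j <- take(n_pair)
        d <- draw_lfc(n_pair)
        for (cl in c(k, sib_of[k])) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene = gid[j], class = cls[cl], lfc = d$lfc, tier = d$tier,
            exclusive = FALSE, stringsAsFactors = FALSE)
        }
        done_sib[k] <- done_sib[sib_of[k]] <- TRUE
      }
    } else {
      n_own <- n_excl
    }
    if (n_own > 0) {
      j <- take(n_own)
      d <- draw_lfc(n_own)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gid[j], class = cls[k], lfc = d$lfc, tier = d$tier,
        exclusive = TRUE, stringsAsFactors = FALSE)
    }
  }

  # globally shared signatures: each owned by a random pair of classes
  if (cfg$n_shared_signatures > 0) {
    j <- take(cfg$n_shared_signatures)
    d <- draw_lfc(cfg$n_shared_signatures)
    for (i in seq_along(j)) {
      pair <- sample.int(cfg$n_classes, 2L)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gid[j[i]], class = cls[pair], lfc = d$lfc[i], tier = d$tier[i],
        exclusive = FALSE, stringsAsFactors = FALSE)
    }
  }

  sig <- do.call(rbind, rows)
  nulls <- data.frame(gene = gid[pool], class = NA_character_, lfc = 0,
                      tier = "null", exclusive = FALSE, stringsAsFactors = FALSE)
  out <- rbind(sig, nulls)
  rownames(out) <- NULL
  out
}

#' Simulate a cohort with planted signature genes
#'
#' @param config a [sim_config()].
#' @return `list(counts, truth)`: a [count_matrix] and a `signature_truth`
#'   data.frame (one row per gene-class ownership; null genes carry class
#'   `NA` and lfc 0) with the per-gene baseline means, lengths and the
#'   config attached as attributes so an independent cohort can be drawn
#'   from the same world.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(derive_seed(config$seed, "simulate_cohort"), {
    truth <- plant_signatures(config)
    gid <- sprintf("g%04d", seq_len(config$n_genes))
    len <- round(stats::runif(config$n_genes, config$gene_length_range[1],
                              config$gene_length_range[2]))
    base <- stats::rlnorm(config$n_genes, config$baseline_meanlog,
                          config$baseline_sdlog) * len / 1000
    is_sig <- gid %in% truth$gene[!is.na(truth$class)]
    base[is_sig] <- pmax(base[is_sig], config$signature_baseline_floor)
    names(base) <- names(len) <- gid

    attr(truth, "baseline") <- base
    attr(truth, "gene_lengths") <- len
    attr(truth, "config") <- config
    class(truth) <- c("signature_truth", "data.frame")

    counts <- draw_counts(truth, config$samples_per_class,
                          classes = class_names(config$n_classes),
                          libsize_sigma = config$libsize_sigma,
                          dispersion = config$dispersion,
                          shift = NULL, prefix = "s")
    list(counts = counts, truth = truth)
  })
}

# log2 fold-change matrix (gene x class) implied by the truth table
lfc_matrix <- function(truth) {
  base <- attr(truth, "baseline")
  cfg <- attr(truth, "config")
  cls <- class_names(cfg$n_classes)
  L <- matrix(0, length(base), length(cls),
              dimnames = list(names(base), cls))
  sig <- truth[!is.na(truth$class), ]
  L[cbind(match(sig$gene, rownames(L)), match(sig$class, cls))] <- sig$lfc
  L
}

draw_counts <- function(truth, samples_per_class, classes, libsize_sigma,
                        dispersion, shift = NULL, prefix = "s") {
  base <- attr(truth, "baseline")
  len <- attr(truth, "gene_lengths")
  L <- lfc_matrix(truth)
  labels <- factor(rep(classes, samples_per_class), levels = colnames(L))
  n <- length(labels)
  lib <- stats::rlnorm(n, 0, libsize_sigma)
  mu_class <- base * 2^L[, as.character(labels), drop = FALSE]  # gene x sample
  if (!is.null(shift)) mu_class <- mu_class * shift
  mu <- sweep(mu_class, 2L, lib, `*`)
  size <- 1 / dispersion  # recycles over genes if per-gene
  cnt <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu), size = size),
                nrow(mu), ncol(mu))
  rownames(cnt) <- names(base)
  colnames(cnt) <- sprintf("%s%04d", prefix, seq_len(n))
  count_matrix(cnt, len, droplevels(labels))
}

#' Simulate an independent validation cohort from an existing truth table
#'
#' Draws new samples from the same signature model with fresh library
#' factors and an optional small per-gene cohort shift (log-normal), the
#' analogue of profiling the same tissues in a second study.
#'
#' @param truth a `signature_truth` returned by [simulate_cohort()].
#' @param classes character vector of classes to draw (subset allowed).
#' @param samples_per_class integer, scalar or one per class.
#' @param shift_sigma log-normal sigma of the per-gene cohort mean shift
#'   (0 = distributionally identical to the original generator).
#' @param seed integer seed.
#' @return a [count_matrix].
#' @export
simulate_independent_cohort <- function(truth, classes = NULL,
                                        samples_per_class = 5,
                                        shift_sigma = 0.1, seed = 43L) {
  stopifnot(inherits(truth, "signature_truth"))
  cfg <- attr(truth, "config")
  all_cls <- class_names(cfg$n_classes)
  if (is.null(classes)) classes <- all_cls
  missing <- setdiff(classes, all_cls)
  if (length(missing))
    stopf("class(es) absent from truth: %s", paste(missing, collapse = ", "))
  spc <- rep_len(samples_per_class, length(classes))
  with_local_seed(derive_seed(seed, "independent_cohort"), {
    shift <- if (shift_sigma > 0)
      stats::rlnorm(cfg$n_genes, 0, shift_sigma) else NULL
    draw_counts(truth, spc, classes, cfg$libsize_sigma, cfg$dispersion,
                shift = shift, prefix = "h")
  })
}

#' Model-implied one-vs-rest log2 fold changes
#'
#' The true one-vs-rest log2 fold change of every gene for every class,
#' computed from the generative model's expected CPM (class mean =
#' baseline x 2^lfc, per-class expected library size, rest = the
#' size-weighted mean of the other classes). This is the correct truth
#' oracle for one-vs-rest differential expression: a signature shared
#' with a sibling class is diluted because its co-owner sits in "rest",
#' and a strong marker of class A is genuinely down-regulated in every
#' other class's contrast.
#'
#' @param truth a `signature_truth` from [simulate_cohort()].
#' @return gene x class matrix of true log2 fold changes.
#' @export
expected_logfc <- function(truth) {
  stopifnot(inherits(truth, "signature_truth"))
  cfg <- attr(truth, "config")
  base <- attr(truth, "baseline")
  L <- lfc_matrix(truth)
  mu <- base * 2^L                      # gene x class expected counts
  # no library rescaling: TMM aligns the (null-gene) majority at logFC 0,
  # and null genes share one baseline across classes, so raw expected
  # counts are the matching truth scale
  n <- cfg$samples_per_class
  out <- matrix(NA_real_, nrow(mu), ncol(mu), dimnames = dimnames(mu))
  for (k in seq_len(ncol(mu))) {
    w <- n[-k] / sum(n[-k])
    rest <- as.vector(mu[, -k, drop = FALSE] %*% w)
    out[, k] <- log2(mu[, k] / rest)
  }
  out
}

#' Planted signature genes of a class
#'
#' @param truth a `signature_truth`.
#' @param class class name (e.g. `"tissue03"`); `NULL` for all signature
#'   genes of any class.
#' @param tier optionally restrict to `"strong"` or `"subtle"`.
#' @return character vector of gene ids.
#' @export
signature_genes <- function(truth, class = NULL, tier = NULL) {
  t <- truth[!is.na(truth$class), ]
  if (!is.null(class)) t <- t[t$class %in% class, ]
  if (!is.null(tier)) t <- t[t$tier %in% tier, ]
  unique(t$gene)
}
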