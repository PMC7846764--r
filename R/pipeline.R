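# End-to-end orchestration: simulate (or read) -> preprocess -> split ->
# balance -> train -> evaluate -> explain -> differential expression ->
# comparison -> cluster evaluation, with per-stage artifacts and a
# consolidated JSON summary. Stage seeds derive from one global seed.

#' Pipeline run configuration
#'
#' Every stage's tunables in one serializable list. `counts` may be a
#' [count_matrix] (or `counts_path`/`format`/`lengths_path`/`labels_path`
#' to read one); when neither is given a cohort is simulated from
#' `sim` (a [sim_config()]).
#'
#' @param sim a [sim_config()] (default: the package's reference
#'   synthetic cohort).
#' @param counts optional [count_matrix] to analyse instead.
#' @param per_class_test_n held-out samples per class.
#' @param min_count,min_tpm expression-filter thresholds.
#' @param min_samples filter sample threshold; `NULL` = `ceiling(0.8 *
#'   smallest class)`.
#' @param balance `"smote"`, `"none"`, `"ros"` or `"rus"`.
#' @param k_neighbors SMOTE neighbourhood size.
#' @param conv_channels,fc_hidden,epochs,lr,batch_size,patience CNN
#'   settings (desk-scale defaults).
#' @param background_size,shap_nsamples attribution settings.
#' @param depth rank depth of the selected gene lists; `NULL` = planted
#'   signatures per class when simulating, else 25.
#' @param lfc_cut,fdr_cut DE significance filters.
#' @param cluster_subsets,cluster_inits resampling-null size.
#' @param embed_method `"pca"` or `"umap"` for the cluster stage.
#' @param seed global seed.
#' @return a `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       counts = NULL,
                       per_class_test_n = 20,
                       min_count = 6, min_tpm = 0.1, min_samples = NULL,
                       balance = "smote", k_neighbors = 5,
                       conv_channels = c(8, 16, 32, 64), fc_hidden = 64,
                       epochs = 30, lr = 1e-3, batch_size = 32, patience = 5,
                       background_size = 100, shap_nsamples = 64,
                       depth = NULL,
                       lfc_cut = 4, fdr_cut = 0.01,
                       cluster_subsets = 20, cluster_inits = 20,
                       embed_method = "pca",
                       seed = 1L) {
  structure(as.list(environment())[names(formals(run_config))],
            class = "run_config")
}

stage_msg <- function(log, name, t0, ...) {
  dt <- as.numeric(Sys.time()) - t0
  message(sprintf("[%s] %5.1fs %s", name, dt, paste(..., collapse = " ")))
}

#' Run the full pipeline
#'
#' Executes both analysis branches — the classifier/attribution branch
#' and the differential-expression branch — plus their comparison and
#' the cluster-separability null, writing stage artifacts under
#' `out_dir` and returning a consolidated report. Idempotent given the
#' config seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (`NULL` = do not write artifacts).
#' @param verbose print per-stage progress.
#' @return a `run_report` list: `summary` (macro_f1, selected_depth,
#'   overlap_pct, cluster_p, ...), plus all stage objects.
#' @export
run_all <- function(config = run_config(), out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- as.numeric(Sys.time())
  say <- function(...) if (verbose) stage_msg(NULL, ..., t0 = t0)
  seed <- config$seed
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(name, fn) if (!is.null(out_dir)) fn(file.path(out_dir, name))

  # --- simulate / load -------------------------------------------------
  truth <- NULL
  if (is.null(config$counts)) {
    simc <- config$sim
    simc$seed <- derive_seed(seed, "sim")
    sim <- simulate_cohort(simc)
    cm <- sim$counts
    truth <- sim$truth
    emit("truth.csv", function(p) write_truth(truth, p))
    say("simulate", sprintf("%d genes x %d samples", nrow(cm$counts), ncol(cm$counts)))
  } else {
    cm <- config$counts
  }
  if (is.null(cm$labels)) stopf("labels are required")
  emit("counts.tsv", function(p) write_counts(cm, p))
  emit("labels.tsv", function(p) write_labels(
    stats::setNames(cm$labels, cm$sample_ids), p))

  # --- preprocess ------------------------------------------------------
  tpm <- compute_tpm(cm)
  min_samples <- config$min_samples
  if (is.null(min_samples)) min_samples <- ceiling(0.8 * min(table(cm$labels)))
  keep <- filter_genes(cm, tpm, config$min_count, config$min_tpm, min_samples)
  fcm <- count_matrix(cm$counts[keep, , drop = FALSE],
                      cm$gene_lengths[keep], cm$labels)
  say("filter", sprintf("%d of %d genes kept", sum(keep), length(keep)))

  split <- split_train_test(cm$labels, config$per_class_test_n,
                            seed = derive_seed(seed, "split"))
  # reference sample for TMM restricted to training data: held-out
  # samples must not influence training-time normalization
  tmm <- tmm_factors(fcm, ref_samples = fcm$sample_ids[split == "train"])
  expr <- tmm_cpm(fcm, tmm)
  dataset <- build_dataset(expr, fcm$labels, split)
  emit("split.tsv", function(p) utils::write.table(
    data.frame(sample_id = fcm$sample_ids, split = split), p,
    sep = "\t", quote = FALSE, row.names = FALSE))
  emit("gene_order.csv", function(p)
    utils::write.csv(dataset$gene_order, p, row.names = FALSE))
  say("preprocess", sprintf("%dx%d images", dataset$side, dataset$side))

  # --- balance + train -------------------------------------------------
  tr <- split == "train"
  bal <- balance_training(dataset$images[tr, , drop = FALSE],
                          dataset$labels[tr], method = config$balance,
                          k_neighbors = config$k_neighbors,
                          seed = derive_seed(seed, "balance"))
  say("balance", sprintf("%s: %d -> %d training samples", config$balance,
                         sum(tr), nrow(bal$X)))
  spec <- cnn_spec(dataset$side, nlevels(dataset$labels),
                   conv_channels = config$conv_channels,
                   fc_hidden = config$fc_hidden)
  model <- build_cnn(spec, seed = derive_seed(seed, "init"))
  model <- train_cnn(model, bal$X, bal$y, epochs = config$epochs,
                     lr = config$lr, batch_size = config$batch_size,
                     patience = config$patience,
                     seed = derive_seed(seed, "train"), verbose = verbose)
  emit("model", function(p) save_cnn(model, p))
  say("train", sprintf("%d epochs, final val F1 %.3f",
                       nrow(model$history), max(model$history$val_f1)))

  # --- evaluate --------------------------------------------------------
  metrics <- evaluate_model(model, dataset$images[!tr, , drop = FALSE],
                            dataset$labels[!tr])
  emit("metrics.json", function(p) jsonlite::write_json(
    list(macro_f1 = metrics$macro_f1, per_class = metrics$per_class),
    p, auto_unbox = TRUE, digits = NA))
  emit("confusion.csv", function(p)
    utils::write.csv(as.data.frame.matrix(metrics$confusion), p))
  say("evaluate", sprintf("macro-F1 %.4f", metrics$macro_f1))

  # --- explain ---------------------------------------------------------
  at <- attribution_tensor(model, dataset, which = "test",
                           background_size = config$background_size,
                           nsamples = config$shap_nsamples,
                           seed = derive_seed(seed, "shap"),
                           classes = "true")
  filt <- filter_attributions(at)
  table <- median_rank_genes(filt$values, filt$labels)
  depth <- config$depth
  if (is.null(depth)) {
    depth <- if (!is.null(truth))
      round(mean(vapply(class_names(attr(truth, "config")$n_classes),
                        function(cl) length(signature_genes(truth, cl)),
                        numeric(1))))
    else 25L
  }
  sel <- select_top_genes(table, depth, unique_fraction = 0.5)
  ucurve <- uniqueness_curve(table, unique(pmin(max(table$rank),
                                                c(1, 2, 5, 10, depth, 2 * depth))))
  emit("ranked_genes.csv", function(p) utils::write.csv(table, p, row.names = FALSE))
  emit("uniqueness.csv", function(p) utils::write.csv(ucurve, p, row.names = FALSE))
  say("explain", sprintf("%d kept samples, depth %d, %d unique genes",
                         ncol(filt$values), depth, length(sel$union)))

  # --- differential expression ----------------------------------------
  de <- de_one_vs_rest(fcm, tmm, lfc_cut = config$lfc_cut,
                       fdr_cut = config$fdr_cut)
  emit("de_table.csv", function(p) utils::write.csv(de, p, row.names = FALSE))
  say("diffexp", sprintf("%d significant flags", sum(de$significant)))

  # --- compare ---------------------------------------------------------
  cmp <- overlap_report(table, de, depth)
  emit("overlap.json", function(p) jsonlite::write_json(
    list(collapsed = cmp$collapsed, slots = cmp$slots,
         per_class = cmp$per_class), p, auto_unbox = TRUE, digits = NA))
  say("compare", sprintf("overlap %.1f%%", cmp$collapsed$overlap_pct))

  # --- cluster evaluation ---------------------------------------------
  test_expr <- t(transform_expression(expr[, !tr, drop = FALSE]))
  nt <- null_subset_test(test_expr, dataset$labels[!tr],
                         evaluated_genes = sel$union,
                         n_subsets = config$cluster_subsets,
                         inits_per_subset = config$cluster_inits,
                         method = config$embed_method,
                         seed = derive_seed(seed, "cluster"))
  emit("cluster_null.json", function(p) jsonlite::write_json(
    list(statistic = nt$statistic, null = nt$null, p = nt$p),
    p, auto_unbox = TRUE, digits = NA))
  say("clustereval", sprintf("V %.3f vs null %.3f, p %.3g",
                             nt$statistic, mean(nt$null), nt$p))

  summary <- list(macro_f1 = metrics$macro_f1,
                  n_genes_kept = sum(keep),
                  depth = depth,
                  depth_at_half_unique = sel$depth_at_fraction,
                  n_selected_unique = length(sel$union),
                  overlap_pct = cmp$collapsed$overlap_pct,
                  cluster_v = nt$statistic,
                  cluster_null_mean = mean(nt$null),
                  cluster_p = nt$p,
                  seed = seed)
  emit("summary.json", function(p) jsonlite::write_json(summary, p,
                                                        auto_unbox = TRUE,
                                                        digits = NA))
  structure(list(summary = summary, config = config, counts = cm,
                 filtered = fcm, truth = truth, tmm = tmm, dataset = dataset,
                 balanced = bal, model = model, metrics = metrics,
                 attributions = at, filtered_attributions = filt,
                 ranked = table, selection = sel, uniqueness = ucurve,
                 de = de, overlap = cmp, cluster = nt),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("run_report: macro-F1 %.4f | depth %d -> %d unique genes | ",
                     "DE overlap %.1f%% | cluster V %.3f (null %.3f), p %.3g\n"),
              s$macro_f1, s$depth, s$n_selected_unique, s$overlap_pct,
              s$cluster_v, s$cluster_null_mean, s$cluster_p))
  invisible(x)
}
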