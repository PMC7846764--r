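# Shared fixtures. Expensive objects (trained pipelines) are built once
# per test run and memoized; everything is generated in code.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# the reference synthetic world, preprocessed up to the image dataset
# (cheap: no training)
default_cohort <- function() {
  memo("default_cohort", function() {
    sim <- simulate_cohort(sim_config())
    cm <- sim$counts
    tpm <- compute_tpm(cm)
    keep <- filter_genes(cm, tpm,
                         min_samples = ceiling(0.8 * min(table(cm$labels))))
    fcm <- count_matrix(cm$counts[keep, ], cm$gene_lengths[keep], cm$labels)
    split <- split_train_test(cm$labels, 20, seed = 7)
    tmm <- tmm_factors(fcm, ref_samples = fcm$sample_ids[split == "train"])
    expr <- tmm_cpm(fcm, tmm)
    dataset <- build_dataset(expr, fcm$labels, split)
    list(cm = cm, truth = sim$truth, fcm = fcm, tpm = tpm, split = split,
         tmm = tmm, expr = expr, dataset = dataset)
  })
}

# the full default pipeline (the expensive shared fixture behind the
# model-level acceptance tests); ~8 min on one CPU
default_report <- function() {
  memo("default_report", function() {
    run_all(run_config(seed = 1L), out_dir = NULL, verbose = FALSE)
  })
}

# a compact all-strong-signature world for the attribution-vs-DE overlap
# property (no subtle tier, no siblings)
strong_report <- function() {
  memo("strong_report", function() {
    cfg <- run_config(
      sim = sim_config(n_classes = 5,
                       samples_per_class = c(60, 70, 80, 90, 100),
                       n_genes = 800, n_exclusive_per_class = 15,
                       n_shared_signatures = 20, strong_frac = 1,
                       sibling_pairs = list(), seed = 5L),
      seed = 5L)
    run_all(cfg, out_dir = NULL, verbose = FALSE)
  })
}

# transformed test-sample expression (sample x gene) from a run report,
# the input of the cluster-separability stage
report_test_expr <- function(rep) {
  tr <- rep$dataset$split == "train"
  expr <- tmm_cpm(rep$filtered, rep$tmm)
  list(X = t(transform_expression(expr[, !tr, drop = FALSE])),
       labels = rep$dataset$labels[!tr])
}

# a frozen ranked table built by hand, for table-shape operations
toy_ranked_table <- function() {
  df <- rbind(
    data.frame(class = "c1", rank = 1:4, gene = c("gA", "gB", "gC", "gD"),
               median_shap = c(4, 3, 2, 1)),
    data.frame(class = "c2", rank = 1:4, gene = c("gE", "gB", "gF", "gG"),
               median_shap = c(5, 2.5, 2, 0.5)))
  structure(df, class = c("ranked_gene_table", "data.frame"))
}

# independent V-measure oracle: mutual-information identities on a
# contingency table (distinct route from the conditional-entropy
# implementation)
v_measure_oracle <- function(ct) {
  n <- sum(ct)
  pj <- ct / n
  pc <- rowSums(pj); pk <- colSums(pj)
  mi <- 0
  for (i in seq_len(nrow(ct))) for (j in seq_len(ncol(ct))) {
    if (pj[i, j] > 0)
      mi <- mi + unname(pj[i, j] * log(pj[i, j] / (pc[i] * pk[j])))
  }
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  Hc <- ent(pc); Hk <- ent(pk)
  h <- if (Hc == 0) 1 else mi / Hc
  cc <- if (Hk == 0) 1 else mi / Hk
  v <- if (h + cc == 0) 0 else 2 * h * cc / (h + cc)
  list(h = h, c = cc, v = v)
}

# expand a contingency table back into label/cluster vectors
table_to_labels <- function(ct) {
  idx <- which(ct > 0, arr.ind = TRUE)
  list(labels = rep(rownames(ct)[idx[, 1]], ct[idx]),
       clusters = rep(colnames(ct)[idx[, 2]], ct[idx]))
}
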