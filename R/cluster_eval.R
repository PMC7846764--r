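# Cluster-separability evaluation of gene subsets: 2-D embedding,
# k-means with k = number of classes, V-measure scoring, and the
# resampling null that asks whether a candidate gene set separates the
# classes better than random same-size subsets.

#' 2-D embedding of samples restricted to a gene subset
#'
#' @param X sample x gene matrix of (transformed) expression.
#' @param genes optional character/integer subset of columns; the
#'   embedding is recomputed on the restriction.
#' @param method `"umap"` (default; `uwot`, 15 neighbours, min_dist 0.1)
#'   or `"pca"` (first two principal components; fast and exactly
#'   deterministic, used inside the resampling null).
#' @param seed integer seed.
#' @param n_neighbors,min_dist UMAP parameters.
#' @return sample x 2 coordinate matrix.
#' @export
embed_samples <- function(X, genes = NULL, method = c("umap", "pca"),
                          seed = 1L, n_neighbors = 15, min_dist = 0.1) {
  method <- match.arg(method)
  if (!is.null(genes)) {
    if (!length(genes)) stopf("empty gene subset")
    X <- X[, genes, drop = FALSE]
  }
  if (nrow(X) < 2) stopf("need >= 2 samples")
  if (method == "pca") {
    Xc <- scale(X, center = TRUE, scale = FALSE)
    sv <- svd(Xc, nu = 2, nv = 0)
    emb <- sv$u %*% diag(sv$d[1:2], 2)
  } else {
    emb <- with_local_seed(derive_seed(seed, "umap"), {
      uwot::umap(X, n_neighbors = min(n_neighbors, nrow(X) - 1),
                 min_dist = min_dist, n_threads = 1, n_sgd_threads = 0,
                 verbose = FALSE)
    })
  }
  rownames(emb) <- rownames(X)
  emb
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' V-measure of a clustering against true classes
#'
#' Homogeneity `h = 1 - H(C|K)/H(C)` (each cluster holds a single class),
#' completeness `c = 1 - H(K|C)/H(K)` (each class sits in a single
#' cluster), `V = 2hc/(h+c)`; conventions: `h = 1` when `H(C) = 0`,
#' `c = 1` when `H(K) = 0`, `V = 0` when `h + c = 0`.
#'
#' @param labels true class labels.
#' @param clusters cluster assignment, same length.
#' @return `v_measure_result`: `homogeneity`, `completeness`, `v`,
#'   `contingency` (class x cluster).
#' @export
v_measure <- function(labels, clusters) {
  stopifnot(length(labels) == length(clusters), length(labels) > 0)
  ct <- table(class = labels, cluster = clusters)
  n <- sum(ct)
  pc <- rowSums(ct) / n
  pk <- colSums(ct) / n
  Hc <- entropy_nats(pc)
  Hk <- entropy_nats(pk)
  # conditional entropies from the joint
  pj <- ct / n
  Hck <- -sum(pj[pj > 0] * log(pj[pj > 0] / rep(pk, each = nrow(ct))[pj > 0]))
  Hkc <- -sum(pj[pj > 0] * log(pj[pj > 0] / rep(pc, times = ncol(ct))[pj > 0]))
  h <- if (Hc == 0) 1 else 1 - Hck / Hc
  cm <- if (Hk == 0) 1 else 1 - Hkc / Hk
  v <- if (h + cm == 0) 0 else 2 * h * cm / (h + cm)
  structure(list(homogeneity = h, completeness = cm, v = v, contingency = ct),
            class = "v_measure_result")
}

#' @export
print.v_measure_result <- function(x, ...) {
  cat(sprintf("V = %.4f (homogeneity %.4f, completeness %.4f)\n",
              x$v, x$homogeneity, x$completeness))
  invisible(x)
}

#' Distribution of k-means V-measures over random initializations
#'
#' Repeated single-start k-means on a fixed embedding; each iteration is
#' an independent initialization and contributes one V-measure.
#'
#' @param embedding sample x d coordinates.
#' @param labels true class labels.
#' @param k number of clusters (use the number of classes so completeness
#'   and homogeneity are comparable).
#' @param iterations number of initializations.
#' @param seed integer seed.
#' @return `list(v, mean)`: all V-measures and their mean.
#' @export
kmeans_vmeasure_distribution <- function(embedding, labels, k,
                                         iterations = 100, seed = 1L) {
  if (k > nrow(embedding)) stopf("k (%d) exceeds sample count (%d)",
                                 k, nrow(embedding))
  vs <- with_local_seed(derive_seed(seed, "kmeans"), {
    vapply(seq_len(iterations), function(i) {
      km <- suppressWarnings(
        stats::kmeans(embedding, centers = k, nstart = 1, iter.max = 100))
      v_measure(labels, km$cluster)$v
    }, numeric(1))
  })
  list(v = vs, mean = mean(vs))
}

#' Resampling null for a candidate gene subset
#'
#' Protocol: the candidate set is embedded and scored by the mean
#' V-measure over `inits_per_subset` k-means initializations; the same
#' protocol is applied to `n_subsets` random gene subsets of equal size
#' (each re-embedded), whose means form the null distribution. The
#' one-tailed p-value compares the candidate's mean against the null on
#' the prediction scale, `t = (stat - mean(null)) / (sd(null) *
#' sqrt(1 + 1/n))` with `n - 1` degrees of freedom, so a candidate drawn
#' from the null itself yields p uniformly spread around 0.5. `test =
#' "mean"` gives the plain one-sample mean test instead.
#'
#' @param X sample x gene expression matrix (transformed scale).
#' @param labels true class labels.
#' @param evaluated_genes character vector: the candidate gene set.
#' @param n_subsets number of random subsets forming the null.
#' @param inits_per_subset k-means initializations per subset.
#' @param k number of clusters (default: number of classes).
#' @param method embedding method (see [embed_samples()]).
#' @param test `"prediction"` (default) or `"mean"`.
#' @param seed integer seed.
#' @return `null_test_result`: `statistic` (candidate mean V), `null`
#'   (the subset means), `p`, `t`, `df`.
#' @export
null_subset_test <- function(X, labels, evaluated_genes, n_subsets = 100,
                             inits_per_subset = 100, k = NULL,
                             method = c("pca", "umap"),
                             test = c("prediction", "mean"), seed = 1L) {
  method <- match.arg(method)
  test <- match.arg(test)
  labels <- droplevels(as.factor(labels))
  if (is.null(k)) k <- nlevels(labels)
  subset_size <- length(evaluated_genes)
  if (subset_size > ncol(X))
    stopf("subset size (%d) exceeds gene count (%d)", subset_size, ncol(X))
  missing <- setdiff(evaluated_genes, colnames(X))
  if (length(missing))
    stopf("evaluated gene(s) absent from X: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  score <- function(genes, s) {
    emb <- embed_samples(X, genes, method = method, seed = s)
    kmeans_vmeasure_distribution(emb, labels, k, inits_per_subset,
                                 seed = s)$mean
  }
  stat <- score(evaluated_genes, derive_seed(seed, "evaluated"))
  null <- with_local_seed(derive_seed(seed, "null_subsets"), {
    vapply(seq_len(n_subsets), function(i) {
      genes <- sample(colnames(X), subset_size)
      score(genes, derive_seed(seed, paste0("subset", i)))
    }, numeric(1))
  })
  n <- length(null)
  se <- stats::sd(null) * if (test == "prediction") sqrt(1 + 1 / n) else sqrt(1 / n)
  t <- (stat - mean(null)) / se
  p <- stats::pt(t, df = n - 1, lower.tail = FALSE)
  structure(list(statistic = stat, null = null, p = p, t = t, df = n - 1,
                 test = test),
            class = "null_test_result")
}

#' @export
print.null_test_result <- function(x, ...) {
  cat(sprintf("null_subset_test: statistic %.4f vs null %.4f +/- %.4f (n=%d), one-tailed p = %.3g\n",
              x$statistic, mean(x$null), stats::sd(x$null), x$df + 1, x$p))
  invisible(x)
}
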