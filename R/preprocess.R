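# Expression preprocessing: TPM, expression filtering, TMM normalization,
# the outlier-damping log transform, square-image encoding and the
# train/test split.

#' Transcripts per million
#'
#' Length-normalized within-sample abundance: `count/length`, rescaled so
#' each sample sums to 1e6.
#'
#' @param cm a [count_matrix] (gene lengths required) or a plain counts
#'   matrix plus `gene_lengths`.
#' @param gene_lengths lengths in bp when `cm` is a plain matrix.
#' @return gene x sample TPM matrix.
#' @export
compute_tpm <- function(cm, gene_lengths = NULL) {
  if (inherits(cm, "count_matrix")) {
    counts <- cm$counts
    gene_lengths <- cm$gene_lengths
  } else counts <- cm
  if (is.null(gene_lengths)) stopf("gene lengths are required for TPM")
  if (any(gene_lengths <= 0)) stopf("zero or negative gene length")
  rate <- counts / gene_lengths
  tot <- colSums(rate)
  if (any(tot == 0)) stopf("sample(s) with zero total counts: %s",
                           paste(colnames(counts)[tot == 0], collapse = ", "))
  sweep(rate, 2L, tot, `/`) * 1e6
}

#' Expressed-gene filter
#'
#' A gene is kept iff it has at least `min_count` reads in more than
#' `min_samples` samples AND more than `min_tpm` TPM in more than
#' `min_samples` samples (the intersection of the two criteria).
#'
#' @param counts gene x sample counts (matrix or [count_matrix]).
#' @param tpm gene x sample TPM matrix, same gene axis.
#' @param min_count minimum read count (inclusive).
#' @param min_tpm minimum TPM (exclusive).
#' @param min_samples number of samples the thresholds must be exceeded in
#'   (exclusive). At non-reference scale pick `ceiling(0.8 * smallest
#'   class)`, the rule the default threshold of 80 derives from.
#' @return named logical gene mask.
#' @export
filter_genes <- function(counts, tpm, min_count = 6, min_tpm = 0.1,
                         min_samples = 80) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  if (nrow(counts) != nrow(tpm))
    stopf("counts and tpm must share the gene axis")
  if (min_samples >= ncol(counts))
    stopf("min_samples (%d) must be < number of samples (%d)",
          min_samples, ncol(counts))
  keep <- (rowSums(counts >= min_count) > min_samples) &
          (rowSums(tpm > min_tpm) > min_samples)
  stats::setNames(keep, rownames(counts))
}

#' Trimmed mean of M-values normalization factors
#'
#' Between-sample scaling factors from the doubly trimmed,
#' precision-weighted mean of per-gene log2 expression ratios against a
#' reference sample (the sample whose 75th count-fraction percentile is
#' closest to the mean such percentile). Genes with a zero count in either
#' sample are excluded; the top/bottom `trim_M` of M-values and `trim_A`
#' of A-values are trimmed; weights are inverse delta-method variances.
#' Factors are re-centered to geometric mean 1.
#'
#' @param cm a [count_matrix] or plain counts matrix.
#' @param trim_M tail fraction trimmed from each end of the M
#'   distribution.
#' @param trim_A tail fraction trimmed from each end of the A
#'   distribution.
#' @param ref_samples optional character vector restricting which samples
#'   may serve as the reference (e.g. training samples only, to keep
#'   held-out data out of training-time normalization).
#' @return object of class `tmm_factors`: `factors` (named, geometric
#'   mean 1), `ref_sample`, `lib_sizes`.
#' @export
tmm_factors <- function(cm, trim_M = 0.30, trim_A = 0.05, ref_samples = NULL) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  lib <- colSums(counts)
  if (any(lib == 0))
    stopf("sample(s) with zero library size: %s",
          paste(colnames(counts)[lib == 0], collapse = ", "))
  frac <- sweep(counts, 2L, lib, `/`)
  uq <- apply(frac, 2L, stats::quantile, probs = 0.75)
  cand <- if (is.null(ref_samples)) seq_len(ncol(counts))
          else match(ref_samples, colnames(counts))
  ref <- cand[which.min(abs(uq[cand] - mean(uq[cand])))]
  f <- vapply(seq_len(ncol(counts)), function(k) {
    if (k == ref) return(1)
    tmm_pair(counts[, k], counts[, ref], lib[k], lib[ref], trim_M, trim_A)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  structure(list(factors = stats::setNames(f, colnames(counts)),
                 ref_sample = colnames(counts)[ref],
                 lib_sizes = lib),
            class = "tmm_factors")
}

# one sample against the reference; edgeR-style trimming semantics
tmm_pair <- function(y, yr, n, nr, trim_M, trim_A) {
  keep <- y > 0 & yr > 0
  y <- y[keep]; yr <- yr[keep]
  if (!length(y)) return(1)
  M <- log2((y / n) / (yr / nr))
  A <- 0.5 * log2((y / n) * (yr / nr))
  w <- (n - y) / (n * y) + (nr - yr) / (nr * yr)
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  nn <- length(M)
  if (!nn) return(1)
  if (max(abs(M)) < 1e-6) return(1)
  loM <- floor(nn * trim_M) + 1; hiM <- nn + 1 - loM
  loA <- floor(nn * trim_A) + 1; hiA <- nn + 1 - loA
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(1)
  2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

#' TMM-normalized counts per million
#'
#' @param cm [count_matrix] or counts matrix.
#' @param factors a [tmm_factors()] result (computed if missing).
#' @return gene x sample matrix of counts per million of the effective
#'   (TMM-scaled) library size.
#' @export
tmm_cpm <- function(cm, factors = NULL) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  if (is.null(factors)) factors <- tmm_factors(counts)
  eff <- factors$lib_sizes * factors$factors
  sweep(counts, 2L, eff, `/`) * 1e6
}

#' Outlier-damping expression transform
#'
#' `log2(x + 0.001) + 10`, applied to TMM-normalized expression before
#' image encoding: compresses outliers and moves zeros away from the dead
#' zone of downstream ReLU activations (transform(0) ~ 0.034 > 0).
#'
#' @param x non-negative expression value(s).
#' @return transformed value(s).
#' @export
transform_expression <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) stopf("x must be finite and >= 0")
  log2(x + 0.001) + 10
}

#' Pad a feature vector and reshape it into a square image
#'
#' The side is `ceiling(sqrt(n))`; the vector is laid out row-major and
#' the trailing `side^2 - n` positions are filled with
#' `transform_expression(0)` so pad pixels are indistinguishable from
#' unexpressed genes. An 18,884-gene vector becomes a 138 x 138 image
#' with 160 pad positions.
#'
#' @param x numeric vector of (already transformed) expression values,
#'   optionally named by gene.
#' @return a `gene_image`: list with `image` (side x side matrix), `side`,
#'   and `gene_order`, a data.frame mapping each image position (row-major
#'   index, row, col) to its gene (NA for padding).
#' @export
pad_and_reshape <- function(x) {
  n <- length(x)
  if (n < 1) stopf("need at least one value")
  side <- ceiling(sqrt(n))
  pad <- side^2 - n
  v <- c(x, rep(transform_expression(0), pad))
  img <- matrix(v, side, side, byrow = TRUE)
  ids <- if (!is.null(names(x))) names(x) else as.character(seq_len(n))
  gene_order <- data.frame(
    position = seq_len(side^2),
    row = rep(seq_len(side), each = side),
    col = rep(seq_len(side), side),
    gene = c(ids, rep(NA_character_, pad)),
    stringsAsFactors = FALSE)
  structure(list(image = img, side = side, gene_order = gene_order),
            class = "gene_image")
}

#' Recover the flat feature vector from a gene image
#' @param gi a `gene_image`.
#' @return the original (unpadded) vector, named by gene.
#' @export
unpad_image <- function(gi) {
  v <- as.vector(t(gi$image))
  keep <- !is.na(gi$gene_order$gene)
  stats::setNames(v[keep], gi$gene_order$gene[keep])
}

#' Per-class held-out split
#'
#' Randomly assigns exactly `per_class_test_n` samples of every class to
#' the test set, the rest to training.
#'
#' @param labels factor of class labels (named by sample id if available).
#' @param per_class_test_n held-out samples per class.
#' @param seed integer seed.
#' @return character vector `"train"`/`"test"`, aligned with `labels`.
#' @export
split_train_test <- function(labels, per_class_test_n = 50, seed = 1L) {
  labels <- as.factor(labels)
  sizes <- table(labels)
  bad <- names(sizes)[sizes <= per_class_test_n]
  if (length(bad))
    stopf("class(es) with <= %d samples cannot be split: %s",
          per_class_test_n, paste(bad, collapse = ", "))
  split <- rep("train", length(labels))
  with_local_seed(derive_seed(seed, "split_train_test"), {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      split[sample(idx, per_class_test_n)] <- "test"
    }
  })
  names(split) <- names(labels)
  split
}

#' Build a labelled image dataset from an expression matrix
#'
#' Applies [transform_expression()] to a normalized gene x sample matrix,
#' encodes each sample as a row-major flattened square image (pad value =
#' transform of zero) and attaches labels and the train/test split.
#'
#' @param expr gene x sample normalized expression (e.g. [tmm_cpm()]).
#' @param labels factor of class labels per sample.
#' @param split `"train"`/`"test"` per sample (see [split_train_test()]).
#' @param transform whether to apply the expression transform (set FALSE
#'   if `expr` is already transformed).
#' @return a `labeled_dataset`: `images` (sample x side^2 matrix, each row
#'   a flattened image), `side`, `gene_order`, `labels`, `split`.
#' @export
build_dataset <- function(expr, labels, split = NULL, transform = TRUE) {
  stopifnot(is.matrix(expr), ncol(expr) == length(labels))
  if (transform) expr <- transform_expression(expr)
  side <- ceiling(sqrt(nrow(expr)))
  pad <- side^2 - nrow(expr)
  padval <- transform_expression(0)
  flat <- t(rbind(expr, matrix(padval, pad, ncol(expr))))  # sample x side^2
  # rows of `flat` list genes in input order = row-major image layout
  template <- pad_and_reshape(stats::setNames(rep(0, nrow(expr)), rownames(expr)))
  if (is.null(split)) split <- rep("train", length(labels))
  structure(list(images = flat, side = side,
                 gene_order = template$gene_order,
                 labels = as.factor(labels),
                 split = split),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d samples, %dx%d images (%d genes + %d pad), %d classes, %d train / %d test\n",
              nrow(x$images), x$side, x$side,
              sum(!is.na(x$gene_order$gene)), sum(is.na(x$gene_order$gene)),
              nlevels(x$labels), sum(x$split == "train"), sum(x$split == "test")))
  invisible(x)
}
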