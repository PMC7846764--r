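# One-vs-rest differential expression on TMM-normalized counts with a
# conditional negative-binomial exact test (common dispersion estimated
# by pooled method of moments) and Benjamini-Hochberg adjustment.

#' Pooled method-of-moments NB dispersion
#'
#' Counts are scaled to a common library size; for each gene the pooled
#' within-group sample variance is compared with the mean under the NB
#' law `var = mu + alpha mu^2`, and the per-gene excess variances are
#' pooled by a ratio estimator `alpha = sum(s^2 - c*mu) / sum(mu^2)`.
#' Floored at 1e-6 (a Poisson-like cohort yields ~0).
#'
#' @param counts gene x sample matrix or [count_matrix].
#' @param groups factor of group memberships (>= 2 samples per group).
#' @param lib_sizes optional effective library sizes (default column
#'   sums).
#' @return dispersion scalar (>= 1e-6).
#' @export
estimate_common_dispersion <- function(counts, groups, lib_sizes = NULL) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  groups <- droplevels(as.factor(groups))
  if (any(table(groups) < 2)) stopf("every group needs >= 2 samples")
  if (all(counts == 0)) stopf("all-zero count matrix")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  r <- exp(mean(log(lib_sizes))) / lib_sizes
  X <- sweep(counts, 2L, r, `*`)
  num <- 0; den <- 0
  for (g in levels(groups)) {
    M <- X[, groups == g, drop = FALSE]
    n <- ncol(M)
    mu <- rowMeans(M)
    ss <- rowSums((M - mu)^2) / (n - 1)
    cpois <- mean(r[groups == g])  # Poisson part inflation from rescaling
    w <- mu > 1  # very low counts carry no dispersion information
    num <- num + sum((n - 1) * (ss[w] - cpois * mu[w]))
    den <- den + sum((n - 1) * mu[w]^2)
  }
  if (den <= 0) return(1e-6)
  max(num / den, 1e-6)
}

# Conditional NB exact test for one gene: group sums s1, s2 after library
# equalization; two-sided p = total conditional probability of outcomes no
# more likely than the observed split. For very large totals, where the
# exact support scan would cost hundreds of thousands of pmf evaluations,
# the conditional law is effectively Gaussian and a normal approximation
# (continuity-corrected, variance from the two group variances) is used.
exact_nb_p <- function(s1, s2, n1, n2, phi, mu = NULL) {
  s <- s1 + s2
  if (s == 0) return(1)
  if (is.null(mu)) mu <- s / (n1 + n2)
  phi <- max(phi, 1e-8)
  size1 <- n1 / phi; size2 <- n2 / phi
  mode <- round(s * n1 / (n1 + n2))
  sd1 <- sqrt(n1 * mu * (1 + phi * mu))
  if (abs(s1 - mode) + 24 * sd1 > 4e4) {
    v1 <- n1 * mu * (1 + phi * mu)
    v2 <- n2 * mu * (1 + phi * mu)
    vc <- v1 * v2 / (v1 + v2)
    z <- (abs(s1 - mode) - 0.5) / sqrt(vc)
    return(min(1, 2 * stats::pnorm(-max(z, 0))))
  }
  lp <- function(y) stats::dnbinom(y, size = size1, mu = n1 * mu, log = TRUE) +
    stats::dnbinom(s - y, size = size2, mu = n2 * mu, log = TRUE)
  half <- max(20, ceiling(12 * sd1))
  lo <- max(0, min(mode, s1) - half)
  hi <- min(s, max(mode, s1) + half)
  repeat {
    ys <- lo:hi
    lps <- lp(ys)
    mx <- max(lps)
    lobs <- lp(s1)
    grow <- FALSE
    if (lo > 0 && lps[1] > min(lobs, mx - 46)) { lo <- max(0, lo - half); grow <- TRUE }
    if (hi < s && lps[length(lps)] > min(lobs, mx - 46)) { hi <- min(s, hi + half); grow <- TRUE }
    if (!grow) break
  }
  z <- exp(lps - mx)
  p <- sum(z[lps <= lobs + 1e-10]) / sum(z)
  min(max(p, .Machine$double.xmin), 1)
}

#' Negative-binomial exact test between two groups
#'
#' Counts are first adjusted to a common effective library size (the
#' geometric mean), summed within group, and the conditional two-sided
#' exact p-value of the split is computed under
#' `NB(mean = n_k mu, size = n_k / dispersion)` per group.
#'
#' @param y1,y2 gene x sample count matrices for the two groups.
#' @param dispersion common NB dispersion (>= 0).
#' @param lib1,lib2 effective library sizes (library size x TMM factor).
#' @return per-gene two-sided p-values in `(0, 1]`.
#' @export
nb_exact_test <- function(y1, y2, dispersion, lib1 = NULL, lib2 = NULL) {
  if (dispersion < 0) stopf("dispersion must be >= 0")
  y1 <- as.matrix(y1); y2 <- as.matrix(y2)
  if (is.null(lib1)) lib1 <- colSums(y1)
  if (is.null(lib2)) lib2 <- colSums(y2)
  N <- exp(mean(log(c(lib1, lib2))))
  s1 <- round(rowSums(sweep(y1, 2L, N / lib1, `*`)))
  s2 <- round(rowSums(sweep(y2, 2L, N / lib2, `*`)))
  n1 <- ncol(y1); n2 <- ncol(y2)
  vapply(seq_along(s1), function(g)
    exact_nb_p(s1[g], s2[g], n1, n2, dispersion), numeric(1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return FDR-adjusted values (monotone, capped at 1).
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  n <- length(p)
  if (n <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' One-vs-rest differential expression for every class
#'
#' For each class, compares its samples against all remaining samples
#' with the NB exact test on TMM-equalized counts. Log2 fold changes are
#' computed from group-mean CPM with a prior count of 0.5; p-values are
#' BH-adjusted within class; a gene is flagged significant when
#' `FDR < fdr_cut` and `|logFC| > lfc_cut`.
#'
#' @param cm a [count_matrix] with labels (or a counts matrix plus
#'   `labels`).
#' @param tmm a [tmm_factors()] result (computed if NULL).
#' @param labels class labels when `cm` is a plain matrix.
#' @param lfc_cut absolute log2-fold-change cut-off.
#' @param fdr_cut FDR cut-off.
#' @param dispersion optional common dispersion (estimated if NULL).
#' @return a `de_table` data.frame: class, gene, logFC, p, fdr,
#'   significant, direction (`up`/`down`/`ns`), with a per-class summary
#'   (significant and class-exclusive significant counts) in
#'   `attr(, "summary")`.
#' @export
de_one_vs_rest <- function(cm, tmm = NULL, labels = NULL, lfc_cut = 4,
                           fdr_cut = 0.01, dispersion = NULL) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  if (is.null(labels)) labels <- cm$labels
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stopf("need >= 2 classes")
  if (is.null(tmm)) tmm <- tmm_factors(counts)
  eff <- tmm$lib_sizes * tmm$factors
  cpm <- sweep(counts + 0.5, 2L, eff, `/`) * 1e6
  if (is.null(dispersion))
    dispersion <- estimate_common_dispersion(counts, labels, lib_sizes = eff)
  out <- list()
  for (cl in levels(labels)) {
    grp <- labels == cl
    if (sum(grp) < 2) {
      warnf("class '%s' has < 2 samples; skipped", cl)
      next
    }
    p <- nb_exact_test(counts[, grp, drop = FALSE],
                       counts[, !grp, drop = FALSE],
                       dispersion,
                       lib1 = eff[grp], lib2 = eff[!grp])
    lfc <- log2(rowMeans(cpm[, grp, drop = FALSE]) /
                rowMeans(cpm[, !grp, drop = FALSE]))
    fdr <- bh_adjust(p)
    sig <- fdr < fdr_cut & abs(lfc) > lfc_cut
    out[[cl]] <- data.frame(
      class = cl, gene = rownames(counts), logFC = lfc, p = p, fdr = fdr,
      significant = sig,
      direction = ifelse(!sig, "ns", ifelse(lfc > 0, "up", "down")),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  de <- do.call(rbind, out)
  rownames(de) <- NULL
  sig <- de[de$significant, ]
  per_gene <- table(sig$gene)
  summ <- do.call(rbind, lapply(split(sig, sig$class), function(s)
    data.frame(class = s$class[1], n_significant = nrow(s),
               n_up = sum(s$direction == "up"),
               n_down = sum(s$direction == "down"),
               n_exclusive = sum(per_gene[s$gene] == 1), row.names = NULL)))
  attr(de, "summary") <- summ
  attr(de, "dispersion") <- dispersion
  class(de) <- c("de_table", "data.frame")
  de
}

#' Collapsed set of significant genes in a DE table
#' @param de a `de_table`.
#' @return sorted character vector of genes significant in any class.
#' @export
de_significant_genes <- function(de) {
  sort(unique(de$gene[de$significant]))
}
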