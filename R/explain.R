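# Expected-gradients attribution (a sampling approximation of Shapley
# values for differentiable models) and the downstream gene ranking:
# correct-class filtering, per-class median ranking, uniqueness /
# exclusivity accounting and top-k selection.

#' Expected-gradients attributions for one sample
#'
#' Monte-Carlo Shapley approximation: draw baselines `b` from the
#' background set (balanced cycling in shuffled order) and interpolation
#' coefficients `u` (stratified over `[0,1]`), evaluate the gradient of
#' the class output at `b + u (x - b)` and average `gradient * (x - b)`. Satisfies attribution completeness
#' in the sampling limit: the per-class sums converge to
#' `f_c(x) - E_b f_c(b)`.
#'
#' @param model a model with gradient support (`cnn_model` or
#'   [linear_model()]).
#' @param x input feature vector (for CNNs: flattened image, length
#'   side^2).
#' @param background matrix of background rows (same feature layout).
#' @param nsamples number of (b, u) draws.
#' @param seed integer seed.
#' @param classes integer vector of class outputs to attribute (default
#'   all).
#' @param output for CNN models, `"prob"` (default: explain the softmax
#'   probability, the model as deployed) or `"logit"` (explain the
#'   pre-softmax score; concentrates attributions on the class's own
#'   evidence).
#' @return class x feature matrix of attributions (rows for classes not
#'   requested are zero).
#' @export
expected_gradients <- function(model, x, background, nsamples = 200,
                               seed = 1L, classes = NULL, ...) {
  UseMethod("expected_gradients")
}

#' @export
expected_gradients.default <- function(model, x, background, nsamples = 200,
                                       seed = 1L, classes = NULL, ...) {
  stopf("model of class '%s' has no gradient support", class(model)[1])
}

eg_draws <- function(x, background, nsamples, seed) {
  if (!is.matrix(background)) background <- matrix(background, 1L)
  if (nrow(background) < 1) stopf("background must be non-empty")
  if (nsamples < 1) stopf("nsamples must be >= 1")
  with_local_seed(derive_seed(seed, "expected_gradients"), {
    # balanced baseline cycling (each background row drawn equally often)
    # with the interpolation coefficients stratified within each
    # baseline's path: unbiased, with far lower variance than i.i.d.
    # draws (the per-path integral is estimated on a stratified grid);
    # exact for linear models
    nb <- nrow(background)
    counts <- tabulate(rep_len(seq_len(nb), nsamples), nb)
    bidx <- rep(seq_len(nb), counts)
    u <- unlist(lapply(counts, function(k)
      if (k) (sample.int(k) - stats::runif(k)) / k else numeric(0)))
    B <- background[bidx, , drop = FALSE]
    diffs <- matrix(x, nsamples, length(x), byrow = TRUE) - B
    list(points = B + u * diffs, diffs = diffs)
  })
}

#' @rdname expected_gradients
#' @export
expected_gradients.cnn_model <- function(model, x, background, nsamples = 200,
                                         seed = 1L, classes = NULL,
                                         output = c("prob", "logit"), ...) {
  output <- match.arg(output)
  K <- model$spec$n_classes
  if (is.null(classes)) classes <- seq_len(K)
  dr <- eg_draws(x, background, nsamples, seed)
  fwd <- cnn_forward(model$params, model$rstats,
                     rows_to_array(dr$points, model$spec$side),
                     training = FALSE)
  probs <- softmax_rows(fwd$logits)
  phi <- matrix(0, K, length(x))
  for (cl in classes) {
    if (output == "prob") {
      dlog <- probs * (-probs[, cl])
      dlog[, cl] <- dlog[, cl] + probs[, cl]
    } else {
      dlog <- matrix(0, nrow(probs), K)
      dlog[, cl] <- 1
    }
    bk <- cnn_backward(model$params, fwd$caches, dlog, want_params = FALSE)
    phi[cl, ] <- colMeans(array_to_rows(bk$dX) * dr$diffs)
  }
  rownames(phi) <- model$classes %||% as.character(seq_len(K))
  phi
}

#' A linear multi-output model, mainly for validating attributions
#'
#' `f(x) = W x` (one raw output per row of W; no link). Its expected
#' gradients have the closed form `phi_cj = W_cj (x_j - mean_b b_j)`.
#'
#' @param W class x feature coefficient matrix.
#' @return a `linear_model`.
#' @export
linear_model <- function(W) {
  structure(list(W = as.matrix(W)), class = "linear_model")
}

#' @export
expected_gradients.linear_model <- function(model, x, background,
                                            nsamples = 200, seed = 1L,
                                            classes = NULL, ...) {
  K <- nrow(model$W)
  if (is.null(classes)) classes <- seq_len(K)
  dr <- eg_draws(x, background, nsamples, seed)
  phi <- matrix(0, K, length(x))
  md <- colMeans(dr$diffs)
  for (cl in classes) phi[cl, ] <- model$W[cl, ] * md
  phi
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Attribution tensor for a dataset's held-out samples
#'
#' Runs [expected_gradients()] for every selected sample against a
#' background drawn from the training rows, and maps image positions back
#' to genes through the dataset's `gene_order` (pad positions dropped).
#'
#' @param model trained `cnn_model`.
#' @param dataset a `labeled_dataset` (see [build_dataset()]).
#' @param which `"test"` (default) or `"train"`: which samples to explain.
#' @param background_size training rows subsampled as background (the
#'   full training set is the reference behaviour; a subsample keeps the
#'   cost bounded).
#' @param nsamples draws per explanation.
#' @param seed integer seed.
#' @param classes `"all"` or `"true"` (attribute only each sample's true
#'   class; other slices are NA — sufficient for the correct-class
#'   filtering downstream and several-fold cheaper).
#' @param output `"prob"` or `"logit"` (see [expected_gradients()]).
#' @return an `attribution_tensor`: array `[sample, class, gene]` plus
#'   `labels`, `predictions`, and the background description.
#' @export
attribution_tensor <- function(model, dataset, which = "test",
                               background_size = 100, nsamples = 64,
                               seed = 1L, classes = c("all", "true"),
                               output = c("prob", "logit")) {
  classes <- match.arg(classes)
  output <- match.arg(output)
  stopifnot(inherits(dataset, "labeled_dataset"))
  sel <- which(dataset$split == which)
  if (!length(sel)) stopf("no '%s' samples in dataset", which)
  tr <- which(dataset$split == "train")
  bg_n <- min(background_size, length(tr))
  bg_idx <- with_local_seed(derive_seed(seed, "background"),
                            sample(tr, bg_n))
  bg <- dataset$images[bg_idx, , drop = FALSE]
  keepg <- !is.na(dataset$gene_order$gene)
  genes <- dataset$gene_order$gene[keepg]
  K <- model$spec$n_classes
  labs <- dataset$labels[sel]
  preds <- predict(model, dataset$images[sel, , drop = FALSE], type = "class")
  phi <- array(NA_real_, c(length(sel), K, length(genes)),
               dimnames = list(NULL, model$classes, genes))
  for (i in seq_along(sel)) {
    want <- if (classes == "true") resolve_class(model, as.character(labs[i]))
            else seq_len(K)
    p <- expected_gradients(model, dataset$images[sel[i], ], bg,
                            nsamples = nsamples,
                            seed = derive_seed(seed, paste0("sample", sel[i])),
                            classes = want, output = output)
    phi[i, want, ] <- p[want, keepg, drop = FALSE]
  }
  structure(list(phi = phi, labels = labs, predictions = preds,
                 sample_ids = rownames(dataset$images[sel, , drop = FALSE]),
                 background = list(size = bg_n, source = "train"),
                 nsamples = nsamples),
            class = "attribution_tensor")
}

#' Correct-class attribution filtering
#'
#' Keeps only correctly predicted samples and, for each, the single
#' attribution slice of its true class, yielding one value per gene per
#' kept sample.
#'
#' @param at an `attribution_tensor`.
#' @return `list(values, labels)`: gene x kept-sample matrix and the kept
#'   samples' class labels. Classes that lose all their samples are
#'   reported with a warning.
#' @export
filter_attributions <- function(at) {
  stopifnot(inherits(at, "attribution_tensor"))
  ok <- which(as.character(at$predictions) == as.character(at$labels))
  if (!length(ok)) stopf("no correctly predicted samples to keep")
  lost <- setdiff(levels(at$labels), unique(as.character(at$labels[ok])))
  if (length(lost))
    warnf("class(es) with zero correct predictions excluded: %s",
          paste(lost, collapse = ", "))
  K <- dim(at$phi)[2]
  G <- dim(at$phi)[3]
  vals <- vapply(ok, function(i)
    at$phi[i, match(as.character(at$labels[i]), dimnames(at$phi)[[2]]), ],
    numeric(G))
  rownames(vals) <- dimnames(at$phi)[[3]]
  list(values = vals, labels = droplevels(at$labels[ok]))
}

#' Per-class median attribution ranking
#'
#' For each class, the median attribution of every gene over that class's
#' kept samples, ranked from largest to smallest (rank 1 = largest);
#' ties broken by ascending gene id.
#'
#' @param values gene x sample matrix (see [filter_attributions()]).
#' @param labels factor of the samples' classes.
#' @return a `ranked_gene_table` data.frame: class, rank, gene,
#'   median_shap.
#' @export
median_rank_genes <- function(values, labels) {
  stopifnot(ncol(values) == length(labels))
  labels <- droplevels(as.factor(labels))
  out <- lapply(levels(labels), function(cl) {
    med <- apply(values[, labels == cl, drop = FALSE], 1L, stats::median)
    ord <- order(-med, names(med))
    data.frame(class = cl, rank = seq_along(med), gene = names(med)[ord],
               median_shap = med[ord], row.names = NULL,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), class = c("ranked_gene_table", "data.frame"))
}

top_depth <- function(table, depth) {
  lapply(split(table, table$class), function(t)
    t$gene[t$rank <= depth])
}

#' Uniqueness and exclusivity at expanding rank depths
#'
#' At depth d there are `n_classes x d` slots; `unique` counts distinct
#' genes across classes (a gene in several classes counts once) and
#' `exclusive` counts genes present in exactly one class's top-d list.
#'
#' @param table a `ranked_gene_table`.
#' @param depths integer vector of depths (>= 1).
#' @return data.frame: depth, slots, unique_n, unique_frac, exclusive_n,
#'   exclusive_frac.
#' @export
uniqueness_curve <- function(table, depths) {
  max_rank <- max(table$rank)
  if (any(depths < 1) || any(depths > max_rank))
    stopf("depths must be in [1, %d]", max_rank)
  ncls <- length(unique(table$class))
  do.call(rbind, lapply(depths, function(d) {
    lists <- top_depth(table, d)
    genes <- unlist(lists, use.names = FALSE)
    tab <- table(genes)
    slots <- as.integer(ncls * d)
    data.frame(depth = d, slots = slots,
               unique_n = length(tab), unique_frac = length(tab) / slots,
               exclusive_n = sum(tab == 1), exclusive_frac = sum(tab == 1) / slots)
  }))
}

#' Select each class's top-ranked genes
#'
#' Returns the per-class top-`depth` lists and their deduplicated union
#' (the collapsed signature set). If `unique_fraction` is given, also
#' reports the smallest depth at which the unique-gene fraction first
#' drops to that level (the depth-selection rule used at reference scale
#' to pick 103 ranks at 50% uniqueness), or NA if never reached.
#'
#' @param table a `ranked_gene_table`.
#' @param depth rank depth.
#' @param unique_fraction optional target unique fraction in `(0, 1]`.
#' @return `list(per_class, union, depth_at_fraction)`.
#' @export
select_top_genes <- function(table, depth, unique_fraction = NULL) {
  max_rank <- max(table$rank)
  if (depth < 1 || depth > max_rank) stopf("depth must be in [1, %d]", max_rank)
  per_class <- top_depth(table, depth)
  res <- list(per_class = per_class,
              union = sort(unique(unlist(per_class, use.names = FALSE))),
              depth_at_fraction = NA_integer_)
  if (!is.null(unique_fraction)) {
    for (d in seq_len(max_rank)) {
      uc <- uniqueness_curve(table, d)
      if (uc$unique_frac <= unique_fraction) {
        res$depth_at_fraction <- d
        break
      }
    }
    if (is.na(res$depth_at_fraction))
      warnf("unique fraction never drops to %.2f within %d ranks",
            unique_fraction, max_rank)
  }
  res
}

#' Top-list overlap between two cohorts
#'
#' Per matched class, the size of the intersection of the two cohorts'
#' top-`depth` gene lists, plus the median across classes.
#'
#' @param tableA,tableB `ranked_gene_table`s over a shared gene universe.
#' @param depth rank depth.
#' @return `list(per_class, median)`.
#' @export
cohort_overlap <- function(tableA, tableB, depth) {
  clsA <- unique(tableA$class); clsB <- unique(tableB$class)
  shared <- intersect(clsA, clsB)
  if (!length(shared))
    stopf("no matched classes; A has [%s], B has [%s]",
          paste(clsA, collapse = ", "), paste(clsB, collapse = ", "))
  unmatched <- setdiff(clsB, clsA)
  if (length(unmatched))
    stopf("class(es) unmatched in cohort A: %s",
          paste(unmatched, collapse = ", "))
  la <- top_depth(tableA, depth); lb <- top_depth(tableB, depth)
  ov <- vapply(shared, function(cl)
    length(intersect(la[[cl]], lb[[cl]])), integer(1))
  list(per_class = ov, median = stats::median(ov))
}
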