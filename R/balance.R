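# Class balancing of the training set: SMOTE plus random over-/under-
# sampling baselines. Operates on sample x feature matrices of
# (transformed) expression vectors, before image reshaping.

#' SMOTE class balancing
#'
#' Over-samples every minority class up to `target_size` by synthesizing
#' points on segments between a source sample and one of its `k_neighbors`
#' nearest same-class neighbours (Euclidean): `s = x + u * (z - x)`,
#' `u ~ U(0, 1)`. Sources are cycled round-robin in a shuffled order so
#' the per-source synthetic counts differ by at most one. Originals are
#' retained unchanged.
#'
#' @param X sample x feature numeric matrix.
#' @param y factor of class labels.
#' @param k_neighbors neighbourhood size k.
#' @param target_size `"largest-class"` or an explicit count.
#' @param seed integer seed.
#' @return `list(X, y, provenance)`; `provenance` has one row per
#'   synthetic sample (source row, neighbour row, u, class) and row
#'   indices refer to the input `X`.
#' @export
smote_balance <- function(X, y, k_neighbors = 5, target_size = "largest-class",
                          seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  y <- droplevels(as.factor(y))
  sizes <- table(y)
  target <- if (identical(target_size, "largest-class")) max(sizes)
            else as.integer(target_size)
  newX <- list(); newy <- list(); prov <- list()
  with_local_seed(derive_seed(seed, "smote"), {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      need <- target - length(idx)
      if (need <= 0) next
      if (length(idx) <= k_neighbors)
        stopf("class '%s' has %d samples; SMOTE with k=%d needs more than k",
              cl, length(idx), k_neighbors)
      D <- as.matrix(stats::dist(X[idx, , drop = FALSE]))
      diag(D) <- Inf
      nn <- t(apply(D, 1L, function(d) order(d)[seq_len(k_neighbors)]))
      src <- rep(sample(seq_along(idx)), length.out = need)
      nb <- nn[cbind(src, sample.int(k_neighbors, need, replace = TRUE))]
      u <- stats::runif(need)
      S <- X[idx[src], , drop = FALSE] +
        u * (X[idx[nb], , drop = FALSE] - X[idx[src], , drop = FALSE])
      newX[[cl]] <- S
      newy[[cl]] <- rep(cl, need)
      prov[[cl]] <- data.frame(source = idx[src], neighbor = idx[nb],
                               u = u, class = cl, stringsAsFactors = FALSE)
    }
  })
  if (length(newX)) {
    Xb <- rbind(X, do.call(rbind, unname(newX)))
    yb <- factor(c(as.character(y), unlist(unname(newy))), levels = levels(y))
    pv <- do.call(rbind, unname(prov))
  } else {
    Xb <- X; yb <- y
    pv <- data.frame(source = integer(), neighbor = integer(),
                     u = numeric(), class = character())
  }
  rownames(pv) <- NULL
  list(X = Xb, y = yb, provenance = pv)
}

#' Random over-sampling to the largest class size
#'
#' @inheritParams smote_balance
#' @return `list(X, y, provenance)`; provenance holds the duplicated row
#'   indices.
#' @export
random_oversample <- function(X, y, seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  y <- droplevels(as.factor(y))
  target <- max(table(y))
  extra <- integer(0)
  with_local_seed(derive_seed(seed, "ros"), {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      need <- target - length(idx)
      if (need > 0) extra <- c(extra, sample(idx, need, replace = TRUE))
    }
  })
  list(X = rbind(X, X[extra, , drop = FALSE]),
       y = factor(c(as.character(y), as.character(y[extra])), levels = levels(y)),
       provenance = data.frame(source = extra))
}

#' Random under-sampling to the smallest class size
#'
#' @inheritParams smote_balance
#' @return `list(X, y, provenance)`; provenance holds the kept row
#'   indices (a subset of the input rows).
#' @export
random_undersample <- function(X, y, seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  y <- droplevels(as.factor(y))
  target <- min(table(y))
  keep <- integer(0)
  with_local_seed(derive_seed(seed, "rus"), {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      keep <- c(keep, if (length(idx) > target) sample(idx, target) else idx)
    }
  })
  keep <- sort(keep)
  list(X = X[keep, , drop = FALSE],
       y = factor(y[keep], levels = levels(y)),
       provenance = data.frame(source = keep))
}

#' Balance a training matrix by the requested method
#' @inheritParams smote_balance
#' @param method `"none"`, `"smote"`, `"ros"` or `"rus"`.
#' @export
balance_training <- function(X, y, method = c("smote", "none", "ros", "rus"),
                             k_neighbors = 5, seed = 1L) {
  method <- match.arg(method)
  switch(method,
         none = list(X = X, y = droplevels(as.factor(y)),
                     provenance = data.frame(source = integer())),
         smote = smote_balance(X, y, k_neighbors = k_neighbors, seed = seed),
         ros = random_oversample(X, y, seed = seed),
         rus = random_undersample(X, y, seed = seed))
}
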