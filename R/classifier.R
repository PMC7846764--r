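# The tissue classifier: four 3x3 convolutional blocks (conv -> batchnorm
# -> ReLU), 2x2 max-pooling after blocks 2 and 4, a two-layer fully
# connected head ending in a softmax over classes.

#' CNN architecture specification
#'
#' Four back-to-back convolutional blocks with 3x3 kernels that preserve
#' spatial size (unit stride, symmetric padding); 2x2 floor-mode max
#' pooling after blocks 2 and 4. At reference scale (side 138, final
#' channel count 256) the flattened embedding is 34 x 34 x 256 = 295,936.
#'
#' @param side input image side length (>= 4).
#' @param n_classes number of output classes.
#' @param conv_channels the four conv output channel counts; the default
#'   doubles per block up to 256.
#' @param fc_hidden width of the hidden fully connected layer.
#' @return a `cnn_spec`.
#' @export
cnn_spec <- function(side, n_classes, conv_channels = c(32, 64, 128, 256),
                     fc_hidden = 512) {
  if (!is_count(side) || side < 4) stopf("side must be a count >= 4")
  if (!is_count(n_classes)) stopf("n_classes must be a positive count")
  if (length(conv_channels) != 4 || !all(vapply(conv_channels, is_count, TRUE)))
    stopf("conv_channels must be four positive counts")
  embedding_size(side, conv_channels[4])  # validates the pooling schedule
  structure(list(side = as.integer(side), n_classes = as.integer(n_classes),
                 conv_channels = as.integer(conv_channels),
                 fc_hidden = as.integer(fc_hidden)),
            class = "cnn_spec")
}

#' Flattened embedding length after the pooling schedule
#'
#' Spatial size is halved (floor) after blocks 2 and 4:
#' `side -> floor(side/2) -> floor(floor(side/2)/2)`; the embedding is
#' that spatial extent squared times the final channel count. For side
#' 138 and 256 channels: 138 -> 69 -> 34, 34^2 x 256 = 295,936.
#'
#' @param side input side length (>= 4).
#' @param channels final convolutional channel count.
#' @return integer embedding length.
#' @export
embedding_size <- function(side, channels) {
  if (side < 4) stopf("side must be >= 4")
  s <- (side %/% 2) %/% 2
  if (s < 1) stopf("spatial extent collapses to zero")
  as.integer(s^2 * channels)
}

#' Build an (untrained) CNN
#'
#' He-normal weight initialization; batchnorm scale 1 / shift 0.
#'
#' @param spec a [cnn_spec()].
#' @param seed integer seed for the initialization.
#' @return a `cnn_model` (parameters, batchnorm running statistics,
#'   class levels unset until training).
#' @export
build_cnn <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cnn_spec"))
  ch <- c(1L, spec$conv_channels)
  embed <- embedding_size(spec$side, spec$conv_channels[4])
  with_local_seed(derive_seed(seed, "build_cnn"), {
    params <- list()
    for (b in 1:4) {
      fan_in <- 9 * ch[b]
      params[[paste0("conv", b)]] <-
        array(stats::rnorm(9 * ch[b] * ch[b + 1], 0, sqrt(2 / fan_in)),
              c(3, 3, ch[b], ch[b + 1]))
      params[[paste0("g", b)]] <- rep(1, ch[b + 1])
      params[[paste0("bb", b)]] <- rep(0, ch[b + 1])
    }
    params$fc1W <- matrix(stats::rnorm(embed * spec$fc_hidden, 0, sqrt(2 / embed)),
                          embed, spec$fc_hidden)
    params$fc1b <- rep(0, spec$fc_hidden)
    params$fc2W <- matrix(stats::rnorm(spec$fc_hidden * spec$n_classes, 0,
                                       sqrt(2 / spec$fc_hidden)),
                          spec$fc_hidden, spec$n_classes)
    params$fc2b <- rep(0, spec$n_classes)
    rstats <- list(rm = lapply(spec$conv_channels, function(c) rep(0, c)),
                   rv = lapply(spec$conv_channels, function(c) rep(1, c)))
    structure(list(spec = spec, params = params, rstats = rstats,
                   classes = NULL, history = NULL),
              class = "cnn_model")
  })
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("cnn_model: side %d, channels %s, fc %d -> %d classes%s\n",
              x$spec$side, paste(x$spec$conv_channels, collapse = "/"),
              x$spec$fc_hidden, x$spec$n_classes,
              if (is.null(x$classes)) " (untrained)" else ""))
  invisible(x)
}

#' Class probabilities for flattened-image rows
#'
#' @param object a `cnn_model`.
#' @param X sample x side^2 matrix of flattened images.
#' @param type `"prob"` for the softmax matrix, `"class"` for hard labels.
#' @param batch_size evaluation batch size.
#' @param ... unused.
#' @return probability matrix (samples x classes) or label vector.
#' @export
predict.cnn_model <- function(object, X, type = c("prob", "class"),
                              batch_size = 64L, ...) {
  type <- match.arg(type)
  if (is.vector(X)) X <- matrix(X, 1L)
  stopifnot(ncol(X) == object$spec$side^2)
  out <- matrix(NA_real_, nrow(X), object$spec$n_classes)
  for (i in split(seq_len(nrow(X)), ceiling(seq_len(nrow(X)) / batch_size))) {
    fwd <- cnn_forward(object$params, object$rstats,
                       rows_to_array(X[i, , drop = FALSE], object$spec$side),
                       training = FALSE)
    out[i, ] <- softmax_rows(fwd$logits)
  }
  if (!is.null(object$classes)) colnames(out) <- object$classes
  if (type == "class") {
    lab <- max.col(out, ties.method = "first")
    if (!is.null(object$classes))
      factor(object$classes[lab], levels = object$classes)
    else lab
  } else out
}

#' Gradient of one class output with respect to the input image
#'
#' Backpropagates the softmax probability of `class` to the input pixels
#' (evaluation mode batch normalization), the primitive underlying
#' expected-gradients attributions.
#'
#' @param model a `cnn_model`.
#' @param X sample x side^2 matrix of flattened images.
#' @param class class index (or label if the model is trained).
#' @return matrix of the same shape as `X` with `d p_class / d x`.
#' @export
input_gradient <- function(model, X, class) {
  if (is.vector(X)) X <- matrix(X, 1L)
  cl <- resolve_class(model, class)
  fwd <- cnn_forward(model$params, model$rstats,
                     rows_to_array(X, model$spec$side), training = FALSE)
  probs <- softmax_rows(fwd$logits)
  dlog <- probs * (-probs[, cl])
  dlog[, cl] <- dlog[, cl] + probs[, cl]
  bk <- cnn_backward(model$params, fwd$caches, dlog, want_params = FALSE)
  array_to_rows(bk$dX)
}

resolve_class <- function(model, class) {
  if (is.numeric(class)) return(as.integer(class))
  i <- match(as.character(class), model$classes)
  if (is.na(i)) stopf("unknown class '%s'", class)
  i
}

#' Train the CNN
#'
#' Adam on the softmax cross-entropy, with a stratified validation split
#' carved from the training rows and early stopping on validation
#' macro-F1. Deterministic given `seed` (single-threaded BLAS assumed;
#' with a threaded BLAS reductions may reorder, so determinism is
#' best-effort at the library level).
#'
#' @param model a `cnn_model` from [build_cnn()].
#' @param X sample x side^2 training matrix (flattened images).
#' @param y factor of training labels (nlevels must match the
#'   architecture's class count).
#' @param epochs maximum epochs.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param val_frac fraction of rows held out for validation.
#' @param patience early-stopping patience (epochs without improvement in
#'   validation macro-F1); `Inf` disables early stopping.
#' @param seed integer seed (shuffling, validation split).
#' @param verbose print per-epoch progress.
#' @return the trained `cnn_model`; `$history` holds per-epoch mean
#'   training loss and validation macro-F1.
#' @export
train_cnn <- function(model, X, y, epochs = 30L, lr = 1e-3, batch_size = 32L,
                      val_frac = 0.1, patience = 5L, seed = 1L,
                      verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"), is.matrix(X), nrow(X) == length(y))
  y <- droplevels(as.factor(y))
  if (nlevels(y) != model$spec$n_classes)
    stopf("labels have %d levels but the model expects %d",
          nlevels(y), model$spec$n_classes)
  model$classes <- levels(y)
  yi <- as.integer(y)
  K <- model$spec$n_classes
  side <- model$spec$side
  with_local_seed(derive_seed(seed, "train_cnn"), {
    val <- unlist(lapply(split(seq_along(yi), yi), function(ix)
      sample(ix, max(1L, round(val_frac * length(ix))))))
    tr <- setdiff(seq_along(yi), val)
    st <- adam_init(model$params)
    best <- list(f1 = -Inf, params = model$params, rstats = model$rstats,
                 stale = 0L)
    hist <- data.frame(epoch = integer(), loss = numeric(), val_f1 = numeric())
    for (ep in seq_len(epochs)) {
      ord <- sample(tr)
      losses <- numeric(0)
      for (bi in split(ord, ceiling(seq_along(ord) / batch_size))) {
        Xa <- rows_to_array(X[bi, , drop = FALSE], side)
        fwd <- cnn_forward(model$params, model$rstats, Xa, training = TRUE)
        model$rstats <- fwd$rstats
        P <- softmax_rows(fwd$logits)
        n <- length(bi)
        loss <- -mean(log(pmax(P[cbind(seq_len(n), yi[bi])], 1e-12)))
        if (!is.finite(loss))
          stopf("non-finite loss at epoch %d (batch of %d); lower the learning rate",
                ep, n)
        losses <- c(losses, loss)
        dZ <- P
        dZ[cbind(seq_len(n), yi[bi])] <- dZ[cbind(seq_len(n), yi[bi])] - 1
        dZ <- dZ / n
        bk <- cnn_backward(model$params, fwd$caches, dZ, want_params = TRUE)
        up <- adam_update(model$params, bk$grads, st, lr)
        model$params <- up$params
        st <- up$st
      }
      pv <- predict(model, X[val, , drop = FALSE], type = "prob")
      pred <- factor(model$classes[max.col(pv, ties.method = "first")],
                     levels = model$classes)
      vf1 <- suppressWarnings(
        evaluate_predictions(y[val], pred, model$classes)$macro_f1)
      hist <- rbind(hist, data.frame(epoch = ep, loss = mean(losses),
                                     val_f1 = vf1))
      if (verbose)
        message(sprintf("epoch %2d  loss %.4f  val macro-F1 %.4f",
                        ep, mean(losses), vf1))
      if (is.finite(vf1) && vf1 > best$f1 + 1e-9) {
        best <- list(f1 = vf1, params = model$params, rstats = model$rstats,
                     stale = 0L)
      } else {
        best$stale <- best$stale + 1L
        if (best$stale >= patience) break
      }
    }
    model$params <- best$params
    model$rstats <- best$rstats
    model$history <- hist
  })
  model
}

#' F1 score
#'
#' Harmonic mean of precision and recall; by convention 0 when both are 0.
#'
#' @param precision,recall values in `[0, 1]`.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(precision, recall) {
  stopifnot(all(precision >= 0 & precision <= 1, na.rm = TRUE),
            all(recall >= 0 & recall <= 1, na.rm = TRUE))
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

evaluate_predictions <- function(truth, pred, classes) {
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  cm <- table(truth = truth, predicted = pred)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), NA_real_)
  absent <- rowSums(cm) == 0
  if (any(absent))
    warnf("class(es) absent from the test set, metrics undefined: %s",
          paste(classes[absent], collapse = ", "))
  f1 <- f1_score(prec, ifelse(is.na(rec), 0, rec))
  f1[absent] <- NA_real_
  list(per_class = data.frame(class = classes, precision = prec,
                              recall = rec, f1 = f1, row.names = NULL),
       macro_f1 = mean(f1, na.rm = TRUE),
       confusion = cm)
}

#' Evaluate a trained model on held-out data
#'
#' @param model trained `cnn_model`.
#' @param X sample x side^2 matrix of flattened test images (must be
#'   disjoint from training data for the metrics to mean anything).
#' @param y factor of true labels.
#' @return `class_metrics`: per-class precision/recall/F1, unweighted
#'   macro-F1, confusion matrix (rows = true class), and the predictions.
#' @export
evaluate_model <- function(model, X, y) {
  pred <- predict(model, X, type = "class")
  y <- factor(y, levels = model$classes)
  out <- evaluate_predictions(y, pred, model$classes)
  out$predictions <- pred
  class(out) <- "class_metrics"
  out
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("class_metrics: macro-F1 %.4f over %d classes\n",
              x$macro_f1, nrow(x$per_class)))
  invisible(x)
}

#' Save / load a model (JSON architecture descriptor + weights file)
#'
#' @param model a `cnn_model`.
#' @param dir output directory (created if needed).
#' @return the directory (save) or the restored `cnn_model` (load).
#' @export
save_cnn <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(side = model$spec$side, n_classes = model$spec$n_classes,
         conv_channels = model$spec$conv_channels,
         fc_hidden = model$spec$fc_hidden, classes = model$classes),
    file.path(dir, "architecture.json"), auto_unbox = TRUE)
  saveRDS(list(params = model$params, rstats = model$rstats,
               history = model$history),
          file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_cnn
#' @export
load_cnn <- function(dir) {
  arch <- jsonlite::read_json(file.path(dir, "architecture.json"),
                              simplifyVector = TRUE)
  w <- readRDS(file.path(dir, "weights.rds"))
  spec <- cnn_spec(arch$side, arch$n_classes, arch$conv_channels,
                   arch$fc_hidden)
  structure(list(spec = spec, params = w$params, rstats = w$rstats,
                 classes = arch$classes, history = w$history),
            class = "cnn_model")
}
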