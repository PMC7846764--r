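test_that("embedding_size follows the two-pool floor schedule", {
  # reference scale: 138 -> 69 -> 34, 34^2 x 256 = 295,936
  expect_identical(embedding_size(138, 256), 295936L)
  expect_identical(embedding_size(8, 4), 16L)
  expect_identical(embedding_size(4, 1), 1L)
  expect_error(embedding_size(3, 1), ">= 4")
  # odd sides floor at both pooling points
  expect_identical(embedding_size(35, 64), 4096L)
})

test_that("embedding_size matches the engine-reported flattened length", {
  withr::with_seed(71, {
    for (side in c(7, 12, 21)) {
      ch <- sample(1:6, 4)
      spec <- cnn_spec(side, 3, conv_channels = ch, fc_hidden = 8)
      model <- build_cnn(spec, seed = side)
      fwd <- tissueshap:::cnn_forward(model$params, model$rstats,
                                      tissueshap:::rows_to_array(
                                        matrix(rnorm(2 * side^2), 2), side))
      expect_equal(ncol(fwd$caches$flat), embedding_size(side, ch[4]))
    }
  })
})

test_that("build_model outputs a softmax over classes", {
  spec <- cnn_spec(138, 47, conv_channels = c(2, 2, 2, 4), fc_hidden = 16)
  model <- build_cnn(spec, seed = 3)
  p <- predict(model, rnorm(138^2))
  expect_equal(dim(p), c(1, 47))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p > 0))

  # zeroed final layer -> exactly uniform probabilities
  small <- build_cnn(cnn_spec(8, 5, c(2, 2, 2, 2), 4), seed = 3)
  small$params$fc2W[] <- 0
  small$params$fc2b[] <- 0
  p0 <- predict(small, matrix(rnorm(3 * 64), 3))
  expect_equal(unname(p0), matrix(1 / 5, 3, 5))
})

test_that("backpropagated input gradients match finite differences", {
  spec <- cnn_spec(6, 3, conv_channels = c(2, 3, 2, 2), fc_hidden = 5)
  model <- build_cnn(spec, seed = 13)
  withr::with_seed(17, x <- rnorm(36))
  g <- input_gradient(model, x, class = 2)
  eps <- 1e-5
  num <- vapply(seq_along(x), function(j) {
    xp <- x; xp[j] <- xp[j] + eps
    xm <- x; xm[j] <- xm[j] - eps
    (predict(model, xp)[, 2] - predict(model, xm)[, 2]) / (2 * eps)
  }, numeric(1))
  expect_equal(as.vector(g), num, tolerance = 1e-5)
})

test_that("f1_score is the harmonic mean with the zero convention", {
  expect_equal(f1_score(1, 1), 1)
  x <- c(0.2, 0.5, 0.9)
  expect_equal(f1_score(x, x), x)       # fixed point
  expect_equal(f1_score(0.5, 1), 2 / 3) # direct evaluation
  expect_equal(f1_score(0, 0), 0)
  expect_error(f1_score(1.2, 0.5))
})

test_that("evaluate_model metrics and confusion bookkeeping", {
  y <- factor(rep(c("a", "b"), each = 6))
  # perfect predictions: all metrics 1, diagonal confusion
  mp <- tissueshap:::evaluate_predictions(y, y, c("a", "b"))
  expect_equal(mp$macro_f1, 1)
  expect_equal(mp$per_class$precision, c(1, 1))
  expect_equal(mp$per_class$recall, c(1, 1))
  expect_equal(unname(diag(mp$confusion)), c(6, 6))

  # a zeroed final layer is a constant predictor (uniform probabilities,
  # first class wins ties): macro-F1 on 2 balanced classes = 1/3
  model <- build_cnn(cnn_spec(4, 2, c(2, 2, 2, 2), 4), seed = 7)
  model$params$fc2W[] <- 0
  model$params$fc2b[] <- 0
  model$classes <- c("a", "b")
  X <- matrix(rnorm(12 * 16), 12)
  m <- evaluate_model(model, X, y)
  expect_equal(m$macro_f1, mean(c(2 / 3, 0)))
  expect_equal(as.character(unique(m$predictions)), "a")
  # confusion rows sum to per-class test counts
  expect_equal(unname(rowSums(m$confusion)), c(6, 6))
  expect_equal(unname(m$confusion["b", ]), c(6, 0))

  # class absent from the test set is flagged and excluded from the macro
  expect_warning(
    ma <- tissueshap:::evaluate_predictions(factor(rep("a", 4), levels = c("a", "b")),
                                            factor(rep("a", 4), levels = c("a", "b")),
                                            c("a", "b")),
    "absent")
  expect_true(is.na(ma$per_class$f1[2]))
  expect_equal(ma$macro_f1, 1)
})

test_that("training contract: lr 0 freezes parameters; loss decreases; seeded determinism", {
  spec <- cnn_spec(5, 2, c(2, 2, 2, 2), 4)
  withr::with_seed(23, {
    X <- rbind(matrix(1, 8, 25), matrix(-1, 8, 25)) + matrix(rnorm(16 * 25, sd = .3), 16)
  })
  y <- factor(rep(c("a", "b"), each = 8))
  m0 <- build_cnn(spec, seed = 29)
  frozen <- train_cnn(m0, X, y, epochs = 2, lr = 0, batch_size = 4,
                      val_frac = 0.25, patience = 10, seed = 31)
  expect_equal(frozen$params, m0$params)

  m1 <- train_cnn(m0, X, y, epochs = 5, batch_size = 4, val_frac = 0.25,
                  patience = 10, seed = 31)
  expect_true(all(diff(m1$history$loss[1:3]) < 0))

  m2 <- train_cnn(m0, X, y, epochs = 5, batch_size = 4, val_frac = 0.25,
                  patience = 10, seed = 31)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("models survive a save/load round trip", {
  dir <- withr::local_tempdir()
  spec <- cnn_spec(5, 3, c(2, 2, 2, 2), 4)
  model <- build_cnn(spec, seed = 41)
  model$classes <- c("x", "y", "z")
  save_cnn(model, dir)
  expect_true(file.exists(file.path(dir, "architecture.json")))
  back <- load_cnn(dir)
  X <- matrix(rnorm(2 * 25), 2)
  expect_equal(predict(back, X), predict(model, X))
})

test_that("sibling classes dominate the off-diagonal confusion mass", {
  # a world where the sibling pair shares its entire signature slot:
  # the two classes are distinguishable only by noise, every other class
  # keeps clean markers
  cfg <- sim_config(n_classes = 4, samples_per_class = c(60, 60, 60, 60),
                    n_genes = 300, n_exclusive_per_class = 10,
                    n_shared_signatures = 8,
                    sibling_pairs = list(list(classes = c(1L, 2L), frac = 1)),
                    seed = 77)
  sim <- simulate_cohort(cfg)
  cm <- sim$counts
  tpm <- compute_tpm(cm)
  keep <- filter_genes(cm, tpm, min_samples = 48)
  fcm <- count_matrix(cm$counts[keep, ], cm$gene_lengths[keep], cm$labels)
  split <- split_train_test(cm$labels, 15, seed = 78)
  tmm <- tmm_factors(fcm, ref_samples = fcm$sample_ids[split == "train"])
  ds <- build_dataset(tmm_cpm(fcm, tmm), fcm$labels, split)
  tr <- split == "train"
  spec <- cnn_spec(ds$side, 4, conv_channels = c(4, 8, 16, 32), fc_hidden = 32)
  model <- build_cnn(spec, seed = 79)
  model <- train_cnn(model, ds$images[tr, ], ds$labels[tr], epochs = 6,
                     patience = 6, seed = 80)
  m <- evaluate_model(model, ds$images[!tr, ], ds$labels[!tr])
  off <- m$confusion
  diag(off) <- 0
  sib_mass <- off["tissue01", "tissue02"] + off["tissue02", "tissue01"]
  expect_gt(sum(off), 0)  # identical signatures force confusion
  expect_gt(sib_mass / sum(off), 0.5)
  # the non-sibling classes stay accurate
  expect_gt(min(m$per_class$recall[3:4]), 0.8)
})
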