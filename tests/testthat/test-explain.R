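test_that("expected gradients: constant model, linear closed form, IG oracle", {
  withr::with_seed(301, {
    # constant model (zero coefficients): all attributions vanish
    zero <- linear_model(matrix(0, 2, 10))
    phi0 <- expected_gradients(zero, rnorm(10), matrix(rnorm(50), 5),
                               nsamples = 20, seed = 1)
    expect_equal(phi0, matrix(0, 2, 10))

    # linear model converges to w * (x - mean(background))
    W <- matrix(rnorm(3 * 40), 3)
    x <- rnorm(40)
    bg <- matrix(rnorm(30 * 40), 30)
    phi <- expected_gradients(linear_model(W), x, bg, nsamples = 4000, seed = 2)
    closed <- W * matrix(x - colMeans(bg), 3, 40, byrow = TRUE)
    expect_lt(norm(phi - closed, "F") / norm(closed, "F"), 0.05)

    # single baseline, dense u grid: matches the integrated-gradients
    # Riemann-sum oracle on a CNN
    model <- build_cnn(cnn_spec(5, 3, c(2, 3, 2, 2), 4), seed = 3)
    xx <- rnorm(25)
    b <- rnorm(25)
    phi1 <- expected_gradients(model, xx, matrix(b, 1), nsamples = 1500,
                               seed = 4, classes = 2)
    steps <- (seq_len(1500) - 0.5) / 1500
    gsum <- colMeans(input_gradient(
      model, t(vapply(steps, function(u) b + u * (xx - b), numeric(25))), 2))
    ig <- gsum * (xx - b)
    expect_lt(sum(abs(phi1[2, ] - ig)) / sum(abs(ig)), 0.01)
  })
  expect_error(expected_gradients(lm(speed ~ dist, cars), 1, matrix(1)),
               "gradient support")
})

test_that("filter_attributions keeps correct samples' true-class slice", {
  mk <- function(pred) {
    phi <- array(seq_len(3 * 2 * 4), c(3, 2, 4),
                 dimnames = list(NULL, c("a", "b"), paste0("g", 1:4)))
    structure(list(phi = phi,
                   labels = factor(c("a", "b", "a"), levels = c("a", "b")),
                   predictions = factor(pred, levels = c("a", "b"))),
              class = "attribution_tensor")
  }
  all_ok <- filter_attributions(mk(c("a", "b", "a")))
  expect_equal(dim(all_ok$values), c(4, 3))  # one value per gene per sample
  # true-class slice selected: sample 2 is class "b"
  at <- mk(c("a", "b", "a"))
  expect_equal(all_ok$values[, 2], at$phi[2, "b", ])

  one_bad <- suppressWarnings(filter_attributions(mk(c("a", "a", "a"))))
  expect_equal(dim(one_bad$values), c(4, 2))  # misclassified column absent

  expect_warning(filter_attributions(mk(c("b", "b", "b"))), "zero correct")
  expect_error(filter_attributions(mk(c("b", "a", "b"))), "no correctly")
})

test_that("median_rank_genes medians, tie-break and permutation symmetry", {
  vals <- rbind(gB = c(2, 2, 9), gA = c(1, 3, 9))
  labels <- factor(c("c1", "c1", "c2"))
  tab <- median_rank_genes(vals, labels)
  c1 <- tab[tab$class == "c1", ]
  # medians tie at 2: ascending gene id breaks the tie
  expect_equal(c1$gene, c("gA", "gB"))
  expect_equal(c1$median_shap, c(2, 2))
  # one sample per class: the median is the value itself
  expect_equal(tab$median_shap[tab$class == "c2"], c(9, 9))
  # permuting samples changes nothing
  perm <- c(2, 1, 3)
  expect_equal(median_rank_genes(vals[, perm], labels[perm]), tab)
  # medians are non-increasing with rank within class
  expect_true(all(diff(c1$median_shap) <= 0))
})

test_that("uniqueness_curve counts slots, unique and exclusive genes", {
  # 47 classes x depth 103 = 4,841 slots
  big <- structure(
    do.call(rbind, lapply(sprintf("c%02d", 1:47), function(cl)
      data.frame(class = cl, rank = 1:103,
                 gene = sprintf("g%03d", 1:103), median_shap = 0))),
    class = c("ranked_gene_table", "data.frame"))
  uc <- uniqueness_curve(big, 103)
  expect_equal(uc$slots, 4841)
  expect_equal(uc$unique_n, 103)
  expect_equal(uc$exclusive_n, 0)

  toy <- toy_ranked_table()
  u1 <- uniqueness_curve(toy, 1)  # top genes all distinct
  expect_equal(c(u1$unique_frac, u1$exclusive_frac), c(1, 1))
  u2 <- uniqueness_curve(toy, 2)  # one shared gene in 4 slots
  expect_equal(u2$slots, 4)
  expect_equal(u2$unique_n, 3)
  expect_equal(u2$exclusive_n, 2)
  expect_error(uniqueness_curve(toy, 9), "depths")
})

test_that("select_top_genes union, exclusives and the 50%-unique depth rule", {
  tab <- structure(
    rbind(data.frame(class = "c1", rank = 1:3, gene = c("A", "B", "C"),
                     median_shap = 3:1),
          data.frame(class = "c2", rank = 1:3, gene = c("C", "B", "A"),
                     median_shap = 3:1)),
    class = c("ranked_gene_table", "data.frame"))
  sel <- select_top_genes(tab, 3, unique_fraction = 0.5)
  expect_equal(sel$depth_at_fraction, 3)  # 3 unique / 6 slots at depth 3
  expect_equal(sel$union, c("A", "B", "C"))

  toy <- toy_ranked_table()
  s1 <- select_top_genes(toy, 1)
  expect_lte(length(s1$union), 2)  # bounded by class count
  s2 <- select_top_genes(toy, 2)
  uc <- uniqueness_curve(toy, 2)
  # the collapsed set contains every exclusive gene
  counts <- table(unlist(lapply(split(toy, toy$class), function(t)
    t$gene[t$rank <= 2])))
  expect_true(all(names(counts)[counts == 1] %in% s2$union))
  expect_warning(select_top_genes(toy, 2, unique_fraction = 0.1),
                 "never drops")
})

test_that("cohort_overlap per-class intersections and error on unmatched classes", {
  toy <- toy_ranked_table()
  same <- cohort_overlap(toy, toy, 3)
  expect_equal(unname(same$per_class), c(3, 3))  # identical tables
  other <- toy
  other$gene <- paste0(other$gene, "_x")  # disjoint universes
  expect_equal(cohort_overlap(toy, other, 3)$median, 0)
  stray <- toy
  stray$class <- sub("c2", "c9", stray$class)
  expect_error(cohort_overlap(toy, stray, 2), "c9")
})

test_that("attribution ranking on the trained pipeline recovers planted structure", {
  rep <- default_report()
  truth <- rep$truth
  tab <- rep$ranked
  genes <- rownames(rep$filtered_attributions$values)
  allsig <- intersect(signature_genes(truth), genes)

  for (cl in levels(rep$dataset$labels)) {
    own <- intersect(signature_genes(truth, cl), genes)
    top <- tab$gene[tab$class == cl & tab$rank <= length(own)]
    # the top-ranked gene is the class's own planted marker
    expect_true(top[1] %in% own)
    # null genes essentially never outrank planted signatures
    expect_gte(mean(top %in% allsig), 0.7)
  }

  # attribution completeness on one explained sample: the summed
  # attributions approximate f(x) - E[f(background)]
  ds <- rep$dataset
  tr <- ds$split == "train"
  bg <- ds$images[withr::with_seed(56, sample(which(tr), 20)), ]
  x <- ds$images[which(!tr)[1], ]
  cl <- tissueshap:::resolve_class(rep$model, as.character(ds$labels[!tr][1]))
  phi <- expected_gradients(rep$model, x, bg, nsamples = 200, seed = 31,
                            classes = cl)
  fx <- predict(rep$model, x)[, cl]
  fb <- mean(predict(rep$model, bg)[, cl])
  expect_equal(sum(phi[cl, ]), unname(fx - fb), tolerance = 0.05)
})

test_that("two cohorts from one truth overlap far above chance", {
  rep <- default_report()
  truth <- rep$truth
  ds <- rep$dataset
  # an independent validation cohort pushed through the same trained model
  ic <- simulate_independent_cohort(truth, samples_per_class = 6,
                                    shift_sigma = 0.1, seed = 33)
  keep <- rownames(rep$filtered$counts)
  icm <- count_matrix(ic$counts[keep, ], ic$gene_lengths[keep], ic$labels)
  itmm <- tmm_factors(icm)
  iexpr <- tmm_cpm(icm, itmm)
  tr <- ds$split == "train"
  images <- rbind(ds$images[tr, ], build_dataset(iexpr, icm$labels)$images)
  ds2 <- structure(list(
    images = images, side = ds$side, gene_order = ds$gene_order,
    labels = factor(c(as.character(ds$labels[tr]), as.character(icm$labels)),
                    levels = levels(ds$labels)),
    split = rep(c("train", "test"), c(sum(tr), ncol(icm$counts)))),
    class = "labeled_dataset")
  at2 <- attribution_tensor(rep$model, ds2, background_size = 100,
                            nsamples = 64, seed = 35, classes = "true")
  f2 <- filter_attributions(at2)
  tab2 <- median_rank_genes(f2$values, f2$labels)
  depth <- rep$summary$depth
  ov <- cohort_overlap(rep$ranked, tab2, depth)
  # hypergeometric chance expectation: depth^2 / n_genes (< 1 gene here)
  chance <- depth^2 / length(keep)
  expect_gt(ov$median, 10 * chance)
  expect_gte(min(ov$per_class), 1)
})
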