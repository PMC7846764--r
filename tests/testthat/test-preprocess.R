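test_that("compute_tpm normalizes to one million with length scaling", {
  cnt <- matrix(c(10, 10, 50, 100, 20, 5), 3,
                dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  # hand formula: rate = count/length, scaled to 1e6
  len <- c(1000, 2000, 500)
  tpm <- compute_tpm(cnt, len)
  rate <- cnt / len
  expect_equal(tpm, sweep(rate, 2, colSums(rate), "/") * 1e6)
  expect_equal(colSums(tpm), c(s1 = 1e6, s2 = 1e6))

  # single gene: all of the million
  one <- compute_tpm(cnt[1, , drop = FALSE], 1234)
  expect_equal(as.vector(one), c(1e6, 1e6))

  # equal counts, lengths L and 2L -> TPM ratio 2:1
  eq <- matrix(c(30, 30), 2, 1, dimnames = list(c("a", "b"), "s"))
  t2 <- compute_tpm(eq, c(1000, 2000))
  expect_equal(unname(t2["a", ] / t2["b", ]), 2)

  expect_error(compute_tpm(cnt, c(0, 1000, 500)), "length")
})

test_that("filter_genes implements the two-criterion intersection rule", {
  withr::with_seed(3, {
    cnt <- matrix(rpois(50 * 30, 5), 50,
                  dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:30)))
    tpm <- compute_tpm(cnt, rep(1000, 50))
    mask <- filter_genes(cnt, tpm, min_count = 6, min_tpm = 0.1,
                         min_samples = 10)
    # brute-force double-loop tally
    oracle <- vapply(1:50, function(g) {
      nc <- 0; nt <- 0
      for (s in 1:30) {
        if (cnt[g, s] >= 6) nc <- nc + 1
        if (tpm[g, s] > 0.1) nt <- nt + 1
      }
      nc > 10 && nt > 10
    }, logical(1))
    expect_equal(unname(mask), oracle)
  })

  # boundary of the stated rule: >= min_count reads in > min_samples samples
  n <- 20
  cnt <- matrix(1, 3, n, dimnames = list(c("pass", "edge", "zero"),
                                         sprintf("s%02d", 1:n)))
  cnt["pass", 1:11] <- 6    # 6 reads in exactly min_samples + 1 samples
  cnt["edge", 1:10] <- 100  # high counts but only min_samples samples
  cnt["zero", ] <- 0
  tpm <- compute_tpm(cnt + 0.5, rep(1000, 3)) # all TPM > 0.1
  mask <- filter_genes(cnt, tpm, min_count = 6, min_tpm = 0.1, min_samples = 10)
  expect_true(mask[["pass"]])
  expect_false(mask[["edge"]])
  expect_false(mask[["zero"]])

  expect_error(filter_genes(cnt, tpm, min_samples = 20), "min_samples")
})

test_that("tmm_factors: symmetry, scale invariance and brute-force toy", {
  withr::with_seed(5, {
    cnt <- matrix(rnbinom(200 * 6, mu = 50, size = 2), 200,
                  dimnames = list(sprintf("g%03d", 1:200), sprintf("s%d", 1:6)))
  })
  # identical samples -> all factors 1
  same <- cnt[, c(1, 1, 1)]
  colnames(same) <- c("a", "b", "c")
  expect_equal(unname(tmm_factors(same)$factors), rep(1, 3))

  # doubling a sample's counts leaves its factor at 1 (proportions unchanged)
  two <- cbind(s1 = cnt[, 1], s2 = 2 * cnt[, 1])
  expect_equal(unname(tmm_factors(two)$factors), c(1, 1))

  # global rescaling of one sample barely moves the factors: M-values are
  # depth-invariant; only the precision weights see the depth change
  f0 <- tmm_factors(cnt)$factors
  sc <- cnt; sc[, 3] <- sc[, 3] * 5
  expect_lt(max(abs(tmm_factors(sc)$factors - f0)), 0.05)

  # 6-gene x 2-sample toy vs a brute-force enumeration of the trimmed
  # weighted mean (written independently of tmm_pair)
  toy <- matrix(c(100, 50, 25, 200, 10, 5,
                  80, 60, 50, 150, 40, 2), 6,
                dimnames = list(letters[1:6], c("k", "r")))
  n <- sum(toy[, "k"]); nr <- sum(toy[, "r"])
  M <- log2((toy[, "k"] / n) / (toy[, "r"] / nr))
  A <- 0.5 * log2((toy[, "k"] / n) * (toy[, "r"] / nr))
  w <- (n - toy[, "k"]) / (n * toy[, "k"]) + (nr - toy[, "r"]) / (nr * toy[, "r"])
  # 30% M-trim of 6 values: floor(6 * 0.3) + 1 = 2 .. 5 (one per side);
  # 5% A-trim removes nothing
  keep <- rank(M, ties.method = "first") %in% 2:5 &
    rank(A, ties.method = "first") %in% 1:6
  expected <- 2^(sum((M / w)[keep]) / sum((1 / w)[keep]))
  got <- tmm_factors(toy)
  # whichever sample is the reference, the ratio of factors matches the
  # brute-force trimmed weighted mean (trimming is symmetric here)
  ratio <- got$factors[["k"]] / got$factors[["r"]]
  expect_equal(ratio, expected, tolerance = 1e-10)

  zero <- cnt; zero[, 2] <- 0
  expect_error(tmm_factors(zero), "zero library size")
})

test_that("tmm_factors agrees with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  withr::with_seed(11, {
    for (rep in 1:3) {
      cnt <- matrix(rnbinom(300 * 8, mu = exp(rnorm(300, log(60), 1)),
                            size = 3), 300,
                    dimnames = list(sprintf("g%03d", 1:300), sprintf("s%d", 1:8)))
      ours <- tmm_factors(cnt)$factors
      ref <- edgeR::calcNormFactors(edgeR::DGEList(cnt), method = "TMM")
      expect_equal(unname(ours), ref$samples$norm.factors, tolerance = 0.02)
    }
  })
})

test_that("transform_expression matches its closed form and is monotone", {
  expect_equal(transform_expression(1023.999), 20)
  expect_equal(transform_expression(0), log2(0.001) + 10)
  x <- sort(runif(50, 0, 100))
  expect_true(all(diff(transform_expression(x)) > 0))
  expect_error(transform_expression(-1), ">= 0")
})

test_that("pad_and_reshape side rule, padding value and round trip", {
  # the reference-scale shape: 18,884 genes -> 138 x 138 with 160 pads
  gi <- pad_and_reshape(rep(1, 18884))
  expect_equal(gi$side, 138)
  expect_equal(sum(is.na(gi$gene_order$gene)), 160)

  expect_equal(pad_and_reshape(1:9)$side, 3)
  gi10 <- pad_and_reshape(1:10)
  expect_equal(gi10$side, 4)
  expect_equal(sum(is.na(gi10$gene_order$gene)), 6)
  expect_equal(as.vector(gi10$image[4, 3:4]),
               rep(transform_expression(0), 2))

  # row-major layout and exact unpad round trip
  v <- setNames(rnorm(7), paste0("g", 1:7))
  gi7 <- pad_and_reshape(v)
  expect_equal(gi7$image[1, 2], v[["g2"]])
  expect_equal(gi7$image[2, 1], v[["g4"]])
  expect_equal(unpad_image(gi7), v)
})

test_that("split_train_test is exact, per-class and seeded", {
  labels <- factor(rep(sprintf("c%02d", 1:47), each = 55))
  sp <- split_train_test(labels, per_class_test_n = 50, seed = 1)
  expect_equal(sum(sp == "test"), 2350)
  expect_equal(sum(sp == "train"), 47 * 55 - 2350)
  tt <- table(labels[sp == "test"])
  expect_true(all(tt == 50))
  expect_identical(sp, split_train_test(labels, 50, seed = 1))
  expect_false(identical(sp, split_train_test(labels, 50, seed = 2)))

  small <- factor(rep(c("a", "b"), c(50, 60)))
  expect_error(split_train_test(small, 50), "a")
})

test_that("build_dataset flattens row-major and survives the round trip", {
  withr::with_seed(7, {
    expr <- matrix(rlnorm(11 * 4), 11,
                   dimnames = list(paste0("g", 1:11), paste0("s", 1:4)))
  })
  ds <- build_dataset(expr, factor(c("a", "a", "b", "b")))
  expect_equal(ds$side, 4)
  # image row of sample 2 equals the transformed expression vector + pads
  v <- transform_expression(expr[, 2])
  expect_equal(unname(ds$images[2, 1:11]), unname(v))
  expect_equal(unname(ds$images[2, 12:16]), rep(transform_expression(0), 5))
  # gene_order maps flattened positions back to genes
  keep <- !is.na(ds$gene_order$gene)
  expect_equal(ds$gene_order$gene[keep], rownames(expr))
})
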