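test_that("cpm matches the direct formula on hand cases", {
  m <- matrix(10, 1, 1, dimnames = list("g", "s"))
  expect_equal(unname(cpm(m)[1, 1]), 1e6)
  m2 <- matrix(c(1, 9), 2, 1, dimnames = list(c("a", "b"), "s"))
  expect_equal(unname(cpm(m2)[, 1]), c(1e5, 9e5))
  m3 <- rbind(m2, zero = 0)
  expect_equal(unname(cpm(m3)["zero", ]), 0)
})

test_that("cpm columns sum to one million and zero libraries are rejected", {
  set.seed(1)
  m <- rand_counts(50, 6)
  expect_equal(unname(colSums(cpm(m))), rep(1e6, 6), tolerance = 1e-9)
  m[, 2] <- 0
  expect_error(cpm(m), "positive")
})

test_that("filter_expressed keeps genes by CPM support count", {
  ## gene at CPM 0.5 everywhere: counts 1 in libraries of 2e6
  base <- matrix(2e6 - 1, 1, 4)
  m <- rbind(low = 1, filler = base - 1)
  colnames(m) <- paste0("s", 1:4)
  out <- filter_expressed(m, min_cpm = 1, min_samples = 1)
  expect_false("low" %in% rownames(out))
  expect_true("low" %in% attr(out, "removed"))

  ## gene at CPM >= 1 in exactly k samples is kept iff k >= min_samples
  for (k in 0:4) {
    cts <- matrix(0, 2, 4, dimnames = list(c("g", "big"), paste0("s", 1:4)))
    cts["big", ] <- 1e6
    if (k > 0) cts["g", seq_len(k)] <- 2  # CPM ~2 in k samples
    for (ms in 1:4) {
      kept <- "g" %in% rownames(filter_expressed(cts, 1, ms))
      expect_identical(kept, k >= ms)
    }
  }
})

test_that("filter_expressed tolerates empty results and is order-invariant", {
  z <- matrix(0:1, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  z["b", ] <- 1e6  # carrier so libraries are positive
  z["a", ] <- 0
  expect_equal(nrow(filter_expressed(z, min_cpm = 2e6, min_samples = 1)), 0)

  set.seed(2)
  m <- rand_counts(40, 5, lambda = 2)
  perm <- sample(nrow(m))
  f1 <- filter_expressed(m, 1, 2)
  f2 <- filter_expressed(m[perm, ], 1, 2)
  expect_setequal(rownames(f1), rownames(f2))
  expect_error(filter_expressed(m, 1, 99), "exceeds")
})

test_that("median_of_ratios reproduces closed-form size factors", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), 3, 2,
              dimnames = list(letters[1:3], c("A", "B")))
  nr <- median_of_ratios(m)
  expect_equal(unname(nr$size_factors), c(1, 1))
  expect_equal(nr$normalized, m)

  m2 <- cbind(A = c(10, 20, 30), B = c(20, 40, 60))
  rownames(m2) <- letters[1:3]
  nr2 <- median_of_ratios(m2)
  expect_equal(unname(nr2$size_factors[2] / nr2$size_factors[1]), 2)
  expect_equal(unname(nr2$normalized[, "A"]), unname(nr2$normalized[, "B"]))

  single <- matrix(c(5, 50, 500), 3, 1, dimnames = list(letters[1:3], "A"))
  expect_equal(unname(median_of_ratios(single)$size_factors), 1)
})

test_that("median_of_ratios is scale-equivariant on positive matrices", {
  ## rescaling one column by c rescales its size factor by c relative to the
  ## others (the factors share an arbitrary overall scale through the
  ## per-gene geometric means, so only ratios are identified)
  set.seed(3)
  for (i in 1:10) {
    m <- rand_counts(30, 4, lambda = 100) + 1  # all positive
    sf <- median_of_ratios(m)$size_factors
    c_scale <- runif(1, 0.2, 5)
    m2 <- m
    m2[, 3] <- m[, 3] * c_scale
    sf2 <- median_of_ratios(m2)$size_factors
    expect_equal(unname(sf2[3] / sf2[1]),
                 unname(c_scale * sf[3] / sf[1]), tolerance = 1e-12)
    expect_equal(unname(sf2[-3] / sf2[1]), unname(sf[-3] / sf[1]),
                 tolerance = 1e-12)
  }
})

test_that("size factors agree with the DESeq2 estimator up to a common scale", {
  skip_if_not_installed("DESeq2")
  set.seed(6)
  m <- rand_counts(200, 6, lambda = 60)
  m[sample(length(m), 100)] <- 0  # some zeros so the reference set matters
  sf <- median_of_ratios(m)$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ## DESeq2 takes the median in log space, which differs from the ratio-space
  ## median only in the midpoint of an even-sized reference set
  expect_equal(unname(sf / sf[1]), unname(ref / ref[1]), tolerance = 1e-4)
})

test_that("median_of_ratios needs a non-empty reference set", {
  m <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(c("a", "b"), c("A", "B")))
  expect_error(median_of_ratios(m), "reference")
})

test_that("mds_outliers flags a planted outlier and respects the cap", {
  set.seed(4)
  ## gene-level means vary ~10-fold, so replicate profiles correlate near 1
  profile <- exp(rnorm(300, log(100), 1))
  m <- sapply(1:5, function(i) rpois(300, profile))
  m[, 5] <- rpois(300, exp(rnorm(300, log(100), 1)))  # unrelated profile
  dimnames(m) <- list(sprintf("g%d", 1:300), sprintf("s%d", 1:5))
  rep_groups <- c("a", "a", "a", "b", "b")
  rpt <- mds_outliers(m, rep_groups, n_flag_max = 2, k = 2)
  expect_true("s5" %in% rpt$flagged)
  expect_true(all(rpt$flagged %in% colnames(m)))

  rpt0 <- mds_outliers(m, rep_groups, n_flag_max = 0)
  expect_length(rpt0$flagged, 0)
})

test_that("mds_outliers leaves identical samples unflagged and validates input", {
  m <- matrix(rep(c(5, 10, 20), 4), 3, 4,
              dimnames = list(letters[1:3], paste0("s", 1:4)))
  rpt <- mds_outliers(m, rep("g", 4))
  expect_length(rpt$flagged, 0)
  expect_equal(dim(rpt$coordinates), c(4, 2))
  expect_error(mds_outliers(m[, 1:2], c("g", "g")), "3 samples")
})

test_that("mds_outliers exempts singleton groups", {
  set.seed(5)
  m <- rand_counts(100, 5)
  rpt <- mds_outliers(m, c("a", "a", "a", "a", "lone"))
  expect_true("lone" %in% rpt$exempt)
  expect_false("s05" %in% rpt$flagged)
})
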