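# KNN with correlation distance, normalization, one-vs-rest assembly.

test_that("normalization is fit on training rows with population SDs", {
  X <- cbind(a = c(0, 2), b = c(5, 5))
  p <- fit_normalization(X)
  expect_equal(unname(p$mean), c(1, 5))
  expect_equal(unname(p$sd), c(1, 0))  # population convention
  Xn <- apply_normalization(X, p)
  expect_equal(unname(Xn[, 1]), c(-1, 1))
  expect_true(all(Xn[, 2] == 0))      # constant column -> zeros
  set.seed(2)
  X2 <- matrix(rnorm(60, 3, 2), 20, 3)
  Xn2 <- apply_normalization(X2, fit_normalization(X2))
  expect_lt(max(abs(colMeans(Xn2))), 1e-10)
  expect_error(fit_normalization(X2[0, ]), "empty")
})

test_that("correlation distance follows 1 - Pearson r with documented fallbacks", {
  u <- c(1.2, -0.3, 2.2)
  expect_equal(correlation_distance(u, u), 0)
  expect_equal(correlation_distance(u, -u), 2)
  expect_equal(correlation_distance(c(1, 2, 3), c(1, 3, 2)), 0.5)
  # symmetry and affine invariance
  set.seed(8)
  a <- rnorm(6); b <- rnorm(6)
  expect_equal(correlation_distance(a, b), correlation_distance(b, a))
  expect_equal(correlation_distance(3 * a + 2, b), correlation_distance(a, b),
               tolerance = 1e-12)
  # zero-variance fallback and errors
  expect_equal(correlation_distance(c(1, 1, 1), b[1:3]), 1)
  expect_error(correlation_distance(a, b[1:3]), "mismatch")
  expect_error(correlation_distance(1, 2), "length")
})

test_that("knn scores are neighbour vote fractions with index tie-breaks", {
  # single feature: absolute-difference distance
  Xtr <- matrix(c(0.1, 0.2, 0.9), ncol = 1)
  ytr <- c(1L, 0L, 1L)
  expect_equal(knn_scores(Xtr, ytr, matrix(0, 1, 1), k = 2), 0.5)
  expect_equal(knn_scores(Xtr, ytr, matrix(0.1, 1, 1), k = 1), 1)
  # all-positive training set scores 1 for any query
  expect_equal(knn_scores(Xtr, c(1L, 1L, 1L), matrix(5, 1, 1), k = 3), 1)
  # identical duplicate with k = 1 returns that label (multi-feature)
  set.seed(3)
  X <- matrix(rnorm(40), 10, 4)
  y <- rep(c(1L, 0L), 5)
  expect_equal(knn_scores(X, y, X[4, , drop = FALSE], k = 1), y[4])
  expect_error(knn_scores(X, y, X[1, , drop = FALSE], k = 11), "exceeds")
  # scores live on the k-quantized grid
  s <- knn_scores(X, y, matrix(rnorm(12), 3, 4), k = 4)
  expect_true(all(s %in% ((0:4) / 4)))
})

test_that("knn scores agree with an exhaustive brute-force search", {
  # m = 2 is excluded: the Pearson correlation of 2-vectors is always +/-1,
  # so every distance is 0, 1 or 2 and neighbour order within the massive
  # ties is decided by last-ulp rounding noise, which differs between any
  # two numerically distinct implementations
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(6:15, 1); m <- sample(3:6, 1)
    X <- matrix(rnorm(n * m), n, m)
    y <- rbinom(n, 1, 0.5)
    x <- rnorm(m)
    k <- sample(1:4, 1)
    expect_equal(knn_scores(X, y, matrix(x, 1), k = k),
                 oracle_knn_score(X, y, x, k))
  }
})

test_that("large k drives the score toward the positive prevalence", {
  set.seed(6)
  X <- matrix(rnorm(200), 50, 4)
  y <- c(rep(1L, 20), rep(0L, 30))
  s <- knn_scores(X, y, matrix(rnorm(4), 1), k = 50)
  expect_equal(s, mean(y))
})

test_that("one-vs-rest assignment picks the max with declared-order ties", {
  expect_identical(ovr_assign(c(0.2, 0.9, 0.1, 0.3, 0.0)), "GG2_vs_rest")
  expect_identical(ovr_assign(rep(0.4, 5)), "GG1_vs_rest")
  expect_identical(ovr_assign(c(0.4, 0.4, 0.1, 0.6, 0.6)), "GG3_vs_rest")
  expect_error(ovr_assign(numeric(0)), "empty")
})

test_that("binarize treats the threshold boundary as positive", {
  expect_identical(binarize(c(0.6, 0.5, 0.4999)), c(1L, 1L, 0L))
  expect_error(binarize(0.5, threshold = 1.5), "threshold")
})

test_that("task labels implement the five one-vs-rest groupings", {
  gg <- c(1, 2, 3, 4, 5)
  expect_equal(task_labels("GG1_vs_rest", gg), c(1L, 0L, 0L, 0L, 0L))
  expect_equal(task_labels("GG12_vs_rest", gg), c(1L, 1L, 0L, 0L, 0L))
  expect_equal(task_labels("GG45_vs_rest", gg), c(0L, 0L, 0L, 1L, 1L))
  expect_identical(names(binary_tasks()),
                   c("GG1_vs_rest", "GG2_vs_rest", "GG12_vs_rest",
                     "GG3_vs_rest", "GG45_vs_rest"))
})
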