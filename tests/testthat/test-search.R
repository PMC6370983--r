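# Stratified CV, subset enumeration and the semi-exhaustive search.

test_that("stratified folds deal each class round-robin", {
  y <- c(rep(1L, 6), rep(0L, 44))
  f <- stratified_kfold(y, 3, seed = 7)
  for (k in 0:2) {
    expect_equal(sum(y == 1 & f$fold == k), 2L)
    expect_true(sum(y == 0 & f$fold == k) %in% 14:15)
  }
  y2 <- c(rep(1L, 9), rep(0L, 53))
  f2 <- stratified_kfold(y2, 3, seed = 1)
  expect_true(all(table(f2$fold[y2 == 1]) == 3L))
  # determinism and seed sensitivity
  expect_identical(stratified_kfold(y, 3, seed = 7)$fold, f$fold)
  expect_false(identical(stratified_kfold(y, 3, seed = 8)$fold, f$fold))
  expect_error(stratified_kfold(c(1L, 1L, rep(0L, 10)), 3, seed = 1), "class")
})

test_that("fold generation leaves the caller's RNG stream untouched", {
  set.seed(123)
  a <- rnorm(1)
  set.seed(123)
  invisible(stratified_kfold(rep(0:1, 10), 3, seed = 99))
  expect_identical(rnorm(1), a)
})

test_that("subset enumeration matches the closed-form binomial count", {
  subs <- enumerate_subsets(3, 1, 2)
  expect_identical(subs, list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L)))
  expect_equal(count_subsets(3, 1, 2), 6)
  expect_equal(length(enumerate_subsets(6, 2, 4)), count_subsets(6, 2, 4))
  expect_error(count_subsets(5, 3, 2), "min_size")
})

test_that("a label-equal feature is a perfect separator under k = 1", {
  set.seed(10)
  y <- rep(c(1L, 0L), 15)
  X <- cbind(as.numeric(y), matrix(rnorm(60), 30, 2))
  folds <- stratified_kfold(y, 3, seed = 3)
  res <- evaluate_subset(X, y, 1L, folds, knn_config(k = 1))
  expect_equal(res$mean_auc, 1)
  expect_equal(res$fold_auc, rep(1, 3))
})

test_that("pure-noise features yield null-centred CV AUC", {
  set.seed(77)
  aucs <- replicate(60, {
    y <- rep(c(1L, 0L), each = 15)
    X <- matrix(rnorm(60), 30, 2)
    folds <- stratified_kfold(y, 3, seed = sample.int(1e6, 1))
    evaluate_subset(X, y, c(1L, 2L), folds)$mean_auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("normalization and neighbours use training folds only (no leakage)", {
  set.seed(5)
  X <- matrix(rnorm(80), 20, 4)
  y <- rep(c(1L, 0L), 10)
  folds <- stratified_kfold(y, 3, seed = 2)
  views <- zonegrade:::fold_views(X, folds)
  for (v in views) {
    direct <- fit_normalization(X[v$train, , drop = FALSE])
    # fold-view normalization is exactly the train-only fit
    expect_equal(v$Xn, apply_normalization(X, direct))
    # perturbing test rows does not change the fitted parameters
    X2 <- X; X2[v$test, ] <- X2[v$test, ] * 100 + 3
    expect_equal(fit_normalization(X2[v$train, , drop = FALSE]), direct)
  }
})

test_that("search ranks by mean AUC with parsimony-then-lexicographic ties", {
  set.seed(30)
  y <- rep(c(1L, 0L), 12)
  # feature 1 separates perfectly; 2 and 3 are noise
  X <- cbind(as.numeric(y) + rnorm(24, 0, 1e-6), matrix(rnorm(48), 24, 2))
  folds <- stratified_kfold(y, 3, seed = 4)
  res <- semi_exhaustive_search(X, y, folds, 1, 2, cfg = knn_config(k = 1),
                                top_n = 7, engine = "r")
  expect_equal(res$n_evaluated, count_subsets(3, 1, 2))
  expect_identical(res$ranked$subset[[1]], 1L)  # smallest subset wins ties
  expect_equal(res$ranked$mean_auc[1], 1)
  expect_true(all(diff(res$ranked$mean_auc) <= 0))
})

test_that("compiled and reference search engines produce identical rankings", {
  set.seed(60)
  n <- 40
  y <- rep(c(1L, 0L), n / 2)
  X <- matrix(rnorm(n * 6), n, 6) + 0.8 * as.numeric(y)
  folds <- stratified_kfold(y, 3, seed = 9)
  r_cpp <- semi_exhaustive_search(X, y, folds, 1, 3, top_n = 20, engine = "cpp")
  r_ref <- semi_exhaustive_search(X, y, folds, 1, 3, top_n = 20, engine = "r")
  expect_equal(r_cpp$ranked$subset_indices, r_ref$ranked$subset_indices)
  expect_equal(r_cpp$ranked$mean_auc, r_ref$ranked$mean_auc, tolerance = 1e-14)
  # determinism of repeated runs
  r_cpp2 <- semi_exhaustive_search(X, y, folds, 1, 3, top_n = 20, engine = "cpp")
  expect_identical(r_cpp$ranked$mean_auc, r_cpp2$ranked$mean_auc)
})

test_that("zone analysis groups TZ with AFS and carries task prevalences", {
  spec <- synthetic_cohort_spec(seed = 13)
  feats <- cohort_features(generate_cohort(spec, size = 21), G = 32)
  cfg <- list(max_size = 1, top_n = 3, seed = 5,
              feature_pool = c(26L, 27L, 13L))
  pz <- run_zone_analysis(feats, "PZ", cfg)
  tz <- run_zone_analysis(feats, "TZAFS", cfg)
  expect_equal(pz$n_lesions, 50L)
  expect_equal(tz$n_lesions, 62L)
  expect_equal(pz$summary$n_pos[pz$summary$task == "GG45_vs_rest"], 6L)
  expect_equal(tz$summary$n_pos[tz$summary$task == "GG45_vs_rest"], 9L)
  expect_identical(nrow(pz$summary), 5L)
  expect_error(run_zone_analysis(feats[feats$zone == "PZ", ], "TZAFS", cfg),
               "no lesions")
})
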