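# Synthetic cohort generator: determinism, calibration, separability.

test_that("fragments are deterministic and honour the texture spec", {
  sp <- class_texture_spec(2, 120, 15, correlation_length = 1.5)
  f1 <- generate_fragment(sp, seed = 101)
  f2 <- generate_fragment(sp, seed = 101)
  expect_identical(f1$pixels, f2$pixels)
  expect_false(identical(f1$pixels,
                         generate_fragment(sp, seed = 102)$pixels))
  expect_identical(dim(f1$pixels), c(61L, 61L))
  # standardized field: mean and sd exact by construction
  expect_equal(mean(f1$pixels), 120, tolerance = 1e-9)
  expect_equal(sqrt(mean((f1$pixels - 120)^2)), 15, tolerance = 1e-9)
})

test_that("zero correlation length gives i.i.d. pixels (lag-1 autocorrelation ~ 0)", {
  sp <- class_texture_spec(1, 0, 1, correlation_length = 0)
  acs <- vapply(1:100, function(s) {
    px <- generate_fragment(sp, seed = 5000 + s)$pixels
    a <- as.vector(px[, -61]); b <- as.vector(px[, -1])
    stats::cor(a, b)
  }, 0)
  expect_lt(abs(mean(acs)), 0.05)
})

test_that("a central blob raises the fragment mean", {
  base <- class_texture_spec(1, 100, 20)
  blob <- class_texture_spec(1, 100, 20, blob_contrast = 100, blob_radius = 10)
  f0 <- generate_fragment(base, seed = 7)
  f1 <- generate_fragment(blob, seed = 7)
  expect_gt(mean(f1$pixels), mean(f0$pixels))
  # blob is confined to the centre
  expect_identical(f1$pixels[1, 1], f0$pixels[1, 1])
})

test_that("cohorts reproduce the zonal class imbalance deterministically", {
  cohort <- generate_cohort(synthetic_cohort_spec(seed = 11), size = 13)
  expect_equal(nrow(cohort$records), 112L)
  expect_equal(sum(cohort$records$zone == "PZ"), 50L)
  expect_equal(sum(cohort$records$zone %in% c("TZ", "AFS")), 62L)
  tab <- table(cohort$records$zone == "PZ", cohort$records$gg)
  expect_equal(unname(tab["TRUE", ]), c(14, 21, 9, 3, 3))
  expect_equal(unname(tab["FALSE", ]), c(22, 20, 11, 5, 4))
  expect_true(all(cohort$records$modality[cohort$records$zone == "PZ"] == "DWI_B800"))
  expect_true(all(cohort$records$modality[cohort$records$zone != "PZ"] == "T2W"))
  # same master seed -> identical cohort; small custom counts respected
  c2 <- generate_cohort(synthetic_cohort_spec(seed = 11), size = 13)
  expect_identical(cohort$fragments[[40]]$pixels, c2$fragments[[40]]$pixels)
  tiny <- generate_cohort(synthetic_cohort_spec(
    counts = data.frame(zone = "PZ", gg = 1L, n = 3L), seed = 2))
  expect_equal(nrow(tiny$records), 3L)
})

test_that("null cohorts share one texture spec across all grade groups", {
  sp <- synthetic_cohort_spec(seed = 3)
  nc <- null_cohort(sp, size = 13)
  specs <- nc$spec$class_specs
  for (g in 2:5) {
    expect_equal(specs[[g]]$mean_intensity, specs[[1]]$mean_intensity)
    expect_equal(specs[[g]]$correlation_length, specs[[1]]$correlation_length)
  }
  expect_equal(nrow(nc$records), 112L)
})

test_that("larger planted mean shifts never reduce the median recovered AUC", {
  counts <- subset(study_cohort_counts(), zone == "PZ")
  med_auc <- vapply(c(0, 1, 2), function(eff) {
    aucs <- vapply(1:20, function(s) {
      ch <- generate_cohort(planted_cohort_spec(effect_sd = eff,
                                                counts = counts,
                                                seed = 4000 + s), size = 9)
      X <- matrix(vapply(ch$fragments, function(f) mean(f$pixels), 0), ncol = 1)
      y <- task_labels("GG12_vs_rest", ch$records$gg)
      folds <- stratified_kfold(y, 3, seed = s)
      evaluate_subset(X, y, 1L, folds)$mean_auc
    }, 0)
    stats::median(aucs)
  }, 0)
  expect_true(all(diff(med_auc) >= 0))
  expect_lt(abs(med_auc[1] - 0.5), 0.15)  # null case sits near chance
})

test_that("texture-only class differences are separable by texture features", {
  # equal means and SDs; only the correlation length differs between the
  # GG1+2 and GG3-5 groups
  counts <- subset(study_cohort_counts(), zone == "PZ")
  sp <- planted_cohort_spec(effect_sd = 0, texture_ratio = 3,
                            counts = counts, seed = 91)
  ch <- generate_cohort(sp)
  y <- task_labels("GG12_vs_rest", ch$records$gg)
  feats <- cohort_features(ch)
  folds <- stratified_kfold(y, 3, seed = 8)
  texture_idx <- 1:25
  best <- max(vapply(texture_idx, function(j) {
    evaluate_subset(as.matrix(feats[, feature_names()]), y, j, folds)$mean_auc
  }, 0))
  expect_gte(best, 0.8)
  # and the fragment means stay uninformative
  Xm <- matrix(vapply(ch$fragments, function(f) mean(f$pixels), 0), ncol = 1)
  expect_lt(evaluate_subset(Xm, y, 1L, folds)$mean_auc, 0.75)
})
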