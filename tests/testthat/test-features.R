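# Quantization, run-length / Haralick / histogram features and the
# 38-feature panel.

test_that("quantize performs uniform min-max binning with endpoint convention", {
  expect_true(all(quantize(matrix(7, 5, 5), G = 8)$levels == 1L))
  q <- quantize(matrix(c(0, 0.5, 1, 1), 2, 2), G = 4)
  expect_identical(sort(unique(as.vector(q$levels))), c(1L, 3L, 4L))  # 0.5 -> floor(2)+1 = 3
  q2 <- quantize(matrix(c(-3, 9, -3, 9), 2, 2), G = 128)
  expect_identical(sort(unique(as.vector(q2$levels))), c(1L, 128L))
  expect_error(quantize(matrix(1:4, 2, 2), G = 1), "G")
})

test_that("histogram features match their definitions and percentile convention", {
  x <- matrix(c(1, 2, 3, 4), 2, 2)
  h <- histogram_features(x, quantize(x, 4))
  expect_equal(h[["hist_mean"]], 2.5)
  expect_equal(h[["hist_median"]], 2.5)
  expect_equal(h[["hist_min"]], 1)
  expect_equal(h[["hist_max"]], 4)
  expect_equal(h[["hist_p10"]], 1.3)  # linear interpolation h = (n-1)p + 1
  expect_equal(h[["hist_variance"]], mean((c(1, 2, 3, 4) - 2.5)^2))
  # two-value toy: population variance 1
  h2 <- histogram_features(matrix(c(0, 2), 1, 2))
  expect_equal(h2[["hist_variance"]], 1)
  # uniform quantized histogram -> energy 1/G
  u <- matrix(rep(c(0, 1, 2, 3), each = 4), 4, 4)
  expect_equal(histogram_features(u, quantize(u, 4))[["hist_energy"]], 1 / 4)
  # constant fragment conventions
  hc <- histogram_features(matrix(5, 3, 3))
  expect_equal(hc[["hist_variance"]], 0)
  expect_equal(hc[["hist_skewness"]], 0)
  expect_equal(hc[["hist_kurtosis"]], 0)
})

test_that("histogram moments and percentiles agree with brute-force oracles", {
  set.seed(31)
  for (rep in 1:10) {
    x <- matrix(rnorm(64, 10, 4), 8, 8)
    h <- histogram_features(x, quantize(x, 4))
    v <- as.numeric(x)
    m2 <- mean((v - mean(v))^2); m3 <- mean((v - mean(v))^3)
    expect_equal(h[["hist_skewness"]], m3 / m2^1.5, tolerance = 1e-12)
    for (p in c(0.10, 0.20, 0.30, 0.40, 0.75)) {
      expect_equal(h[[sprintf("hist_p%d", round(100 * p))]],
                   oracle_percentile(v, p), tolerance = 1e-12)
    }
    # monotone percentiles
    ps <- h[c("hist_p10", "hist_p20", "hist_p30", "hist_p40", "hist_p75")]
    expect_true(all(diff(ps) >= 0))
  }
})

test_that("co-occurrence matrices are normalized pair counts", {
  # constant fragment: single entry
  P <- cooccurrence(quantize(matrix(2, 4, 4), 4), c(0, 1))
  expect_equal(P[1, 1], 1)
  expect_equal(sum(P), 1)
  # two horizontal pairs on a 2x2: all mass at (1,2)
  q <- quantize(rbind(c(0, 1), c(0, 1)), 2)
  P2 <- cooccurrence(q, c(0, 1))
  expect_equal(P2[1, 2], 1)
  expect_equal(sum(P2 != 0), 1L)
  # opposite offsets transpose
  set.seed(4)
  q3 <- quantize(matrix(rnorm(49), 7, 7), 4)
  expect_equal(cooccurrence(q3, c(0, 1)), t(cooccurrence(q3, c(0, -1))))
  expect_equal(cooccurrence(q3, c(-1, 0)), t(cooccurrence(q3, c(1, 0))))
  expect_true(all(cooccurrence(q3, c(0, 1)) >= 0))
  expect_error(cooccurrence(quantize(matrix(1:3, 1, 3), 2), c(1, 0)),
               "degenerate")
})

test_that("Haralick features honour degenerate conventions and hand-derived cases", {
  hc <- haralick_features(quantize(matrix(1, 8, 8), 4))
  expect_equal(hc[["haralick_asm"]], 1)
  expect_equal(hc[["haralick_contrast"]], 0)
  expect_equal(hc[["haralick_entropy"]], 0)
  expect_equal(hc[["haralick_idm"]], 1)
  expect_equal(hc[["haralick_correlation"]], 0)
  expect_equal(hc[["haralick_mcc"]], 0)
  # alternating column stripes: every horizontal pair differs by exactly one
  # level (contrast 1 for both horizontal offsets), vertical pairs are equal
  # (contrast 0), so the four-direction mean is 0.5
  stripes <- matrix(rep(c(0, 1), 4), 4, 8, byrow = TRUE)
  hs <- haralick_features(quantize(stripes, 2))
  expect_equal(hs[["haralick_contrast"]], 0.5)
})

test_that("run-length matrices count maximal runs", {
  q <- quantize(matrix(0, 4, 4), 4)
  R <- run_length_matrix(q, c(0, 1))
  expect_equal(R[1, 4], 4L)
  expect_equal(sum(R), 4L)
  # alternating rows: 16 runs of length 1
  alt <- quantize(matrix(rep(c(0, 1), 8), 4, 4, byrow = TRUE), 2)
  Ra <- run_length_matrix(alt, c(0, 1))
  expect_equal(sum(Ra[, 1]), 16L)
  expect_true(all(Ra[, -1] == 0L))
  # hand-enumerated mixed row [1,1,2,3] with constant remaining rows
  m <- rbind(c(0, 0, 1, 2), matrix(0, 3, 4))
  Rm <- run_length_matrix(quantize(m, 3), c(0, 1))
  expect_equal(Rm[1, 2], 1L)  # run (level 1, length 2)
  expect_equal(Rm[2, 1], 1L)
  expect_equal(Rm[3, 1], 1L)
  expect_equal(Rm[1, 4], 3L)  # three constant rows
  # opposite directions traverse the same undirected runs
  set.seed(9)
  qr <- quantize(matrix(rnorm(36), 6, 6), 3)
  expect_equal(run_length_matrix(qr, c(0, 1)), run_length_matrix(qr, c(0, -1)))
  # pixel conservation: sum_j j R(i,j) = n_p per direction
  expect_equal(sum(sweep(run_length_matrix(qr, c(1, 0)), 2,
                         seq_len(6), "*")), 36)
})

test_that("run-length features match hand-derived values and bounds", {
  g <- glrl_features(quantize(matrix(0, 4, 4), 4))
  expect_equal(g[["glrl_rp"]], 0.25)       # 4 runs / 16 pixels, every direction
  expect_equal(g[["glrl_lre"]], 16)        # (4 * 16) / 4
  # checkerboard: all runs length 1 in every direction
  cb <- quantize(outer(1:6, 1:6, function(i, j) (i + j) %% 2), 2)
  gc <- glrl_features(cb)
  expect_equal(gc[["glrl_sre"]], 1)
  expect_equal(gc[["glrl_rp"]], 1)
  # SRE <= 1 always
  set.seed(12)
  for (rep in 1:5) {
    qq <- quantize(matrix(rnorm(64), 8, 8), 4)
    expect_lte(glrl_features(qq)[["glrl_sre"]], 1)
  }
})

test_that("all 25 texture features agree with the brute-force oracle", {
  set.seed(77)
  for (rep in 1:5) {
    px <- matrix(rnorm(64), 8, 8)
    q <- quantize(px, 4)
    got <- c(glrl_features(q), haralick_features(q))
    expect_equal(unname(got), oracle_texture_features(px, 4), tolerance = 1e-8)
  }
})

test_that("extract_features returns the canonical finite 38-vector", {
  set.seed(21)
  fr <- roi_fragment(matrix(rnorm(61 * 61, 100, 15), 61, 61))
  fv <- extract_features(fr)
  expect_length(fv, 38L)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
  expect_identical(length(grep("^glrl_", names(fv))), 11L)
  expect_identical(length(grep("^haralick_", names(fv))), 14L)
  expect_identical(length(grep("^hist_", names(fv))), 13L)
  # determinism: bit-identical on repeat
  expect_identical(fv, extract_features(fr))
  # constant fragment: documented degenerate values, all finite
  cv <- extract_features(roi_fragment(matrix(3, 61, 61)))
  expect_true(all(is.finite(cv)))
  expect_equal(cv[["haralick_asm"]], 1)
  expect_equal(cv[["haralick_contrast"]], 0)
  expect_equal(cv[["hist_variance"]], 0)
})

test_that("texture features are invariant to positive affine intensity maps", {
  set.seed(55)
  px <- matrix(rnorm(61 * 61), 61, 61)
  f1 <- extract_features(roi_fragment(px))
  f2 <- extract_features(roi_fragment(2.5 * px + 40))
  texture <- c(grep("^glrl_", names(f1)), grep("^haralick_", names(f1)))
  expect_equal(f1[texture], f2[texture], tolerance = 1e-10)
  expect_equal(f1[["hist_energy"]], f2[["hist_energy"]], tolerance = 1e-10)
})
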