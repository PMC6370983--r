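# The 38-feature radiomics panel: 11 Galloway gray-level run-length
# statistics, 14 Haralick co-occurrence statistics, 13 first-order histogram
# statistics. Texture features use 128 gray levels (per-ROI min-max uniform
# quantization) and are averaged over the four directions 0, 90, 180, 270
# degrees; histogram statistics (except energy) use the raw intensities.

# Direction offsets in (drow, dcol): 0 deg = +col, 90 = -row, 180 = -col,
# 270 = +row. 0/180 and 90/270 give transposed co-occurrence matrices and
# identical run-length matrices; all four are computed and averaged, taking
# the stated direction set literally.
DIRECTION_OFFSETS <- list(
  `0`   = c(0L,  1L),
  `90`  = c(-1L, 0L),
  `180` = c(0L, -1L),
  `270` = c(1L,  0L)
)

GLRL_NAMES <- paste0("glrl_", c(
  "sre", "lre", "gln", "rln", "rp",
  "lglre", "hglre", "srlgle", "srhgle", "lrlgle", "lrhgle"))
HARALICK_NAMES <- paste0("haralick_", c(
  "asm", "contrast", "correlation", "variance", "idm",
  "sum_average", "sum_variance", "sum_entropy", "entropy",
  "difference_variance", "difference_entropy", "imc1", "imc2", "mcc"))
HIST_NAMES <- paste0("hist_", c(
  "mean", "variance", "skewness", "kurtosis", "energy",
  "min", "max", "median", "p10", "p20", "p30", "p40", "p75"))

#' Canonical names of the 38-feature panel
#'
#' Ordered as: 11 run-length features, 14 Haralick features, 13 histogram
#' features. This ordering is stable and is the 1-based indexing used by
#' subset search results.
#'
#' @return Character vector of length 38.
#' @export
feature_names <- function() c(GLRL_NAMES, HARALICK_NAMES, HIST_NAMES)

as_pixels <- function(roi) {
  if (inherits(roi, "roi_fragment")) roi$pixels else as.matrix(roi)
}

#' Quantize a fragment to G gray levels
#'
#' Uniform binning of `[min, max]` into `G` equal-width bins: a value `v`
#' maps to `floor(G * (v - min) / (max - min)) + 1`, with the maximum mapping
#' to level `G`. A constant fragment maps everywhere to level 1.
#'
#' @param roi a [roi_fragment()] or numeric matrix.
#' @param G number of gray levels (>= 2), default 128.
#' @return An object of class `quantized_roi` with fields `levels`
#'   (integer matrix in 1..G) and `G`.
#' @export
quantize <- function(roi, G = 128L) {
  px <- as_pixels(roi)
  G <- as.integer(G)
  if (G < 2L) stop_named("quantize: G must be >= 2")
  lo <- min(px); hi <- max(px)
  if (hi == lo) {
    lev <- matrix(1L, nrow(px), ncol(px))
  } else {
    lev <- floor(G * (px - lo) / (hi - lo)) + 1
    lev[lev > G] <- G
    storage.mode(lev) <- "integer"
  }
  structure(list(levels = lev, G = G), class = "quantized_roi")
}

#' Gray-level co-occurrence matrix for one direction offset
#'
#' `P(i, j)` is the fraction of in-bounds pixel pairs `(a, a + offset)` with
#' level i at `a` and level j at `a + offset`. Single-offset, non-symmetric,
#' normalized to sum 1.
#'
#' @param q a [quantize()]d ROI.
#' @param offset length-2 integer `c(drow, dcol)`, one of the four direction
#'   offsets.
#' @return `G x G` numeric matrix summing to 1.
#' @export
cooccurrence <- function(q, offset) {
  stopifnot(inherits(q, "quantized_roi"), length(offset) == 2L)
  L <- q$levels; G <- q$G
  dr <- as.integer(offset[1]); dc <- as.integer(offset[2])
  nr <- nrow(L); nc <- ncol(L)
  rows <- seq_len(nr); cols <- seq_len(nc)
  rows <- rows[rows + dr >= 1L & rows + dr <= nr]
  cols <- cols[cols + dc >= 1L & cols + dc <= nc]
  if (length(rows) == 0L || length(cols) == 0L) {
    stop_named("cooccurrence: grid is degenerate along offset (%d, %d)", dr, dc)
  }
  a <- L[rows, cols, drop = FALSE]
  b <- L[rows + dr, cols + dc, drop = FALSE]
  counts <- tabulate(a + (b - 1L) * G, nbins = G * G)
  matrix(counts / sum(counts), G, G)
}

#' Gray-level run-length matrix for one direction
#'
#' `R(i, j)` counts maximal runs of `j` consecutive pixels at level `i`
#' along the direction's scan lines (rows for horizontal offsets, columns
#' for vertical ones). Opposite directions traverse the same undirected
#' runs and so yield identical matrices.
#'
#' @param q a [quantize()]d ROI.
#' @param direction length-2 integer offset, one of the four directions.
#' @return `G x Lmax` integer count matrix, `Lmax` = scan-line length.
#' @export
run_length_matrix <- function(q, direction) {
  stopifnot(inherits(q, "quantized_roi"), length(direction) == 2L)
  L <- q$levels; G <- q$G
  horizontal <- direction[1] == 0L
  lines <- if (horizontal) {
    lapply(seq_len(nrow(L)), function(r) L[r, ])
  } else {
    lapply(seq_len(ncol(L)), function(cc) L[, cc])
  }
  if (direction[1] < 0L || direction[2] < 0L) lines <- lapply(lines, rev)
  lmax <- length(lines[[1]])
  vals <- integer(0); lens <- integer(0)
  for (ln in lines) {
    r <- rle(as.integer(ln))
    vals <- c(vals, r$values)
    lens <- c(lens, r$lengths)
  }
  counts <- tabulate(vals + (lens - 1L) * G, nbins = G * lmax)
  matrix(as.integer(counts), G, lmax)
}

glrl_features_one <- function(R, n_pixels) {
  n_runs <- sum(R)
  G <- nrow(R); Lmax <- ncol(R)
  i <- seq_len(G); j <- seq_len(Lmax)
  ri <- rowSums(R)          # runs per gray level
  rj <- colSums(R)          # runs per run length
  inv_i2 <- 1 / i^2; inv_j2 <- 1 / j^2
  c(
    glrl_sre    = sum(rj * inv_j2) / n_runs,
    glrl_lre    = sum(rj * j^2) / n_runs,
    glrl_gln    = sum(ri^2) / n_runs,
    glrl_rln    = sum(rj^2) / n_runs,
    glrl_rp     = n_runs / n_pixels,
    glrl_lglre  = sum(ri * inv_i2) / n_runs,
    glrl_hglre  = sum(ri * i^2) / n_runs,
    glrl_srlgle = sum(R * (inv_i2 %o% inv_j2)) / n_runs,
    glrl_srhgle = sum(R * (i^2 %o% inv_j2)) / n_runs,
    glrl_lrlgle = sum(R * (inv_i2 %o% j^2)) / n_runs,
    glrl_lrhgle = sum(R * (i^2 %o% j^2)) / n_runs
  )
}

#' The 11 Galloway run-length features
#'
#' Short/Long Run Emphasis, Gray Level and Run Length Nonuniformity, Run
#' Percentage (denominator = pixel count), Low/High Gray Level Run Emphasis
#' and the four joint short/long x low/high emphases, computed per direction
#' and averaged over the four directions.
#'
#' @param q a [quantize()]d ROI.
#' @return Named numeric vector of length 11.
#' @export
glrl_features <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  n_pixels <- length(q$levels)
  acc <- 0
  for (off in DIRECTION_OFFSETS) {
    acc <- acc + glrl_features_one(run_length_matrix(q, off), n_pixels)
  }
  acc / length(DIRECTION_OFFSETS)
}

xlogx <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log(p[pos])
  out
}

haralick_one <- function(P, pre) {
  G <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  i <- seq_len(G)
  mu_x <- sum(i * px); mu_y <- sum(i * py)
  sd_x <- sqrt(sum((i - mu_x)^2 * px))
  sd_y <- sqrt(sum((i - mu_y)^2 * py))

  asm <- sum(P^2)
  contrast <- sum(pre$D2 * P)
  correlation <- if (sd_x > 0 && sd_y > 0) {
    (sum(pre$IJ * P) - mu_x * mu_y) / (sd_x * sd_y)
  } else 0
  variance <- sum((pre$I - mu_x)^2 * P)
  idm <- sum(P / (1 + pre$D2))

  # p_{x+y}(k), k = 2..2G and p_{x-y}(d), d = 0..G-1
  psum <- as.vector(rowsum(as.vector(P), group = pre$sum_grp))
  ks <- 2:(2 * G)
  pdiff <- as.vector(rowsum(as.vector(P), group = pre$diff_grp))
  ds <- 0:(G - 1)

  sum_average <- sum(ks * psum)
  sum_variance <- sum((ks - sum_average)^2 * psum)
  sum_entropy <- -sum(xlogx(psum))
  entropy <- -sum(xlogx(P))
  diff_mean <- sum(ds * pdiff)
  difference_variance <- sum((ds - diff_mean)^2 * pdiff)
  difference_entropy <- -sum(xlogx(pdiff))

  hx <- -sum(xlogx(px)); hy <- -sum(xlogx(py))
  pxpy <- px %o% py
  hxy1 <- -sum(P[pxpy > 0] * log(pxpy[pxpy > 0]))
  hxy2 <- -sum(xlogx(pxpy))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - entropy))))

  # MCC: sqrt of second-largest eigenvalue of
  # Q(i,j) = sum_k p(i,k) p(j,k) / (p_x(i) p_y(k)), restricted to levels
  # with nonzero marginals.
  keep_r <- which(px > 0); keep_c <- which(py > 0)
  mcc <- 0
  if (length(keep_r) >= 2L && length(keep_c) >= 2L) {
    Pk <- P[keep_r, keep_c, drop = FALSE]
    A <- Pk / px[keep_r]                       # p(i,k)/px(i)
    B <- sweep(Pk, 2, py[keep_c], "/")         # p(j,k)/py(k)
    Q <- A %*% t(B)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(ev) >= 2L) mcc <- sqrt(pmax(0, ev[2]))
  }

  c(haralick_asm = asm, haralick_contrast = contrast,
    haralick_correlation = correlation, haralick_variance = variance,
    haralick_idm = idm, haralick_sum_average = sum_average,
    haralick_sum_variance = sum_variance, haralick_sum_entropy = sum_entropy,
    haralick_entropy = entropy,
    haralick_difference_variance = difference_variance,
    haralick_difference_entropy = difference_entropy,
    haralick_imc1 = imc1, haralick_imc2 = imc2, haralick_mcc = mcc)
}

haralick_precompute <- function(G) {
  I <- matrix(seq_len(G), G, G)
  J <- t(I)
  list(I = I, IJ = I * J, D2 = (I - J)^2,
       sum_grp = as.vector(I + J), diff_grp = as.vector(abs(I - J)))
}

#' The 14 Haralick co-occurrence features
#'
#' Angular Second Moment, Contrast, Correlation, Variance, Inverse Difference
#' Moment, Sum Average/Variance/Entropy, Entropy, Difference
#' Variance/Entropy, the two Information Measures of Correlation, and the
#' Maximal Correlation Coefficient — computed on each of the four
#' single-offset co-occurrence matrices and averaged. Natural logarithms,
#' `0 log 0 := 0`; for a degenerate single-level matrix the correlation-type
#' features and MCC are defined as 0.
#'
#' @param q a [quantize()]d ROI.
#' @return Named numeric vector of length 14.
#' @export
haralick_features <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  pre <- haralick_precompute(q$G)
  acc <- 0
  for (off in DIRECTION_OFFSETS) {
    acc <- acc + haralick_one(cooccurrence(q, off), pre)
  }
  acc / length(DIRECTION_OFFSETS)
}

#' The 13 first-order histogram features
#'
#' Mean, population variance, moment skewness `m3 / m2^(3/2)`, (non-excess)
#' kurtosis `m4 / m2^2`, histogram energy `sum(p_i^2)` over the G-level
#' quantized histogram, min, max, median, and the 10/20/30/40/75th
#' percentiles with linear interpolation. All except energy are computed on
#' the raw (pre-quantization) intensities. Skewness and kurtosis of a
#' constant fragment are defined as 0.
#'
#' @param roi a [roi_fragment()] or numeric matrix of raw intensities.
#' @param q the matching [quantize()]d ROI (for the energy term). If `NULL`
#'   it is computed with `G = 128`.
#' @return Named numeric vector of length 13.
#' @export
histogram_features <- function(roi, q = NULL) {
  x <- as.numeric(as_pixels(roi))
  if (length(x) == 0L) stop_named("histogram_features: empty fragment")
  if (is.null(q)) q <- quantize(roi)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 else 0
  p <- tabulate(q$levels, nbins = q$G) / length(q$levels)
  qs <- stats::quantile(x, c(0.10, 0.20, 0.30, 0.40, 0.75), type = 7,
                        names = FALSE)
  c(hist_mean = m, hist_variance = m2, hist_skewness = skew,
    hist_kurtosis = kurt, hist_energy = sum(p^2),
    hist_min = min(x), hist_max = max(x),
    hist_median = stats::median(x),
    hist_p10 = qs[1], hist_p20 = qs[2], hist_p30 = qs[3],
    hist_p40 = qs[4], hist_p75 = qs[5])
}

#' Extract the full 38-feature panel from one fragment
#'
#' Concatenates the 11 run-length, 14 Haralick and 13 histogram features in
#' the canonical order of [feature_names()]. Deterministic, always finite.
#'
#' @param roi a [roi_fragment()] or numeric matrix.
#' @param G number of gray levels for quantization (default 128).
#' @return Named numeric vector of length 38.
#' @export
extract_features <- function(roi, G = 128L) {
  q <- quantize(roi, G)
  out <- c(glrl_features(q), haralick_features(q), histogram_features(roi, q))
  stopifnot(length(out) == 38L, all(is.finite(out)))
  names(out) <- feature_names()
  out
}

#' Feature table for a whole cohort
#'
#' One row per lesion: `patient_id, lesion_id, zone, gg` followed by the 38
#' canonical feature columns.
#'
#' @param cohort a cohort list with `records` and `fragments` (e.g. from
#'   [generate_cohort()] or [read_cohort_png()]).
#' @param G gray levels for quantization.
#' @return A data.frame with 4 + 38 columns.
#' @export
cohort_features <- function(cohort, G = 128L) {
  rec <- cohort$records
  mat <- t(vapply(cohort$fragments, extract_features, numeric(38), G = G))
  cbind(rec[, c("patient_id", "lesion_id", "zone", "gg")],
        as.data.frame(mat))
}
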