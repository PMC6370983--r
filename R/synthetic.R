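# Synthetic cohorts of 61x61 lesion fragments with controllable
# class-dependent intensity and texture structure.
#
# Texture model: Gaussian white noise smoothed by an isotropic Gaussian
# kernel of scale `correlation_length` (pixels) and re-standardized to mean
# 0, sd 1, then scaled by `sd_intensity` and shifted by the lesion mean,
# with an optional focal blob added around the fragment centre. Smoothing
# controls second-order (co-occurrence / run-length) structure without
# touching the first-order histogram location, so intensity and texture
# effects can be planted independently.

#' Per-class texture specification
#'
#' @param gg Grade Group label (1..5).
#' @param mean_intensity class mean intensity (arbitrary units).
#' @param sd_intensity within-fragment pixel standard deviation (> 0).
#' @param correlation_length Gaussian smoothing scale in pixels (>= 0;
#'   0 = i.i.d. pixel noise).
#' @param blob_contrast intensity added inside the central blob (default 0).
#' @param blob_radius blob radius in pixels.
#' @param between_lesion_sd standard deviation of the per-lesion mean around
#'   `mean_intensity` (the between-lesion biological variability; pooled
#'   within-class SD of the fragment-mean feature).
#' @param correlation_length_jitter log-scale SD of the per-lesion
#'   multiplicative jitter on `correlation_length`; texture estimated from
#'   3721 pixels is nearly noise-free, so without between-lesion texture
#'   variability any class difference in smoothness would separate
#'   perfectly.
#' @return A `class_texture_spec` list.
#' @export
class_texture_spec <- function(gg, mean_intensity, sd_intensity = 20,
                               correlation_length = 1, blob_contrast = 0,
                               blob_radius = 10,
                               between_lesion_sd = sd_intensity / 2,
                               correlation_length_jitter = 0.25) {
  if (sd_intensity <= 0) stop_named("class_texture_spec: sd_intensity must be > 0")
  if (correlation_length < 0) stop_named("class_texture_spec: correlation_length must be >= 0")
  structure(list(gg = as.integer(gg), mean_intensity = mean_intensity,
                 sd_intensity = sd_intensity,
                 correlation_length = correlation_length,
                 blob_contrast = blob_contrast, blob_radius = blob_radius,
                 between_lesion_sd = between_lesion_sd,
                 correlation_length_jitter = correlation_length_jitter),
            class = "class_texture_spec")
}

# Separable Gaussian smoothing with edge renormalization (kernel truncated
# at 3 sigma; weights beyond the grid are dropped and the remainder
# renormalized, so constants are preserved at the edges).
gaussian_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  h <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-h:h)^2) / (2 * sigma^2))
  smooth_lines <- function(m) {
    n <- nrow(m)
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - h):(i + h)
      ok <- j >= 1L & j <= n
      w <- kern[ok]
      W[i, j[ok]] <- w / sum(w)
    }
    W %*% m
  }
  out <- smooth_lines(mat)            # along rows (column direction)
  t(smooth_lines(t(out)))             # along columns
}

#' Generate one synthetic ROI fragment
#'
#' Deterministic given `(spec, seed)`: the fragment equals
#' `mean_intensity + sd_intensity * field + blob`, where `field` is smoothed
#' Gaussian white noise re-standardized to mean 0 and sd 1, and `blob` adds
#' `blob_contrast` within `blob_radius` pixels of the centre.
#'
#' @param spec a [class_texture_spec()].
#' @param seed integer seed.
#' @param size fragment side length (default 61).
#' @param modality modality tag for the fragment.
#' @return A [roi_fragment()].
#' @export
generate_fragment <- function(spec, seed, size = 61L, modality = "T2W") {
  stopifnot(inherits(spec, "class_texture_spec"))
  field <- with_seed(seed, matrix(stats::rnorm(size * size), size, size))
  field <- gaussian_smooth(field, spec$correlation_length)
  field <- (field - mean(field)) / sqrt(mean((field - mean(field))^2))
  px <- spec$mean_intensity + spec$sd_intensity * field
  if (spec$blob_contrast != 0) {
    ctr <- (size + 1) / 2
    rr <- matrix(seq_len(size), size, size)
    dist2 <- (rr - ctr)^2 + (t(rr) - ctr)^2
    px <- px + spec$blob_contrast * (dist2 <= spec$blob_radius^2)
  }
  roi_fragment(px, modality = modality)
}

#' Zonal Grade Group lesion counts of the study cohort
#'
#' PZ 14/21/9/3/3 and TZ+AFS 22/20/11/5/4 for GG1..GG5 (112 lesions in
#' total). The TZ+AFS counts are split deterministically into TZ and AFS
#' records (AFS lesions are graded like TZ lesions and always pooled with
#' them in the analysis).
#'
#' @return Data.frame with columns `zone`, `gg`, `n`.
#' @export
study_cohort_counts <- function() {
  rbind(
    data.frame(zone = "PZ", gg = 1:5, n = c(14L, 21L, 9L, 3L, 3L)),
    data.frame(zone = "TZ", gg = 1:5, n = c(17L, 15L, 8L, 4L, 3L)),
    data.frame(zone = "AFS", gg = 1:5, n = c(5L, 5L, 3L, 1L, 1L))
  )
}

#' Default per-class texture specifications
#'
#' The cohort-level conditions used throughout: class mean intensities
#' spaced one between-lesion SD apart per Grade Group step and a 15%
#' increase in spatial correlation length per step against a 25% per-lesion
#' texture jitter, so classes overlap on every feature axis — both
#' first-order and second-order features carry signal but none separates
#' perfectly, as in clinical cohorts.
#'
#' @return Named list of five [class_texture_spec()]s, `GG1`..`GG5`.
#' @export
default_class_specs <- function() {
  specs <- lapply(1:5, function(g) {
    class_texture_spec(
      gg = g,
      mean_intensity = 100 + 10 * (g - 1),
      sd_intensity = 20,
      correlation_length = 1.15^(g - 1),
      between_lesion_sd = 10
    )
  })
  names(specs) <- paste0("GG", 1:5)
  specs
}

#' Cohort specification
#'
#' @param counts data.frame `zone, gg, n` (default [study_cohort_counts()]).
#' @param class_specs named list `GG1`..`GG5` of [class_texture_spec()]s
#'   (default [default_class_specs()]); used for all zones.
#' @param seed master seed; all per-lesion seeds derive from it.
#' @return A `synthetic_cohort_spec` list.
#' @export
synthetic_cohort_spec <- function(counts = study_cohort_counts(),
                                  class_specs = default_class_specs(),
                                  seed = 17L) {
  if (any(counts$n < 0) || sum(counts$n) == 0) {
    stop_named("synthetic_cohort_spec: counts must be >= 0 with positive total")
  }
  structure(list(counts = counts, class_specs = class_specs,
                 seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

#' Generate a labeled synthetic cohort
#'
#' One fragment and lesion record per count entry. Per-lesion means are
#' drawn around the class mean with `between_lesion_sd`; per-lesion seeds
#' derive deterministically from the master seed, so the cohort is
#' reproducible and extensible. PZ fragments are tagged `DWI_B800`, TZ/AFS
#' fragments `T2W`.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param size fragment side length (default 61).
#' @return A `synthetic_cohort` list with `records` (data.frame) and
#'   `fragments` (list of [roi_fragment()]).
#' @export
generate_cohort <- function(spec = synthetic_cohort_spec(), size = 61L) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  counts <- spec$counts
  recs <- list(); frags <- list()
  idx <- 0L
  for (ci in seq_len(nrow(counts))) {
    zone <- counts$zone[ci]; gg <- counts$gg[ci]
    cls <- spec$class_specs[[paste0("GG", gg)]]
    modality <- if (zone == "PZ") "DWI_B800" else "T2W"
    for (r in seq_len(counts$n[ci])) {
      idx <- idx + 1L
      mean_seed <- derive_seed(spec$seed, 2L * idx)
      frag_seed <- derive_seed(spec$seed, 2L * idx + 1L)
      draw <- with_seed(mean_seed, c(
        stats::rnorm(1, cls$mean_intensity, cls$between_lesion_sd),
        stats::rnorm(1, 0, cls$correlation_length_jitter)))
      lesion_spec <- cls
      lesion_spec$mean_intensity <- draw[1]
      lesion_spec$correlation_length <- cls$correlation_length * exp(draw[2])
      pid <- sprintf("SYN-%03d", idx)
      lid <- paste0(pid, "-1")
      frag <- generate_fragment(lesion_spec, frag_seed, size = size,
                                modality = modality)
      frag$patient_id <- pid; frag$lesion_id <- lid
      frags[[idx]] <- frag
      recs[[idx]] <- data.frame(patient_id = pid, lesion_id = lid,
                                zone = zone, gg = gg, modality = modality,
                                seed = frag_seed, stringsAsFactors = FALSE)
    }
  }
  structure(list(records = do.call(rbind, recs), fragments = frags,
                 spec = spec), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d lesions (%d PZ, %d TZ+AFS)>\n",
              nrow(x$records), sum(x$records$zone == "PZ"),
              sum(x$records$zone != "PZ")))
  invisible(x)
}

#' Null cohort: identical texture spec for every Grade Group
#'
#' Labels carry no signal by construction; used for AUC null calibration.
#'
#' @param spec a [synthetic_cohort_spec()]; its `GG1` class spec is applied
#'   to all five groups.
#' @param size fragment side length.
#' @return A `synthetic_cohort`.
#' @export
null_cohort <- function(spec = synthetic_cohort_spec(), size = 61L) {
  base <- spec$class_specs[[1]]
  spec$class_specs <- stats::setNames(
    lapply(1:5, function(g) { s <- base; s$gg <- as.integer(g); s }),
    paste0("GG", 1:5))
  generate_cohort(spec, size = size)
}

#' Cohort spec with a planted class effect
#'
#' Shifts the class mean of the lesions NOT in `positive_groups` by
#' `effect_sd` pooled pixel-intensity SDs (the generator's noise scale,
#' `sd_intensity`) and (optionally) multiplies their correlation length by
#' `texture_ratio`, relative to a common base spec. With `effect_sd = 0`
#' and `texture_ratio = 1` this is the null spec.
#'
#' @param effect_sd mean shift in units of the pooled pixel-intensity SD.
#' @param positive_groups Grade Groups forming the unshifted class.
#' @param texture_ratio multiplier on the shifted groups' correlation
#'   length (texture effect; default 1 = none).
#' @param counts,seed as in [synthetic_cohort_spec()].
#' @return A `synthetic_cohort_spec`.
#' @export
planted_cohort_spec <- function(effect_sd = 2, positive_groups = c(1L, 2L),
                                texture_ratio = 1, counts = study_cohort_counts(),
                                seed = 17L) {
  base <- class_texture_spec(gg = 1L, mean_intensity = 100, sd_intensity = 20,
                             correlation_length = 1, between_lesion_sd = 10)
  specs <- lapply(1:5, function(g) {
    s <- base; s$gg <- as.integer(g)
    if (!g %in% positive_groups) {
      s$mean_intensity <- s$mean_intensity + effect_sd * s$sd_intensity
      s$correlation_length <- s$correlation_length * texture_ratio
    }
    s
  })
  names(specs) <- paste0("GG", 1:5)
  synthetic_cohort_spec(counts = counts, class_specs = specs, seed = seed)
}
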