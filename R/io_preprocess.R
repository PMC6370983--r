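# Image containers, readers and ROI preprocessing.
#
# All pixel grids are stored as base R matrices in (row, col) order with
# 0-based pixel indices at the interface; pixel (0,0) sits at the world
# coordinate `origin` (mm) and pixel centres are spaced `spacing` mm apart.

MODALITIES <- c("T2W", "DWI_B800")
ZONES <- c("PZ", "TZ", "AFS")

#' Construct a 2D grayscale image slice
#'
#' The basic raw-image container: a finite-valued pixel matrix plus the
#' physical in-plane pixel spacing (mm), the world coordinate of pixel
#' (0,0), and a modality tag (`"T2W"` or `"DWI_B800"`).
#'
#' @param pixels numeric matrix of finite intensities.
#' @param spacing length-2 positive numeric, mm per pixel in (row, col) order.
#'   A single value is recycled to both axes.
#' @param origin length-2 numeric, world mm coordinate of pixel (0,0).
#' @param modality `"T2W"` or `"DWI_B800"`.
#' @return An object of class `image_slice`.
#' @export
image_slice <- function(pixels, spacing, origin = c(0, 0), modality = "T2W") {
  pixels <- as.matrix(pixels)
  if (length(pixels) == 0L) stop_named("image_slice: empty pixel grid")
  if (!all(is.finite(pixels))) stop_named("image_slice: non-finite pixel values")
  spacing <- rep_len(as.numeric(spacing), 2L)
  if (any(spacing <= 0)) stop_named("image_slice: spacing must be positive")
  origin <- rep_len(as.numeric(origin), 2L)
  modality <- match.arg(modality, MODALITIES)
  structure(list(pixels = pixels, spacing = spacing, origin = origin,
                 modality = modality),
            class = "image_slice")
}

#' @export
print.image_slice <- function(x, ...) {
  cat(sprintf("<image_slice %dx%d px, %.3g x %.3g mm, %s>\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              x$modality))
  invisible(x)
}

#' Construct a lesion-centred ROI fragment
#'
#' @param pixels square numeric matrix of finite intensities (default
#'   expectation: 61 x 61).
#' @param modality `"T2W"` or `"DWI_B800"`.
#' @param patient_id,lesion_id identifiers linking the fragment to a lesion
#'   record.
#' @return An object of class `roi_fragment`.
#' @export
roi_fragment <- function(pixels, modality = "T2W", patient_id = NA_character_,
                         lesion_id = NA_character_) {
  pixels <- as.matrix(pixels)
  if (!all(is.finite(pixels))) stop_named("roi_fragment: non-finite pixel values")
  structure(list(pixels = pixels, modality = match.arg(modality, MODALITIES),
                 patient_id = patient_id, lesion_id = lesion_id),
            class = "roi_fragment")
}

#' @export
print.roi_fragment <- function(x, ...) {
  cat(sprintf("<roi_fragment %dx%d, %s, %s/%s>\n", nrow(x$pixels),
              ncol(x$pixels), x$modality, x$patient_id, x$lesion_id))
  invisible(x)
}

#' Convert a world (mm) coordinate to a 0-based pixel index
#'
#' Nearest-integer rounding (half away from zero); errors if the resulting
#' index falls outside the pixel grid.
#'
#' @param slice an [image_slice()].
#' @param point length-2 world coordinate in mm, (row, col) order.
#' @param label optional lesion label used in error messages.
#' @return Integer vector `c(row, col)`, 0-based.
#' @export
world_to_pixel <- function(slice, point, label = NULL) {
  stopifnot(inherits(slice, "image_slice"), length(point) == 2L)
  idx <- floor((as.numeric(point) - slice$origin) / slice$spacing + 0.5)
  dims <- dim(slice$pixels)
  if (any(idx < 0) || idx[1] >= dims[1] || idx[2] >= dims[2]) {
    stop_named("world_to_pixel: point (%g, %g) maps to pixel (%d, %d), outside the %d x %d grid%s",
               point[1], point[2], idx[1], idx[2], dims[1], dims[2],
               if (is.null(label)) "" else paste0(" [lesion ", label, "]"))
  }
  as.integer(idx)
}

#' Convert a 0-based pixel index to its world (mm) coordinate
#'
#' @inheritParams world_to_pixel
#' @param index length-2 0-based pixel index `c(row, col)`.
#' @export
pixel_to_world <- function(slice, index) {
  stopifnot(inherits(slice, "image_slice"), length(index) == 2L)
  slice$origin + as.numeric(index) * slice$spacing
}

#' Resample a slice to an isotropic in-plane spacing
#'
#' Bilinear interpolation onto a grid with the requested spacing covering the
#' same physical field of view (`new_dim = round(old_dim * old_spacing /
#' target)`); sample points beyond the last pixel centre are clamped to the
#' edge, so constant images resample exactly.
#'
#' @param slice an [image_slice()].
#' @param target_spacing positive mm-per-pixel for both axes (default 0.5,
#'   the working resolution of the pipeline).
#' @return A new [image_slice()] at the target spacing, same origin.
#' @export
resample_inplane <- function(slice, target_spacing = 0.5) {
  stopifnot(inherits(slice, "image_slice"))
  if (length(target_spacing) != 1L || !is.finite(target_spacing) ||
      target_spacing <= 0) {
    stop_named("resample_inplane: target_spacing must be a positive number")
  }
  px <- slice$pixels
  nr <- nrow(px); nc <- ncol(px)
  new_nr <- max(1L, as.integer(round(nr * slice$spacing[1] / target_spacing)))
  new_nc <- max(1L, as.integer(round(nc * slice$spacing[2] / target_spacing)))

  bil_axis <- function(n_new, sp_new, sp_old, n_old) {
    x <- (seq_len(n_new) - 1) * sp_new / sp_old
    x <- pmin(pmax(x, 0), n_old - 1)
    i0 <- pmin(floor(x), n_old - 1)
    list(i0 = as.integer(i0) + 1L,
         i1 = as.integer(pmin(i0 + 1, n_old - 1)) + 1L,
         f = x - i0)
  }
  rr <- bil_axis(new_nr, target_spacing, slice$spacing[1], nr)
  cc <- bil_axis(new_nc, target_spacing, slice$spacing[2], nc)
  wr <- rr$f; wc <- cc$f
  out <- ((1 - wr) %o% (1 - wc)) * px[rr$i0, cc$i0, drop = FALSE] +
         ((1 - wr) %o% wc)       * px[rr$i0, cc$i1, drop = FALSE] +
         (wr %o% (1 - wc))       * px[rr$i1, cc$i0, drop = FALSE] +
         (wr %o% wc)             * px[rr$i1, cc$i1, drop = FALSE]
  image_slice(out, spacing = c(target_spacing, target_spacing),
              origin = slice$origin, modality = slice$modality)
}

#' Z-score normalize a slice
#'
#' Centres and scales all pixels of the slice to mean 0, standard deviation 1
#' (population convention, denominator N). Used for T2W series to remove
#' inter-patient intensity variation; high-b-value DWI is left on its native
#' scale.
#'
#' @param slice an [image_slice()].
#' @return A normalized [image_slice()].
#' @export
zscore_normalize <- function(slice) {
  stopifnot(inherits(slice, "image_slice"))
  x <- slice$pixels
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) stop_named("zscore_normalize: constant image (sd = 0)")
  slice$pixels <- (x - m) / s
  slice
}

#' Extract a square lesion-centred ROI
#'
#' Returns the `size` x `size` window centred on the given 0-based pixel
#' index (offsets -(size-1)/2 ... +(size-1)/2 on each axis). If the window
#' leaves the grid the default is a hard error; with `pad = "replicate"`
#' out-of-grid pixels take the nearest edge value.
#'
#' @param slice an [image_slice()].
#' @param center length-2 0-based pixel index `c(row, col)`.
#' @param size odd window side length in pixels (default 61).
#' @param pad `"error"` (default) or `"replicate"`.
#' @param patient_id,lesion_id identifiers carried onto the fragment.
#' @return A [roi_fragment()].
#' @export
extract_roi <- function(slice, center, size = 61L, pad = c("error", "replicate"),
                        patient_id = NA_character_, lesion_id = NA_character_) {
  stopifnot(inherits(slice, "image_slice"), length(center) == 2L)
  pad <- match.arg(pad)
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) stop_named("extract_roi: size must be a positive odd integer")
  dims <- dim(slice$pixels)
  center <- as.integer(center)
  if (any(center < 0L) || center[1] >= dims[1] || center[2] >= dims[2]) {
    stop_named("extract_roi: center (%d, %d) outside the %d x %d grid [lesion %s/%s]",
               center[1], center[2], dims[1], dims[2], patient_id, lesion_id)
  }
  half <- (size - 1L) %/% 2L
  rows <- center[1] + (-half):half
  cols <- center[2] + (-half):half
  oob <- any(rows < 0L) || any(rows >= dims[1]) || any(cols < 0L) || any(cols >= dims[2])
  if (oob && pad == "error") {
    stop_named("extract_roi: %d x %d window at (%d, %d) exceeds the %d x %d grid [lesion %s/%s]; use pad = 'replicate' to allow edge lesions",
               size, size, center[1], center[2], dims[1], dims[2], patient_id, lesion_id)
  }
  rows <- pmin(pmax(rows, 0L), dims[1] - 1L)
  cols <- pmin(pmax(cols, 0L), dims[2] - 1L)
  roi_fragment(slice$pixels[rows + 1L, cols + 1L, drop = FALSE],
               modality = slice$modality,
               patient_id = patient_id, lesion_id = lesion_id)
}

#' Read a lesion-record table
#'
#' Expects a CSV with header
#' `patient_id,lesion_id,zone,center_row_mm,center_col_mm,slice_index,gg`;
#' zone values must be `PZ`, `TZ` or `AFS` and `gg` must lie in 1..5.
#'
#' @param path CSV file path.
#' @return A data.frame of validated lesion records.
#' @export
read_lesion_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "lesion_id", "zone", "center_row_mm",
            "center_col_mm", "slice_index", "gg")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_named("read_lesion_records: %s is missing column(s): %s", path,
               paste(miss, collapse = ", "))
  }
  bad_zone <- which(!df$zone %in% ZONES)
  if (length(bad_zone)) {
    stop_named("read_lesion_records: %s row %d has invalid zone '%s' (must be PZ, TZ or AFS)",
               path, bad_zone[1], df$zone[bad_zone[1]])
  }
  bad_gg <- which(!df$gg %in% 1:5)
  if (length(bad_gg)) {
    stop_named("read_lesion_records: %s row %d has invalid gg '%s' (must be 1..5)",
               path, bad_gg[1], df$gg[bad_gg[1]])
  }
  df$gg <- as.integer(df$gg)
  df
}

#' Read a grayscale image slice from a 16-bit PNG
#'
#' PNG carries no physical metadata, so spacing (and optionally an intensity
#' range to undo the 0..1 PNG scaling) must be supplied by the caller or a
#' sidecar config.
#'
#' @param path PNG file path.
#' @param spacing length-2 (or scalar) mm-per-pixel.
#' @param modality `"T2W"` or `"DWI_B800"`.
#' @param intensity_range optional `c(min, max)` mapped back from the PNG's
#'   0..1 range.
#' @param origin world coordinate of pixel (0,0).
#' @return An [image_slice()].
#' @export
read_image_png <- function(path, spacing, modality = "T2W",
                           intensity_range = NULL, origin = c(0, 0)) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  if (!is.null(intensity_range)) {
    img <- intensity_range[1] + img * diff(intensity_range)
  }
  image_slice(img, spacing = spacing, origin = origin, modality = modality)
}

#' Read one axial slice from a NIfTI volume
#'
#' @param path NIfTI file path.
#' @param slice_index 1-based index along the third axis (ignored for 2D
#'   images).
#' @param modality `"T2W"` or `"DWI_B800"`.
#' @return An [image_slice()]; spacing comes from the NIfTI `pixdim`.
#' @export
read_image_nifti <- function(path, slice_index = 1L, modality = "T2W") {
  vol <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(vol)
  arr <- as.array(vol)
  if (length(dim(arr)) >= 3L) {
    if (slice_index < 1L || slice_index > dim(arr)[3]) {
      stop_named("read_image_nifti: slice_index %d outside 1..%d in %s",
                 slice_index, dim(arr)[3], path)
    }
    arr <- arr[, , slice_index]
  }
  image_slice(arr, spacing = pd[1:2], origin = c(0, 0), modality = modality)
}

#' Write a synthetic cohort to disk as grayscale PNG fragments
#'
#' Fragments are stored at the PNG bit depth the writer supports (8 bit) and
#' share one global affine intensity map (stored in
#' `cohort.yaml`) so that between-lesion intensity differences survive the
#' PNG round trip; lesion records go to `records.csv`.
#'
#' @param cohort a cohort from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_png <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lo <- min(vapply(cohort$fragments, function(f) min(f$pixels), 0))
  hi <- max(vapply(cohort$fragments, function(f) max(f$pixels), 0))
  if (hi <= lo) hi <- lo + 1
  rec <- cohort$records
  rec$file <- sprintf("%s_%s.png", rec$patient_id, rec$lesion_id)
  for (i in seq_len(nrow(rec))) {
    img <- (cohort$fragments[[i]]$pixels - lo) / (hi - lo)
    png::writePNG(img, file.path(dir, rec$file[i]), dpi = NULL)
  }
  utils::write.csv(rec, file.path(dir, "records.csv"), row.names = FALSE)
  yaml::write_yaml(list(intensity_min = lo, intensity_max = hi,
                        n_lesions = nrow(rec)),
                   file.path(dir, "cohort.yaml"))
  invisible(dir)
}

#' Read a PNG cohort written by [write_cohort_png()]
#'
#' @param dir cohort directory.
#' @return A cohort list with `records` and `fragments`.
#' @export
read_cohort_png <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "cohort.yaml"))
  rec <- utils::read.csv(file.path(dir, "records.csv"), stringsAsFactors = FALSE)
  rng <- c(meta$intensity_min, meta$intensity_max)
  frags <- lapply(seq_len(nrow(rec)), function(i) {
    img <- png::readPNG(file.path(dir, rec$file[i]))
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    roi_fragment(rng[1] + img * diff(rng), modality = rec$modality[i],
                 patient_id = rec$patient_id[i], lesion_id = rec$lesion_id[i])
  })
  structure(list(records = rec, fragments = frags), class = "synthetic_cohort")
}
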