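# Minimal DICOM reader for the optional real-data path.
#
# Scope: single-frame uncompressed grayscale images, little-endian transfer
# syntaxes (implicit or explicit VR). This is deliberately narrow — enough to
# ingest one axial slice with its pixel spacing — and rejects anything else
# with a clear error. No installed R package parses DICOM, hence this
# hand-written reader.

dcm_u16 <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
dcm_u32 <- function(raw4) {
  as.numeric(raw4[1]) + 256 * as.numeric(raw4[2]) +
    65536 * as.numeric(raw4[3]) + 16777216 * as.numeric(raw4[4])
}

# VRs whose explicit-VR encoding uses a 2-byte reserved field + 4-byte length
DCM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

#' Read a single-frame grayscale DICOM image
#'
#' Supports uncompressed little-endian transfer syntaxes (implicit and
#' explicit VR), monochrome photometric interpretations, 8- or 16-bit
#' unsigned or signed pixel data. Pixel spacing comes from tag (0028,0030)
#' and the in-plane origin from (0020,0032) when present.
#'
#' @param path DICOM file path.
#' @param modality `"T2W"` or `"DWI_B800"` tag for the returned slice.
#' @return An [image_slice()].
#' @export
read_image_dicom <- function(path, modality = "T2W") {
  raw <- readBin(path, what = "raw", n = file.size(path))
  if (length(raw) < 140L) stop_named("read_image_dicom: %s is too short to be DICOM", path)
  pos <- 1L
  if (length(raw) >= 132L && rawToChar(raw[129:132]) == "DICM") pos <- 133L

  tags <- list()
  explicit <- TRUE
  n <- length(raw)
  while (pos + 8L <= n + 1L) {
    group <- dcm_u16(raw[pos:(pos + 1L)])
    elem  <- dcm_u16(raw[(pos + 2L):(pos + 3L)])
    pos <- pos + 4L
    in_meta <- group == 2L
    use_explicit <- explicit || in_meta  # file-meta group is always explicit
    if (use_explicit) {
      vr <- rawToChar(raw[pos:(pos + 1L)])
      if (grepl("^[A-Z]{2}$", vr)) {
        if (vr %in% DCM_LONG_VRS) {
          len <- dcm_u32(raw[(pos + 4L):(pos + 7L)])
          pos <- pos + 8L
        } else {
          len <- dcm_u16(raw[(pos + 2L):(pos + 3L)])
          pos <- pos + 4L
        }
      } else {  # implicit VR after all
        vr <- "UN"
        len <- dcm_u32(raw[pos:(pos + 3L)])
        pos <- pos + 4L
      }
    } else {
      vr <- "UN"
      len <- dcm_u32(raw[pos:(pos + 3L)])
      pos <- pos + 4L
    }
    if (len == 4294967295) stop_named("read_image_dicom: %s has undefined-length items (compressed or sequence pixel data not supported)", path)
    if (pos + len - 1L > n) stop_named("read_image_dicom: %s is truncated", path)
    val <- if (len > 0) raw[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + as.integer(len)
    key <- sprintf("%04x,%04x", group, elem)
    tags[[key]] <- val
    if (key == "0002,0010") {
      ts <- sub("\\s+$", "", rawToChar(val))
      ts <- gsub("\\0", "", ts)
      if (ts == "1.2.840.10008.1.2") {
        explicit <- FALSE
      } else if (!ts %in% c("1.2.840.10008.1.2.1", "1.2.840.10008.1.2.2")) {
        stop_named("read_image_dicom: %s transfer syntax %s not supported (uncompressed little-endian only)", path, ts)
      } else if (ts == "1.2.840.10008.1.2.2") {
        stop_named("read_image_dicom: %s is big-endian, not supported", path)
      }
    }
    if (key == "7fe0,0010") break  # pixel data is last element we need
  }

  need <- function(key, what) {
    if (is.null(tags[[key]])) stop_named("read_image_dicom: %s lacks %s (%s)", path, what, key)
    tags[[key]]
  }
  str_val <- function(raw) gsub("\\0|\\s+$", "", rawToChar(raw))
  rows <- dcm_u16(need("0028,0010", "Rows"))
  cols <- dcm_u16(need("0028,0011", "Columns"))
  bits <- dcm_u16(need("0028,0100", "BitsAllocated"))
  signed <- !is.null(tags[["0028,0103"]]) && dcm_u16(tags[["0028,0103"]]) == 1L
  nframes <- if (!is.null(tags[["0028,0008"]])) as.integer(str_val(tags[["0028,0008"]])) else 1L
  if (!is.na(nframes) && nframes > 1L) stop_named("read_image_dicom: %s is multi-frame, not supported", path)
  samples <- if (!is.null(tags[["0028,0002"]])) dcm_u16(tags[["0028,0002"]]) else 1L
  if (samples != 1L) stop_named("read_image_dicom: %s is not single-sample grayscale", path)
  if (!bits %in% c(8L, 16L)) stop_named("read_image_dicom: %s has unsupported BitsAllocated = %d", path, bits)

  spacing_str <- str_val(need("0028,0030", "PixelSpacing"))
  spacing <- as.numeric(strsplit(spacing_str, "\\\\")[[1]])  # row\col spacing, mm
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_named("read_image_dicom: %s has invalid PixelSpacing '%s'", path, spacing_str)
  }
  origin <- c(0, 0)
  if (!is.null(tags[["0020,0032"]])) {
    ipp <- as.numeric(strsplit(str_val(tags[["0020,0032"]]), "\\\\")[[1]])
    if (length(ipp) >= 2L && all(is.finite(ipp[1:2]))) origin <- c(ipp[2], ipp[1])
  }

  pix_raw <- need("7fe0,0010", "PixelData")
  npix <- rows * cols
  if (bits == 8L) {
    vals <- as.integer(pix_raw[seq_len(npix)])
    if (signed) vals <- ifelse(vals > 127L, vals - 256L, vals)
  } else {
    if (length(pix_raw) < 2L * npix) stop_named("read_image_dicom: %s pixel data shorter than Rows x Columns", path)
    vals <- readBin(pix_raw, what = "integer", n = npix, size = 2L,
                    signed = signed, endian = "little")
    if (!signed) vals <- vals  # readBin size=2 signed=FALSE returns 0..65535
  }
  # DICOM pixel data is row-major (first row left-to-right, then next row)
  px <- matrix(as.numeric(vals), nrow = rows, ncol = cols, byrow = TRUE)
  slope <- if (!is.null(tags[["0028,1053"]])) as.numeric(str_val(tags[["0028,1053"]])) else 1
  intercept <- if (!is.null(tags[["0028,1052"]])) as.numeric(str_val(tags[["0028,1052"]])) else 0
  if (is.finite(slope) && is.finite(intercept)) px <- px * slope + intercept
  image_slice(px, spacing = spacing, origin = origin, modality = modality)
}
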