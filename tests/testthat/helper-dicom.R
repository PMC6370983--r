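# Independent minimal DICOM writer used to exercise the package's reader.
# Writes a single-frame grayscale file in explicit or implicit VR little
# endian, byte by byte.

u16le <- function(x) as.raw(c(x %% 256, x %/% 256))
u32le <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                              (x %/% 65536) %% 256, (x %/% 16777216) %% 256))

dcm_elem <- function(group, elem, vr, value_raw, explicit) {
  len <- length(value_raw)
  if (len %% 2 == 1) {
    value_raw <- c(value_raw, if (vr %in% c("UI")) as.raw(0) else charToRaw(" "))
    len <- len + 1
  }
  head <- c(u16le(group), u16le(elem))
  if (explicit) {
    if (vr %in% c("OB", "OW", "SQ", "UT", "UN", "OF")) {
      c(head, charToRaw(vr), as.raw(c(0, 0)), u32le(len), value_raw)
    } else {
      c(head, charToRaw(vr), u16le(len), value_raw)
    }
  } else {
    c(head, u32le(len), value_raw)
  }
}

write_minimal_dicom <- function(path, pixels, spacing = c(0.5, 0.5),
                                explicit = TRUE, origin = NULL) {
  pixels <- round(pixels)
  stopifnot(all(pixels >= 0), all(pixels < 65536))
  ts <- if (explicit) "1.2.840.10008.1.2.1" else "1.2.840.10008.1.2"
  out <- c(raw(128), charToRaw("DICM"))
  # file meta group: always explicit VR
  out <- c(out, dcm_elem(2L, 0x0010, "UI", charToRaw(ts), explicit = TRUE))
  # dataset
  ds <- function(vals) charToRaw(paste(format(vals, trim = TRUE), collapse = "\\"))
  out <- c(out, dcm_elem(0x28, 0x0002, "US", u16le(1), explicit))
  out <- c(out, dcm_elem(0x28, 0x0010, "US", u16le(nrow(pixels)), explicit))
  out <- c(out, dcm_elem(0x28, 0x0011, "US", u16le(ncol(pixels)), explicit))
  out <- c(out, dcm_elem(0x28, 0x0030, "DS", ds(spacing), explicit))
  if (!is.null(origin)) {
    # ImagePositionPatient is x\y\z = (col, row, z) in mm
    out <- c(out, dcm_elem(0x20, 0x0032, "DS", ds(c(origin[2], origin[1], 0)),
                           explicit))
  }
  out <- c(out, dcm_elem(0x28, 0x0100, "US", u16le(16), explicit))
  out <- c(out, dcm_elem(0x28, 0x0103, "US", u16le(0), explicit))
  pix <- unlist(lapply(as.integer(t(pixels)), u16le))  # row-major
  out <- c(out, dcm_elem(0x7FE0, 0x0010, "OW", pix, explicit))
  writeBin(out, path)
  invisible(path)
}
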