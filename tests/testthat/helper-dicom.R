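# Builds minimal explicit-VR little-endian DICOM part-10 files so the
# series reader can be exercised without binary fixtures in the repo.

dcm_raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_element <- function(group, elem, vr, value) {
  v <- if (is.character(value)) {
    b <- charToRaw(value)
    pad <- if (vr == "UI") as.raw(0) else charToRaw(" ")
    if (length(b) %% 2 == 1) c(b, pad) else b
  } else if (vr == "US") {
    dcm_raw_u16(value)
  } else {
    value  # raw, pre-encoded (UL payloads, pixel data)
  }
  hdr <- c(dcm_raw_u16(group), dcm_raw_u16(elem))
  if (vr %in% c("OB", "OW")) {
    c(hdr, charToRaw(vr), as.raw(c(0, 0)), dcm_raw_u32(length(v)), v)
  } else {
    c(hdr, charToRaw(vr), dcm_raw_u16(length(v)), v)
  }
}

# writes one axial slice; stored int16 pixel matrix `stored` is [x, y]
write_test_dicom <- function(path, stored, pixel_spacing = c(1, 1),
                             ipp = c(0, 0, 0), slope = 1, intercept = -1024,
                             series_uid = "1.2.3.4", omit_rescale = FALSE) {
  stored <- as.matrix(stored)
  pix <- writeBin(as.integer(stored), raw(), size = 2, endian = "little")
  meta <- dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  meta <- c(dcm_element(0x0002, 0x0000, "UL", dcm_raw_u32(length(meta))),
            meta)
  ds <- c(
    dcm_element(0x0020, 0x000E, "UI", series_uid),
    dcm_element(0x0020, 0x0032, "DS",
                paste(sprintf("%g", ipp), collapse = "\\")),
    dcm_element(0x0028, 0x0010, "US", ncol(stored)),      # Rows (y)
    dcm_element(0x0028, 0x0011, "US", nrow(stored)),      # Columns (x)
    dcm_element(0x0028, 0x0030, "DS",                     # row\col spacing
                paste(sprintf("%g", rev(pixel_spacing)), collapse = "\\")),
    dcm_element(0x0028, 0x0100, "US", 16),                # BitsAllocated
    dcm_element(0x0028, 0x0103, "US", 1)                  # signed
  )
  if (!omit_rescale) {
    ds <- c(ds,
            dcm_element(0x0028, 0x1052, "DS", sprintf("%g", intercept)),
            dcm_element(0x0028, 0x1053, "DS", sprintf("%g", slope)))
  }
  ds <- c(ds, dcm_element(0x7FE0, 0x0010, "OW", pix))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}
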