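# Minimal DICOM series reader (read-only; no DICOM package in this stack).
# Supports Part-10 files with explicit or implicit VR little endian
# transfer syntax, uncompressed 16-bit monochrome pixel data.  Enough for
# scanner exports of axial CT series; anything fancier should be converted
# to NIfTI upstream.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"

dcm_u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}
dcm_u32 <- function(raw, pos) {
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1L]) +
    65536 * as.numeric(raw[pos + 2L]) + 16777216 * as.numeric(raw[pos + 3L])
}
dcm_str <- function(raw) {
  sub(" +$", "", rawToChar(raw[raw != as.raw(0)]))
}
dcm_ds <- function(raw) {
  as.numeric(strsplit(dcm_str(raw), "\\\\")[[1L]])
}

# VRs that use the 12-byte (reserved + 32-bit length) explicit layout
VR_LONG <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# parse one file into a named list of the tags we need
read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    nc_stop(paste0("not a DICOM part-10 file: ", path), "neckct_format_error")

  tags <- list()
  pos <- 133L
  n <- length(raw)
  explicit <- TRUE        # file meta group is always explicit VR
  ts <- NULL
  meta_end <- Inf

  while (pos + 7L <= n) {
    group <- dcm_u16(raw, pos)
    elem  <- dcm_u16(raw, pos + 2L)
    if (group != 2L && is.null(ts)) {
      # leaving the meta group: switch per transfer syntax
      ts <- tags[["00020010"]] %||% UID_EXPLICIT_LE
      ts <- dcm_str(ts)
      if (ts == UID_IMPLICIT_LE) explicit <- FALSE
      else if (ts != UID_EXPLICIT_LE)
        nc_stop(paste0("unsupported transfer syntax ", ts, " in ", path),
                "neckct_format_error")
    }
    if (explicit || group == 2L) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% VR_LONG) {
        len <- dcm_u32(raw, pos + 8L)
        dstart <- pos + 12L
      } else {
        len <- dcm_u16(raw, pos + 6L)
        dstart <- pos + 8L
      }
    } else {
      len <- dcm_u32(raw, pos + 4L)
      dstart <- pos + 8L
    }
    if (len == 4294967295)  # undefined length (sequences) unsupported
      nc_stop(paste0("undefined-length element in ", path),
              "neckct_format_error")
    key <- sprintf("%04X%04X", group, elem)
    if (len > 0 && dstart + len - 1L <= n)
      tags[[key]] <- raw[dstart:(dstart + len - 1L)]
    else if (len == 0)
      tags[[key]] <- raw(0)
    pos <- dstart + len
  }
  tags
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  nc_assert(length(files) > 0, paste0("empty DICOM directory: ", dir),
            "neckct_input_error")

  slices <- lapply(files, read_dicom_file)

  uid_of <- function(tg) dcm_str(tg[["0020000E"]] %||% raw(0))
  uids <- vapply(slices, uid_of, "")
  if (length(unique(uids)) != 1L)
    nc_stop("directory mixes multiple DICOM series", "neckct_format_error")

  need <- function(tg, key, what) {
    v <- tg[[key]]
    if (is.null(v))
      nc_stop(paste0("DICOM tag ", key, " (", what, ") missing"),
              if (grepl("rescale", what)) "neckct_calibration_error"
              else "neckct_format_error")
    v
  }

  first <- slices[[1L]]
  rows <- dcm_u16(need(first, "00280010", "Rows"), 1L)
  cols <- dcm_u16(need(first, "00280011", "Columns"), 1L)
  ps <- dcm_ds(need(first, "00280030", "PixelSpacing"))  # row (y), col (x)
  bits <- dcm_u16(need(first, "00280100", "BitsAllocated"), 1L)
  nc_assert(bits == 16L, "only 16-bit DICOM pixel data supported",
            "neckct_format_error")
  pixrep <- dcm_u16(first[["00280103"]] %||% as.raw(c(1, 0)), 1L)

  zpos <- vapply(slices, function(tg)
    dcm_ds(need(tg, "00200032", "ImagePositionPatient"))[3L], 0)
  ord <- order(zpos)          # increasing z = cranial
  slices <- slices[ord]
  zpos <- zpos[ord]

  dz <- if (length(zpos) > 1L) median(diff(zpos)) else {
    st <- slices[[1L]][["00180050"]]
    if (is.null(st)) 1 else dcm_ds(st)[1L]
  }
  nc_assert(dz > 0, "non-increasing DICOM slice positions",
            "neckct_format_error")

  vox <- array(0, dim = c(cols, rows, length(slices)))
  for (k in seq_along(slices)) {
    tg <- slices[[k]]
    slope <- dcm_ds(need(tg, "00281053", "rescale slope"))[1L]
    inter <- dcm_ds(need(tg, "00281052", "rescale intercept"))[1L]
    pix <- need(tg, "7FE00010", "PixelData")
    stored <- readBin(pix, "integer", n = rows * cols, size = 2L,
                      signed = (pixrep == 1L), endian = "little")
    nc_assert(length(stored) == rows * cols,
              "DICOM pixel data length mismatch", "neckct_format_error")
    # pixel data is row-major from the top row: index (x, y) = (col, row)
    vox[, , k] <- matrix(slope * stored + inter, nrow = cols, ncol = rows)
  }

  ipp1 <- dcm_ds(need(slices[[1L]], "00200032", "ImagePositionPatient"))
  ct_volume(vox, spacing = c(ps[2L], ps[1L], dz),
            origin = c(ipp1[1L], ipp1[2L], zpos[1L]))
}
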