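# Minimal NIfTI-1 reader/writer (no NIfTI package exists in this stack).
# Supports single-file .nii / .nii.gz, little- or big-endian headers on
# read, axis-aligned geometry, datatypes uint8/int16/int32/float32/float64
# (+ int8/uint16 on read).  Scale slope/intercept are applied on read;
# files are written unscaled so calibration is idempotent.

NIFTI_DT <- list(
  uint8   = list(code = 2L,   bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,   bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,   bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L,  bitpix = 32L, what = "numeric", size = 4L, signed = TRUE),
  float64 = list(code = 64L,  bitpix = 64L, what = "numeric", size = 8L, signed = TRUE),
  int8    = list(code = 256L, bitpix = 8L,  what = "integer", size = 1L, signed = TRUE),
  uint16  = list(code = 512L, bitpix = 16L, what = "integer", size = 2L, signed = FALSE)
)

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

write_nifti <- function(data, path, spacing, origin = c(0, 0, 0),
                        datatype = c("float32", "uint8", "int16", "float64")) {
  datatype <- match.arg(datatype)
  dt <- NIFTI_DT[[datatype]]
  dims <- dim(data)
  nc_assert(length(dims) == 3L, "write_nifti expects a 3-D array")

  con <- tryCatch(nifti_open(path, "wb"), error = function(e)
    nc_stop(paste0("cannot open for writing: ", path), "neckct_io_error"))
  on.exit(close(con), add = TRUE)

  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wpad <- function(n) writeBin(raw(n), con)

  wi(348L, 4L)                         # sizeof_hdr
  wpad(36L)                            # data_type, db_name, extents, ...
  wi(c(3L, dims, 1L, 1L, 1L, 1L), 2L)  # dim[8]
  wf(c(0, 0, 0))                       # intent_p1..p3
  wi(0L, 2L)                           # intent_code
  wi(dt$code, 2L)                      # datatype
  wi(dt$bitpix, 2L)                    # bitpix
  wi(0L, 2L)                           # slice_start
  wf(c(1, spacing, 0, 0, 0, 0))        # pixdim[8] (qfac = 1)
  wf(352)                              # vox_offset
  wf(1); wf(0)                         # scl_slope, scl_inter
  wi(0L, 2L); wpad(1L)                 # slice_end, slice_code
  writeBin(as.raw(2L), con)            # xyzt_units: mm
  wf(c(0, 0, 0, 0))                    # cal_max/min, slice_duration, toffset
  wi(c(0L, 0L), 4L)                    # glmax, glmin
  wpad(104L)                           # descrip, aux_file
  wi(0L, 2L)                           # qform_code
  wi(1L, 2L)                           # sform_code
  wf(c(0, 0, 0))                       # quatern b, c, d
  wf(c(0, 0, 0))                       # qoffset x, y, z
  wf(c(spacing[1], 0, 0, origin[1]))   # srow_x
  wf(c(0, spacing[2], 0, origin[2]))   # srow_y
  wf(c(0, 0, spacing[3], origin[3]))   # srow_z
  wpad(16L)                            # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  wpad(4L)                             # no extensions

  vals <- as.vector(data)
  if (dt$what == "integer") {
    writeBin(as.integer(round(vals)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

read_nifti <- function(path) {
  con <- tryCatch(nifti_open(path, "rb"), error = function(e)
    nc_stop(paste0("cannot open: ", path), "neckct_io_error"))
  on.exit(close(con), add = TRUE)

  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L)
    nc_stop(paste0("truncated NIfTI header: ", path), "neckct_format_error")

  parse_hdr <- function(endian) {
    hc <- rawConnection(hdr)
    on.exit(close(hc), add = TRUE)
    ri <- function(n, size) readBin(hc, "integer", n = n, size = size, endian = endian)
    rf <- function(n) readBin(hc, "numeric", n = n, size = 4L, endian = endian)
    skip <- function(n) readBin(hc, "raw", n = n)
    h <- list()
    h$sizeof_hdr <- ri(1L, 4L); skip(36L)
    h$dim <- ri(8L, 2L); skip(14L)
    h$datatype <- ri(1L, 2L); h$bitpix <- ri(1L, 2L); skip(2L)
    h$pixdim <- rf(8L)
    h$vox_offset <- rf(1L)
    h$scl_slope <- rf(1L); h$scl_inter <- rf(1L)
    skip(20L)   # slice_end..toffset
    skip(8L)    # glmax, glmin
    skip(104L)
    h$qform_code <- ri(1L, 2L); h$sform_code <- ri(1L, 2L)
    skip(12L)
    h$qoffset <- rf(3L)
    h$srow <- matrix(rf(12L), nrow = 3L, byrow = TRUE)
    skip(16L)
    h$magic <- rawToChar(readBin(hc, "raw", n = 3L))
    h
  }

  h <- parse_hdr("little")
  endian <- "little"
  if (h$sizeof_hdr != 348L) {
    h <- parse_hdr("big")
    endian <- "big"
    if (h$sizeof_hdr != 348L)
      nc_stop(paste0("not a NIfTI-1 file: ", path), "neckct_format_error")
  }
  if (!h$magic %in% c("n+1", "ni1"))
    nc_stop(paste0("bad NIfTI magic in: ", path), "neckct_format_error")
  ndim <- h$dim[1]
  nc_assert(ndim >= 3L && ndim <= 4L && all(h$dim[5:8] <= 1L),
            "only 3-D NIfTI volumes are supported",
            "neckct_format_error")
  dims <- h$dim[2:4]

  dtrow <- Filter(function(d) d$code == h$datatype, NIFTI_DT)
  if (length(dtrow) == 0L)
    nc_stop(sprintf("unsupported NIfTI datatype code %d", h$datatype),
            "neckct_format_error")
  dt <- dtrow[[1L]]

  nskip <- h$vox_offset - 348
  if (nskip > 0) readBin(con, "raw", n = nskip)
  n <- prod(dims)
  vals <- readBin(con, dt$what, n = n, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < n)
    nc_stop(paste0("truncated NIfTI data: ", path), "neckct_format_error")
  vals <- as.numeric(vals)
  if (is.finite(h$scl_slope) && h$scl_slope != 0 &&
      !(h$scl_slope == 1 && h$scl_inter == 0)) {
    vals <- vals * h$scl_slope + h$scl_inter
  }

  spacing <- abs(h$pixdim[2:4])
  origin <- c(0, 0, 0)
  if (h$sform_code > 0L) {
    diag_s <- abs(c(h$srow[1, 1], h$srow[2, 2], h$srow[3, 3]))
    off_diag <- h$srow[, 1:3]; diag(off_diag) <- 0
    if (all(abs(off_diag) < 1e-6) && all(diag_s > 0)) {
      spacing <- diag_s
      origin <- h$srow[, 4]
    }
  } else if (h$qform_code > 0L) {
    origin <- h$qoffset
  }
  nc_assert(all(spacing > 0), "non-positive voxel spacing in NIfTI header",
            "neckct_format_error")

  list(data = array(vals, dim = dims), spacing = spacing, origin = origin)
}
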