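#' CT volume container
#'
#' A `ct_volume` holds a 3-D grid of Hounsfield units (HU) on a regular
#' anisotropic lattice.  Axis 3 is cranio-caudal with increasing index =
#' cranial; axes 1 and 2 are in-plane (left-right, antero-posterior).
#' The physical center of voxel `(i, j, k)` (1-based) is
#' `origin + (c(i, j, k) - 1) * spacing`, all in mm.
#'
#' @param voxels numeric 3-D array of HU values (finite).
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param origin numeric length-3, physical position (mm) of voxel (1,1,1).
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  nc_assert(is.array(voxels) && length(dim(voxels)) == 3L,
            "voxels must be a 3-D array")
  nc_assert(all(dim(voxels) >= 1L), "grid needs >= 1 voxel per axis")
  nc_assert(is.numeric(spacing) && length(spacing) == 3L && all(spacing > 0),
            "spacing must be 3 positive numbers (mm)")
  nc_assert(all(is.finite(voxels)), "HU values must be finite")
  nc_assert(is.numeric(origin) && length(origin) == 3L && all(is.finite(origin)),
            "origin must be 3 finite numbers (mm)")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' Binary mask on a CT grid
#'
#' Voxel-aligned boolean mask sharing the grid (shape, spacing, origin) of
#' the `ct_volume` it was derived from.
#'
#' @param voxels logical 3-D array.
#' @param spacing,origin grid geometry in mm, as in [ct_volume()].
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing, origin = c(0, 0, 0)) {
  nc_assert(is.array(voxels) && length(dim(voxels)) == 3L && is.logical(voxels),
            "voxels must be a logical 3-D array")
  nc_assert(!anyNA(voxels), "mask may not contain NA")
  nc_assert(is.numeric(spacing) && length(spacing) == 3L && all(spacing > 0),
            "spacing must be 3 positive numbers (mm)")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "binary_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm; HU range [", round(min(x$voxels)), ", ", round(max(x$voxels)),
      "]\n", sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$voxels), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm; ", sum(x$voxels), " true\n", sep = "")
  invisible(x)
}

# physical centers of the axial slices (mm, cranial = increasing)
slice_centers_z <- function(x) {
  x$origin[3] + (seq_len(dim(x$voxels)[3]) - 1) * x$spacing[3]
}

axis_centers <- function(x, axis) {
  x$origin[axis] + (seq_len(dim(x$voxels)[axis]) - 1) * x$spacing[axis]
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Load a CT volume
#'
#' Reads a NIfTI-1 file (`.nii` / `.nii.gz`) or a DICOM series directory
#' into a [ct_volume()].  DICOM stored values are calibrated to HU via the
#' rescale slope/intercept tags; NIfTI scale slope/intercept are applied
#' once on load (re-saving and re-loading applies no second rescale).
#' Axis 3 of the result is cranio-caudal with increasing index = cranial.
#'
#' @param path file path (NIfTI) or directory path (DICOM series).
#' @param format `"auto"` (default, by path type/extension), `"nifti"`, or
#'   `"dicom_series"`.
#' @return a [ct_volume()].
#' @export
load_volume <- function(path, format = c("auto", "nifti", "dicom_series")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom_series" else "nifti"
  }
  if (format == "nifti") {
    nc_assert(file.exists(path) && !dir.exists(path),
              paste0("no such NIfTI file: ", path))
    nif <- read_nifti(path)
    ct_volume(nif$data, nif$spacing, nif$origin)
  } else {
    nc_assert(dir.exists(path), paste0("no such DICOM directory: ", path))
    read_dicom_series(path)
  }
}

#' Save a CT volume as NIfTI-1
#'
#' @param volume a [ct_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param datatype on-disk datatype; the `float32` default is exact for
#'   integer-valued HU (CT scanners store integers), `float64` is exact
#'   for arbitrary values.
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path,
                        datatype = c("float32", "float64", "int16")) {
  nc_assert(inherits(volume, "ct_volume"), "not a ct_volume")
  write_nifti(volume$voxels, path, spacing = volume$spacing,
              origin = volume$origin, datatype = match.arg(datatype))
  invisible(path)
}

#' Save / load a binary mask as NIfTI-1
#'
#' Masks are stored as uint8 0/1 volumes; the save-then-load round trip is
#' voxel-wise and metadata identical.
#'
#' @param mask a [binary_mask()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path` invisibly (`save_mask`); a [binary_mask()] (`load_mask`).
#' @export
save_mask <- function(mask, path) {
  nc_assert(inherits(mask, "binary_mask"), "not a binary_mask")
  write_nifti(mask$voxels + 0L, path, spacing = mask$spacing,
              origin = mask$origin, datatype = "uint8")
  invisible(path)
}

#' @rdname save_mask
#' @export
load_mask <- function(path) {
  nc_assert(file.exists(path), paste0("no such mask file: ", path))
  nif <- read_nifti(path)
  binary_mask(nif$data > 0.5, nif$spacing, nif$origin)
}

#' Axial slab selection
#'
#' Selects the axial slices whose physical centers fall inside the closed
#' interval `[center_z - thickness/2, center_z + thickness/2]`, the slab
#' used for thick-slice cross-sectional area measurement (default 5 mm).
#'
#' @param volume a [ct_volume()].
#' @param center_z physical slab center (mm).
#' @param thickness slab thickness (mm, > 0); default 5.
#' @return an object of class `axial_slab` with fields `center_z`,
#'   `thickness` and `slice_indices` (1-based).
#' @export
slab_at <- function(volume, center_z, thickness = 5) {
  nc_assert(inherits(volume, "ct_volume"), "not a ct_volume")
  nc_assert(is.numeric(thickness) && thickness > 0, "thickness must be > 0")
  zc <- slice_centers_z(volume)
  lo <- center_z - thickness / 2
  hi <- center_z + thickness / 2
  idx <- which(zc >= lo & zc <= hi)
  if (length(idx) == 0L)
    nc_stop(sprintf("slab [%.2f, %.2f] mm contains no slice center", lo, hi),
            "neckct_empty_slab_error")
  structure(list(center_z = center_z, thickness = thickness,
                 slice_indices = idx),
            class = "axial_slab")
}
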