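# Tissue definitions: adipose voxels are those whose HU falls in a closed
# window (default [-150, -30], center -90) inside the anatomic crop box
# (orbit roof to sternal angle cranio-caudally, mid-clavicular interspace
# laterally); the airway is the seeded 26-connected air component between
# the hard-palate and first-tracheal-ring levels; the per-slice body
# contour is the largest 8-connected soft-tissue component with its
# interior holes filled (so the air lumen counts toward neck area and
# disconnected satellites such as ear cartilage are dropped).

#' Adipose Hounsfield window
#'
#' The closed HU interval identifying adipose voxels.  The default
#' \[-150, -30\] has center -90 HU, the standard CT fat band.
#'
#' @param low,high window bounds in HU, `low < high`.
#' @return an object of class `hu_window` with fields `low`, `high`,
#'   `center` (the midpoint).
#' @export
hu_window <- function(low = -150, high = -30) {
  nc_assert(is.numeric(low) && is.numeric(high) && low < high,
            "need low < high")
  structure(list(low = low, high = high, center = (low + high) / 2),
            class = "hu_window")
}

LANDMARK_FIELDS <- c("z_orbit_roof", "z_sternal_angle",
                     "x_left_midclavicle", "x_right_midclavicle",
                     "z_hard_palate", "z_first_tracheal_ring",
                     "z_soft_palate_tip", "z_thyroid_cartilage")

#' Anatomic landmark set
#'
#' Physical positions (mm) of the anatomic margins: the cranio-caudal
#' crop runs from the orbit roof down to the sternal angle, the lateral
#' crop between the mid-clavicular bounds; the airway is clipped between
#' the hard palate and the first tracheal ring; cross-sectional areas are
#' read at the soft-palate tip (upper) and thyroid-cartilage (lower)
#' levels.  Cranial = increasing z.
#'
#' @param z_orbit_roof,z_sternal_angle cranial and caudal crop bounds (mm),
#'   `z_orbit_roof > z_sternal_angle`.
#' @param x_left_midclavicle,x_right_midclavicle lateral crop bounds (mm),
#'   left > right.
#' @param z_hard_palate,z_first_tracheal_ring airway clip bounds (mm),
#'   hard palate cranial.
#' @param z_soft_palate_tip,z_thyroid_cartilage NCSA levels (mm), both
#'   inside the crop.
#' @param airway_seed length-3 physical point (mm) inside the air lumen.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(z_orbit_roof, z_sternal_angle,
                         x_left_midclavicle, x_right_midclavicle,
                         z_hard_palate, z_first_tracheal_ring,
                         z_soft_palate_tip, z_thyroid_cartilage,
                         airway_seed) {
  lm <- list(z_orbit_roof = z_orbit_roof, z_sternal_angle = z_sternal_angle,
             x_left_midclavicle = x_left_midclavicle,
             x_right_midclavicle = x_right_midclavicle,
             z_hard_palate = z_hard_palate,
             z_first_tracheal_ring = z_first_tracheal_ring,
             z_soft_palate_tip = z_soft_palate_tip,
             z_thyroid_cartilage = z_thyroid_cartilage,
             airway_seed = as.numeric(airway_seed))
  nc_assert(all(vapply(lm[LANDMARK_FIELDS], function(v)
    is.numeric(v) && length(v) == 1 && is.finite(v), TRUE)),
    "landmark levels must be single finite numbers", "neckct_landmark_error")
  nc_assert(length(lm$airway_seed) == 3 && all(is.finite(lm$airway_seed)),
            "airway_seed must be a length-3 point", "neckct_landmark_error")
  nc_assert(lm$z_orbit_roof > lm$z_sternal_angle,
            "orbit roof must be cranial to the sternal angle",
            "neckct_landmark_error")
  nc_assert(lm$z_hard_palate > lm$z_first_tracheal_ring,
            "hard palate must be cranial to the first tracheal ring",
            "neckct_landmark_error")
  nc_assert(lm$x_left_midclavicle > lm$x_right_midclavicle,
            "lateral bounds out of order", "neckct_landmark_error")
  in_crop <- function(z) z >= lm$z_sternal_angle & z <= lm$z_orbit_roof
  nc_assert(in_crop(lm$z_soft_palate_tip) && in_crop(lm$z_thyroid_cartilage),
            "NCSA levels must lie inside the crop", "neckct_landmark_error")
  structure(lm, class = "landmark_set")
}

#' Read / write a landmark set as JSON
#'
#' The JSON schema uses physical mm coordinates with keys named exactly
#' as the [landmark_set()] fields.
#'
#' @param path JSON file path.
#' @param landmarks a [landmark_set()].
#' @return a [landmark_set()] (`read_landmarks`); `path` invisibly
#'   (`write_landmarks`).
#' @export
read_landmarks <- function(path) {
  nc_assert(file.exists(path), paste0("no such landmark file: ", path),
            "neckct_input_error")
  js <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                 error = function(e)
                   nc_stop(paste0("malformed landmark JSON: ",
                                  conditionMessage(e)),
                           "neckct_schema_error"))
  missing <- setdiff(c(LANDMARK_FIELDS, "airway_seed"), names(js))
  if (length(missing))
    nc_stop(paste0("landmark JSON missing key(s): ",
                   paste(missing, collapse = ", ")),
            "neckct_schema_error")
  do.call(landmark_set, js[c(LANDMARK_FIELDS, "airway_seed")])
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path) {
  nc_assert(inherits(landmarks, "landmark_set"), "not a landmark_set")
  jsonlite::write_json(unclass(landmarks), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# nearest voxel index of a physical point (1-based); NULL if outside grid
point_to_index <- function(volume, pt) {
  idx <- round((pt - volume$origin) / volume$spacing) + 1
  dims <- dim(volume$voxels)
  if (any(idx < 1) || any(idx > dims)) return(NULL)
  as.integer(idx)
}

#' Adipose tissue mask by HU windowing inside the anatomic crop
#'
#' A voxel is adipose iff its HU lies in the closed window and its center
#' lies inside the crop box: z between the sternal angle and the orbit
#' roof (inclusive), x between the mid-clavicular bounds (inclusive).
#'
#' @param volume a [ct_volume()].
#' @param window a [hu_window()]; default \[-150, -30\].
#' @param landmarks a [landmark_set()].
#' @return a [binary_mask()].
#' @export
fat_mask <- function(volume, window = hu_window(), landmarks) {
  nc_assert(inherits(volume, "ct_volume"), "not a ct_volume")
  nc_assert(inherits(window, "hu_window"), "not a hu_window")
  nc_assert(inherits(landmarks, "landmark_set"), "not a landmark_set")
  xc <- axis_centers(volume, 1)
  zc <- slice_centers_z(volume)
  x_ok <- xc >= landmarks$x_right_midclavicle &
    xc <= landmarks$x_left_midclavicle
  z_ok <- zc >= landmarks$z_sternal_angle & zc <= landmarks$z_orbit_roof
  if (!any(x_ok) || !any(z_ok))
    nc_stop("crop box contains no voxel centers", "neckct_landmark_error")
  m <- volume$voxels >= window$low & volume$voxels <= window$high
  m[!x_ok, , ] <- FALSE
  m[, , !z_ok] <- FALSE
  binary_mask(m, volume$spacing, volume$origin)
}

#' Airway mask by seeded connected-component growth
#'
#' The airway is the 26-connected component of `{HU <= air_threshold}`
#' containing the landmark air seed, restricted to the slices between the
#' first tracheal ring and the hard palate (inclusive of slice centers at
#' the bounds).  Ambient air not connected to the seed within that clip is
#' excluded.
#'
#' @param volume a [ct_volume()].
#' @param landmarks a [landmark_set()]; `airway_seed` must fall on an
#'   air-dense voxel.
#' @param air_threshold HU below which a voxel counts as air
#'   (default -500, far from both the -1000 HU lumen and any soft tissue).
#' @return a [binary_mask()].
#' @export
airway_mask <- function(volume, landmarks, air_threshold = -500) {
  nc_assert(inherits(volume, "ct_volume"), "not a ct_volume")
  nc_assert(inherits(landmarks, "landmark_set"), "not a landmark_set")
  zc <- slice_centers_z(volume)
  kz <- which(zc >= landmarks$z_first_tracheal_ring &
                zc <= landmarks$z_hard_palate)
  if (length(kz) == 0L)
    nc_stop("airway clip interval contains no slices",
            "neckct_landmark_error")

  idx <- point_to_index(volume, landmarks$airway_seed)
  if (is.null(idx) || !(idx[3] %in% kz))
    nc_stop("airway seed lies outside the clipped volume",
            "neckct_seed_error")
  if (volume$voxels[idx[1], idx[2], idx[3]] > air_threshold)
    nc_stop(sprintf("airway seed voxel has HU %.0f > threshold %.0f",
                    volume$voxels[idx[1], idx[2], idx[3]], air_threshold),
            "neckct_seed_error")

  sub <- volume$voxels[, , kz, drop = FALSE] <= air_threshold
  dims <- dim(sub)
  k_local <- match(idx[3], kz)
  seed_lin <- (k_local - 1) * dims[1] * dims[2] +
    (idx[2] - 1) * dims[1] + (idx[1] - 1)
  comp <- .cc3d_seed(as.vector(sub), as.integer(dims), as.integer(seed_lin))
  out <- array(FALSE, dim = dim(volume$voxels))
  out[, , kz] <- array(comp, dim = dims)
  if (!any(out))
    nc_stop("airway component empty after clipping", "neckct_landmark_error")
  binary_mask(out, volume$spacing, volume$origin)
}

#' Body contour of one axial slice
#'
#' The body contour is the largest 8-connected component of
#' `{HU >= tissue_threshold}` on the slice, with interior holes filled so
#' the air lumen counts toward neck area; smaller disconnected components
#' (ear-like satellites) are excluded.
#'
#' @param volume a [ct_volume()].
#' @param slice_index 1-based axial slice index.
#' @param tissue_threshold HU at or above which a pixel is tissue
#'   (default 0; soft tissue sits near +40 HU).
#' @return a logical matrix (in-plane grid) of the filled body contour.
#' @export
body_mask_slice <- function(volume, slice_index, tissue_threshold = 0) {
  nc_assert(inherits(volume, "ct_volume"), "not a ct_volume")
  dims <- dim(volume$voxels)
  nc_assert(slice_index >= 1 && slice_index <= dims[3],
            "slice_index out of range")
  sl <- volume$voxels[, , slice_index] >= tissue_threshold
  if (!any(sl))
    nc_stop(sprintf("no tissue above %g HU on slice %d", tissue_threshold,
                    slice_index), "neckct_empty_body_error")
  .body_component_2d(sl, TRUE)
}

#' Per-compartment fat volumes
#'
#' Intersects the fat mask with a voxel label grid assigning fat voxels
#' to the subcutaneous, posterior and perivertebral compartments, and
#' reports each compartment's volume in cc.
#'
#' @param fat a [binary_mask()] of adipose voxels.
#' @param labels integer array of the same shape: 0 = none,
#'   1 = subcutaneous, 2 = posterior, 3 = perivertebral (optionally with a
#'   `compartments` attribute naming the levels).
#' @return named numeric vector of volumes (cc), one per compartment.
#' @export
compartment_volumes <- function(fat, labels) {
  nc_assert(inherits(fat, "binary_mask"), "not a binary_mask")
  if (!identical(dim(fat$voxels), dim(labels)))
    nc_stop("label grid shape does not match the fat mask",
            "neckct_alignment_error")
  lev <- attr(labels, "compartments") %||%
    c("subcutaneous", "posterior", "perivertebral")
  vox_cc <- prod(fat$spacing) / 1000
  lab_fat <- labels[fat$voxels]
  counts <- tabulate(lab_fat[lab_fat > 0], nbins = length(lev))
  setNames(counts * vox_cc, lev)
}
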