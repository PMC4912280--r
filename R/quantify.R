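# Mask -> anthropometric quantities: NATV and AWV in cc, their ratio,
# and the neck cross-sectional area (NCSA) on a 5-mm axial slab.

#' Mask volume in cc
#'
#' Counts true voxels and converts with the physical voxel volume
#' (1 cc = 1000 mm^3).
#'
#' @param mask a [binary_mask()].
#' @return volume in cc (0 for an empty mask).
#' @export
mask_volume_cc <- function(mask) {
  nc_assert(inherits(mask, "binary_mask"), "not a binary_mask")
  sum(mask$voxels) * prod(mask$spacing) / 1000
}

#' Neck cross-sectional area on an axial slab
#'
#' Measures the body-contour area on every slice of a thick axial slab
#' (default 5 mm) and returns the mean per-slice area in mm^2 — an areal
#' quantity, as reported from a thick single slice.
#'
#' @param volume a [ct_volume()].
#' @param level_z slab center (mm).
#' @param tissue_threshold HU threshold for the body contour (default 0).
#' @param slab_thickness slab thickness in mm (default 5).
#' @return area in mm^2.
#' @export
ncsa <- function(volume, level_z, tissue_threshold = 0, slab_thickness = 5) {
  slab <- slab_at(volume, level_z, slab_thickness)
  px_area <- volume$spacing[1] * volume$spacing[2]
  areas <- vapply(slab$slice_indices, function(k)
    sum(body_mask_slice(volume, k, tissue_threshold)) * px_area, 0)
  mean(areas)
}

#' NATV to AWV ratio
#'
#' @param natv_cc neck adipose tissue volume (cc, >= 0).
#' @param awv_cc airway volume (cc, > 0).
#' @return the dimensionless ratio `natv_cc / awv_cc`.
#' @export
natv_awv_ratio <- function(natv_cc, awv_cc) {
  nc_assert(is.numeric(natv_cc) && natv_cc >= 0, "natv_cc must be >= 0")
  if (!is.numeric(awv_cc) || awv_cc <= 0)
    nc_stop("NATV:AWV undefined for airway volume <= 0 cc",
            "neckct_ratio_error")
  natv_cc / awv_cc
}

#' Default quantification configuration
#'
#' Thresholds and conventions for a quantification run.  Invariant:
#' `air_threshold < window$low < window$high < tissue_threshold`.
#'
#' @param window adipose [hu_window()].
#' @param air_threshold airway HU threshold (default -500).
#' @param tissue_threshold body-contour HU threshold (default 0).
#' @param slab_thickness_mm NCSA slab thickness (default 5).
#' @param quantile_type quantile convention for cohort stratification
#'   (R type 7, linear interpolation).
#' @param seed integer seed for any stochastic stage.
#' @return an object of class `run_config`.
#' @export
run_config <- function(window = hu_window(), air_threshold = -500,
                       tissue_threshold = 0, slab_thickness_mm = 5,
                       quantile_type = 7L, seed = 1L) {
  nc_assert(inherits(window, "hu_window"), "window must be a hu_window")
  nc_assert(air_threshold < window$low && window$high < tissue_threshold,
            "thresholds must satisfy air < window low < window high < tissue")
  nc_assert(slab_thickness_mm > 0, "slab_thickness_mm must be > 0")
  structure(list(window = window, air_threshold = air_threshold,
                 tissue_threshold = tissue_threshold,
                 slab_thickness_mm = slab_thickness_mm,
                 quantile_type = as.integer(quantile_type),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Quantify one scan
#'
#' Runs the full single-scan pipeline — adipose windowing in the crop box,
#' seeded airway extraction, and NCSA at the soft-palate and
#' thyroid-cartilage levels — and assembles the volumetric result.  Any
#' stage failure aborts the scan (no partial result) with the stage named
#' in the error.
#'
#' @param volume a [ct_volume()].
#' @param landmarks a [landmark_set()].
#' @param config a [run_config()].
#' @param patient_id identifier copied into the result.
#' @return an object of class `volumetric_result`: a one-row data.frame
#'   with columns `patient_id`, `natv_cc`, `awv_cc`, `ratio`,
#'   `ncsa_upper_mm2`, `ncsa_lower_mm2`.
#' @export
quantify_scan <- function(volume, landmarks, config = run_config(),
                          patient_id = "scan") {
  nc_assert(inherits(config, "run_config"), "not a run_config")
  stage <- function(name, expr) {
    tryCatch(expr, neckct_error = function(e)
      nc_stop(paste0(name, " stage: ", conditionMessage(e)),
              class(e)[1]))
  }
  fat <- stage("fat_mask",
               fat_mask(volume, config$window, landmarks))
  air <- stage("airway_mask",
               airway_mask(volume, landmarks, config$air_threshold))
  up <- stage("ncsa_upper",
              ncsa(volume, landmarks$z_soft_palate_tip,
                   config$tissue_threshold, config$slab_thickness_mm))
  lo <- stage("ncsa_lower",
              ncsa(volume, landmarks$z_thyroid_cartilage,
                   config$tissue_threshold, config$slab_thickness_mm))
  natv <- mask_volume_cc(fat)
  awv <- mask_volume_cc(air)
  res <- data.frame(patient_id = patient_id, natv_cc = natv, awv_cc = awv,
                    ratio = natv_awv_ratio(natv, awv),
                    ncsa_upper_mm2 = up, ncsa_lower_mm2 = lo,
                    stringsAsFactors = FALSE)
  class(res) <- c("volumetric_result", class(res))
  res
}

#' @export
print.volumetric_result <- function(x, ...) {
  cat(sprintf(
    "<volumetric_result> %s: NATV %.1f cc, AWV %.1f cc, NATV:AWV %.1f\n",
    x$patient_id, x$natv_cc, x$awv_cc, x$ratio))
  cat(sprintf("  NCSA upper %.0f mm^2, lower %.0f mm^2\n",
              x$ncsa_upper_mm2, x$ncsa_lower_mm2))
  invisible(x)
}
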