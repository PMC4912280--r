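# Synthetic neck CT phantoms with analytically known geometry.
#
# Every structure is a solid whose volume has a closed form (ellipsoid
# 4/3*pi*abc; elliptic cylinder pi*a*b*h; cylindrical shell
# pi*(ao*bo - ai*bi)*h; tube pi*r^2*L), so segmentation accuracy can be
# judged against exact ground truth.  Voxel membership is decided by
# voxel-center inclusion: no partial-volume weighting, which makes the
# analytic volume exact up to a surface discretization term.

#' Phantom structure primitives
#'
#' Geometric solids composing a synthetic neck phantom.  All coordinates
#' and sizes in mm; `hu` is the Hounsfield value painted inside the solid.
#'
#' * `phantom_ellipsoid()` — axis-aligned ellipsoid.
#' * `phantom_cylinder()` — elliptic cylinder along z.
#' * `phantom_shell()` — annular elliptic cylinder along z (outer minus
#'   concentric inner ellipse), the subcutaneous-fat primitive.
#' * `phantom_tube()` — tube of circular per-slice cross-section whose
#'   centerline may bend sinusoidally in x; its analytic volume is
#'   `pi * r^2 * L` regardless of the bend because each axial section
#'   stays a disc of radius `r`.
#'
#' @param center,center_xy solid center, length 3 (`x,y,z`) or 2 (`x,y`).
#' @param semi_axes ellipsoid: length 3; cylinder: length 2 in-plane.
#' @param outer,inner shell in-plane semi-axes, length 2 each.
#' @param z_range length 2, caudal and cranial physical z (mm).
#' @param radius tube radius (mm).
#' @param bend_amplitude,bend_wavelength sinusoidal x-displacement of the
#'   tube centerline (mm); amplitude 0 gives a straight tube.
#' @param hu Hounsfield value of the solid.
#' @return a `phantom_shape` list with a `volume_mm3` field.
#' @name phantom_shapes
NULL

new_shape <- function(type, hu, volume_mm3, ...) {
  structure(c(list(type = type, hu = hu, volume_mm3 = volume_mm3),
              list(...)),
            class = "phantom_shape")
}

#' @rdname phantom_shapes
#' @export
phantom_ellipsoid <- function(center, semi_axes, hu) {
  nc_assert(length(center) == 3 && length(semi_axes) == 3 &&
              all(semi_axes > 0), "ellipsoid needs center[3], semi_axes[3] > 0")
  new_shape("ellipsoid", hu, 4 / 3 * pi * prod(semi_axes),
            center = as.numeric(center), semi_axes = as.numeric(semi_axes))
}

#' @rdname phantom_shapes
#' @export
phantom_cylinder <- function(center_xy, semi_axes, z_range, hu) {
  nc_assert(length(center_xy) == 2 && length(semi_axes) == 2 &&
              all(semi_axes > 0) && diff(z_range) > 0,
            "cylinder needs center_xy[2], semi_axes[2] > 0, increasing z_range")
  new_shape("cylinder", hu, pi * prod(semi_axes) * diff(z_range),
            center_xy = as.numeric(center_xy),
            semi_axes = as.numeric(semi_axes),
            z_range = as.numeric(z_range))
}

#' @rdname phantom_shapes
#' @param gap_angle angular width (radians) of a sector removed from the
#'   shell, measured in the normalized (parametric) angle so the removed
#'   volume is exactly `gap_angle / (2 pi)` of the full annulus; a gap
#'   models the soft-tissue bridge that connects skin to the deep tissues
#'   through the subcutaneous fat layer.
#' @param gap_center parametric angle (radians) of the gap center;
#'   default `pi / 2` (the posterior midline when +y is posterior).
#' @export
phantom_shell <- function(center_xy, outer, inner, z_range, hu,
                          gap_angle = 0, gap_center = pi / 2) {
  nc_assert(length(outer) == 2 && length(inner) == 2 &&
              all(inner > 0) && all(outer > inner) && diff(z_range) > 0,
            "shell needs outer > inner > 0 and increasing z_range")
  nc_assert(gap_angle >= 0 && gap_angle < 2 * pi,
            "gap_angle must lie in [0, 2*pi)")
  if (gap_angle > 0)
    nc_assert(abs(inner[1] / outer[1] - inner[2] / outer[2]) < 1e-9,
              "a gapped shell needs inner proportional to outer (the sector cut is exact only for similar ellipses)")
  new_shape("shell", hu,
            (1 - gap_angle / (2 * pi)) *
              pi * (prod(outer) - prod(inner)) * diff(z_range),
            center_xy = as.numeric(center_xy), outer = as.numeric(outer),
            inner = as.numeric(inner), z_range = as.numeric(z_range),
            gap_angle = as.numeric(gap_angle),
            gap_center = as.numeric(gap_center))
}

#' @rdname phantom_shapes
#' @export
phantom_tube <- function(center_xy, radius, z_range, hu = -1000,
                         bend_amplitude = 0, bend_wavelength = 120) {
  nc_assert(length(center_xy) == 2 && radius > 0 && diff(z_range) > 0,
            "tube needs center_xy[2], radius > 0, increasing z_range")
  nc_assert(bend_amplitude >= 0 && bend_wavelength > 0,
            "bend_amplitude >= 0, bend_wavelength > 0")
  new_shape("tube", hu, pi * radius^2 * diff(z_range),
            center_xy = as.numeric(center_xy), radius = as.numeric(radius),
            z_range = as.numeric(z_range),
            bend_amplitude = as.numeric(bend_amplitude),
            bend_wavelength = as.numeric(bend_wavelength))
}

# axis-aligned physical bounding box of a shape (mm)
shape_bbox <- function(s) {
  switch(s$type,
    ellipsoid = rbind(s$center - s$semi_axes, s$center + s$semi_axes),
    cylinder = rbind(c(s$center_xy - s$semi_axes, s$z_range[1]),
                     c(s$center_xy + s$semi_axes, s$z_range[2])),
    shell = rbind(c(s$center_xy - s$outer, s$z_range[1]),
                  c(s$center_xy + s$outer, s$z_range[2])),
    tube = rbind(c(s$center_xy[1] - s$radius - s$bend_amplitude,
                   s$center_xy[2] - s$radius, s$z_range[1]),
                 c(s$center_xy[1] + s$radius + s$bend_amplitude,
                   s$center_xy[2] + s$radius, s$z_range[2])))
}

# voxelize one shape on slice grids X, Y (nx x ny matrices of centers)
# and z centers zc; returns logical array nx x ny x nz
shape_voxels <- function(s, X, Y, zc) {
  nx <- nrow(X); ny <- ncol(X); nz <- length(zc)
  out <- array(FALSE, dim = c(nx, ny, nz))
  if (s$type == "ellipsoid") {
    kz <- which(abs(zc - s$center[3]) <= s$semi_axes[3])
    for (k in kz) {
      rz2 <- 1 - ((zc[k] - s$center[3]) / s$semi_axes[3])^2
      out[, , k] <- ((X - s$center[1]) / s$semi_axes[1])^2 +
        ((Y - s$center[2]) / s$semi_axes[2])^2 <= rz2
    }
  } else if (s$type == "cylinder") {
    kz <- which(zc >= s$z_range[1] & zc <= s$z_range[2])
    inpl <- ((X - s$center_xy[1]) / s$semi_axes[1])^2 +
      ((Y - s$center_xy[2]) / s$semi_axes[2])^2 <= 1
    for (k in kz) out[, , k] <- inpl
  } else if (s$type == "shell") {
    kz <- which(zc >= s$z_range[1] & zc <= s$z_range[2])
    xn <- (X - s$center_xy[1]) / s$outer[1]
    yn <- (Y - s$center_xy[2]) / s$outer[2]
    r_out <- xn^2 + yn^2
    r_in <- ((X - s$center_xy[1]) / s$inner[1])^2 +
      ((Y - s$center_xy[2]) / s$inner[2])^2
    inpl <- r_out <= 1 & r_in > 1
    if (s$gap_angle > 0) {
      # inner = f * outer, so the normalized angle is shared by both
      # ellipses and the sector cut is exact in the parametric measure
      ang <- atan2(yn, xn)
      d <- abs(((ang - s$gap_center + pi) %% (2 * pi)) - pi)
      inpl <- inpl & d > s$gap_angle / 2
    }
    for (k in kz) out[, , k] <- inpl
  } else if (s$type == "tube") {
    kz <- which(zc >= s$z_range[1] & zc <= s$z_range[2])
    for (k in kz) {
      cx <- s$center_xy[1] + s$bend_amplitude *
        sin(2 * pi * (zc[k] - s$z_range[1]) / s$bend_wavelength)
      out[, , k] <- (X - cx)^2 + (Y - s$center_xy[2])^2 <= s$radius^2
    }
  } else {
    nc_stop(paste0("unknown shape type: ", s$type), "neckct_spec_error")
  }
  out
}

#' Phantom specification
#'
#' A declarative description of a synthetic neck CT: an elliptic-cylinder
#' body of soft tissue, fat compartments in the adipose HU band, an air
#' tube for the airway, and an optional bone column.  Noise, when
#' requested, is additive Gaussian clipped to the CT range
#' \[-1024, 3071\] HU and never alters the geometric ground-truth masks.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing numeric length-3, voxel size in mm.
#' @param body a [phantom_cylinder()] (soft tissue, conventionally +40 HU).
#' @param fat_structures list of shapes with HU inside \[-150, -30\]
#'   (conventionally -90 HU).
#' @param airway a [phantom_tube()] with HU < -500 (conventionally -1000).
#' @param bone optional shape (conventionally +700 HU); painted beneath
#'   fat and airway so it never carves the fat or airway ground truth.
#' @param noise_sd standard deviation of additive HU noise (>= 0).
#' @param seed integer RNG seed for the noise field.
#' @param origin physical position of voxel (1,1,1), mm.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, spacing, body, fat_structures, airway,
                         bone = NULL, noise_sd = 0, seed = 1L,
                         origin = c(0, 0, 0)) {
  nc_assert(length(grid_shape) == 3 && all(grid_shape >= 1),
            "grid_shape must be 3 positive integers", "neckct_spec_error")
  nc_assert(length(spacing) == 3 && all(spacing > 0),
            "spacing must be 3 positive numbers", "neckct_spec_error")
  nc_assert(inherits(body, "phantom_shape") && body$type == "cylinder",
            "body must be a phantom_cylinder", "neckct_spec_error")
  nc_assert(is.list(fat_structures) && length(fat_structures) >= 1 &&
              all(vapply(fat_structures, inherits, TRUE, "phantom_shape")),
            "fat_structures must be a list of phantom shapes",
            "neckct_spec_error")
  fat_hu <- vapply(fat_structures, `[[`, 0, "hu")
  nc_assert(all(fat_hu >= -150 & fat_hu <= -30),
            "fat HU must lie inside [-150, -30]", "neckct_spec_error")
  nc_assert(is.null(airway) ||
              (inherits(airway, "phantom_shape") && airway$hu < -500),
            "airway HU must be < -500", "neckct_spec_error")
  nc_assert(noise_sd >= 0, "noise_sd must be >= 0", "neckct_spec_error")

  spec <- structure(list(
    grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
    origin = as.numeric(origin), body = body,
    fat_structures = fat_structures, airway = airway, bone = bone,
    noise_sd = as.numeric(noise_sd), seed = as.integer(seed)
  ), class = "phantom_spec")

  # every structure must lie inside the voxel-center extent of the grid
  lo <- spec$origin
  hi <- spec$origin + (spec$grid_shape - 1) * spec$spacing
  shapes <- c(list(body), fat_structures,
              if (!is.null(airway)) list(airway),
              if (!is.null(bone)) list(bone))
  for (s in shapes) {
    bb <- shape_bbox(s)
    if (any(bb[1, ] < lo - spec$spacing / 2) ||
        any(bb[2, ] > hi + spec$spacing / 2))
      nc_stop(sprintf("%s structure extends outside the grid", s$type),
              "neckct_spec_error")
  }
  spec
}

#' Generate a phantom CT volume with analytic ground truth
#'
#' Paints the spec's structures into an HU grid (precedence: airway over
#' fat over bone over body over ambient air at -1000 HU), adds optional
#' Gaussian noise, and returns exact ground truth: analytic fat and airway
#' volumes (1 cc = 1000 mm^3), an analytic body cross-sectional-area
#' function, voxelized masks, and the landmark set consistent with the
#' geometry.  Fully deterministic given the spec (the spec carries the
#' noise seed).
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `volume` (a [ct_volume()]) and `truth`
#'   (fields `fat_volume_cc`, `airway_volume_cc`, `ncsa_mm2_at` (function
#'   of z), `fat_mask`, `airway_mask`, `body_mask`, `landmarks`).
#' @export
generate_phantom <- function(spec) {
  nc_assert(inherits(spec, "phantom_spec"), "not a phantom_spec",
            "neckct_spec_error")
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]; nz <- spec$grid_shape[3]
  xc <- spec$origin[1] + (seq_len(nx) - 1) * spec$spacing[1]
  yc <- spec$origin[2] + (seq_len(ny) - 1) * spec$spacing[2]
  zc <- spec$origin[3] + (seq_len(nz) - 1) * spec$spacing[3]
  X <- matrix(xc, nx, ny)
  Y <- matrix(yc, nx, ny, byrow = TRUE)

  body_vox <- shape_voxels(spec$body, X, Y, zc)
  fat_vox <- array(FALSE, dim = spec$grid_shape)
  for (s in spec$fat_structures) fat_vox <- fat_vox | shape_voxels(s, X, Y, zc)
  air_vox <- if (is.null(spec$airway)) array(FALSE, dim = spec$grid_shape)
             else shape_voxels(spec$airway, X, Y, zc)
  if (any(fat_vox & air_vox))
    nc_stop("fat and airway structures overlap", "neckct_spec_error")

  hu <- array(-1000, dim = spec$grid_shape)
  hu[body_vox] <- spec$body$hu
  if (!is.null(spec$bone)) {
    bone_vox <- shape_voxels(spec$bone, X, Y, zc)
    hu[bone_vox] <- spec$bone$hu
  }
  for (s in spec$fat_structures) hu[shape_voxels(s, X, Y, zc)] <- s$hu
  if (!is.null(spec$airway)) hu[air_vox] <- spec$airway$hu

  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed,
                       rnorm(length(hu), sd = spec$noise_sd))
    hu <- hu + array(noise, dim = spec$grid_shape)
    hu[hu < -1024] <- -1024
    hu[hu > 3071] <- 3071
  }

  vol <- ct_volume(hu, spec$spacing, spec$origin)
  b <- spec$body
  ab <- prod(b$semi_axes)
  bzr <- b$z_range
  ncsa_fun <- function(z) ifelse(z >= bzr[1] & z <= bzr[2], pi * ab, 0)

  lm <- phantom_landmarks(spec, zc)

  truth <- list(
    fat_volume_cc = sum(vapply(spec$fat_structures, `[[`, 0, "volume_mm3")) / 1000,
    airway_volume_cc = if (is.null(spec$airway)) 0 else spec$airway$volume_mm3 / 1000,
    ncsa_mm2_at = ncsa_fun,
    fat_mask = binary_mask(fat_vox, spec$spacing, spec$origin),
    airway_mask = binary_mask(air_vox, spec$spacing, spec$origin),
    body_mask = binary_mask(body_vox, spec$spacing, spec$origin),
    landmarks = lm
  )
  list(volume = vol, truth = truth)
}

# landmark set consistent with the phantom geometry: the crop box covers
# the whole body, the airway clip covers the whole tube, NCSA levels sit
# at fixed fractions of the body height on slice centers
phantom_landmarks <- function(spec, zc = NULL) {
  if (is.null(zc))
    zc <- spec$origin[3] + (seq_len(spec$grid_shape[3]) - 1) * spec$spacing[3]
  b <- spec$body
  snap <- function(z) zc[which.min(abs(zc - z))]
  upper <- snap(b$z_range[1] + 0.72 * diff(b$z_range))
  lower <- snap(b$z_range[1] + 0.40 * diff(b$z_range))
  aw <- spec$airway
  seed_pt <- if (is.null(aw)) {
    c(b$center_xy, mean(b$z_range))
  } else {
    zmid <- snap(mean(aw$z_range))
    cx <- aw$center_xy[1] + aw$bend_amplitude *
      sin(2 * pi * (zmid - aw$z_range[1]) / aw$bend_wavelength)
    c(cx, aw$center_xy[2], zmid)
  }
  landmark_set(
    z_orbit_roof = b$z_range[2],
    z_sternal_angle = b$z_range[1],
    x_left_midclavicle = b$center_xy[1] + b$semi_axes[1] + 6,
    x_right_midclavicle = b$center_xy[1] - b$semi_axes[1] - 6,
    z_hard_palate = if (is.null(aw)) b$z_range[2] else aw$z_range[2],
    z_first_tracheal_ring = if (is.null(aw)) b$z_range[1] else aw$z_range[1],
    z_soft_palate_tip = upper,
    z_thyroid_cartilage = lower,
    airway_seed = seed_pt
  )
}

# median NATV (cc) by WHO BMI class in the reference cohort, used as
# anchors for the default phantom families
NATV_CLASS_ANCHORS <- c(lean = 444, overweight = 689, obese = 864)
AWV_MEAN_CC <- 23.6

#' Default neck phantom families by BMI class
#'
#' Builds a reproducible [phantom_spec()] whose analytic fat volume falls
#' within 10% of the class anchor (444 / 689 / 864 cc for lean /
#' overweight / obese, the reference cohort's median NATV per WHO BMI
#' category) and whose airway volume is near the cohort mean of 23.6 cc.
#' Fat is split across the three infrahyoid compartments: a subcutaneous
#' shell (55%), a posterior ellipsoid (27%), and a perivertebral
#' ellipsoid (18%), with compartment semi-axes >= 20 mm.
#'
#' @param size_class `"lean"`, `"overweight"` or `"obese"`.
#' @param seed integer; the spec is identical for identical seeds.
#' @param spacing voxel size in mm (default `c(1.2, 1.2, 2)`, the
#'   non-enhanced neck protocol scale; pass `c(1, 1, 1)` for isotropic
#'   accuracy studies).
#' @param noise_sd HU noise SD carried into the spec (default 0).
#' @return a [phantom_spec()].
#' @export
default_cohort_spec <- function(size_class = c("lean", "overweight", "obese"),
                                seed = 1L, spacing = c(1.2, 1.2, 2),
                                noise_sd = 0) {
  size_class <- match.arg(size_class)
  anchor <- NATV_CLASS_ANCHORS[[size_class]]
  ax <- switch(size_class, lean = c(72, 62), overweight = c(82, 70),
               obese = c(90, 76))
  with_seed(seed, {
    fat_target <- anchor * runif(1, 0.96, 1.04) * 1000    # mm^3
    awv_target <- AWV_MEAN_CC * runif(1, 0.88, 1.12) * 1000
    scale <- runif(1, 0.98, 1.02)
    build_neck_spec(body_semi_axes = ax * scale, fat_target = fat_target,
                    awv_target = awv_target, spacing = spacing,
                    noise_sd = noise_sd, seed = seed)
  })
}

# deterministic construction of a neck spec hitting an exact analytic fat
# volume (mm^3) and airway volume (mm^3) for a given body size
build_neck_spec <- function(body_semi_axes, fat_target, awv_target,
                            spacing, noise_sd = 0, seed = 1L,
                            airway_radius = NULL, body_height = 200,
                            margin = 14) {
  a <- body_semi_axes[1]; b <- body_semi_axes[2]
  lx <- 2 * a + 2 * margin; ly <- 2 * b + 2 * margin
  lz <- body_height + 2 * margin
  grid <- c(ceiling(lx / spacing[1]) + 1, ceiling(ly / spacing[2]) + 1,
            ceiling(lz / spacing[3]) + 1)
  cx <- (grid[1] - 1) * spacing[1] / 2
  cy <- (grid[2] - 1) * spacing[2] / 2
  z0 <- margin; z1 <- margin + body_height

  body <- phantom_cylinder(c(cx, cy), c(a, b), c(z0, z1), hu = 40)

  # subcutaneous shell: outer = body minus 4 mm skin, inner solved so the
  # shell volume is exactly 55% of the target
  sub_v <- 0.55 * fat_target
  out_ax <- c(a - 4, b - 4)
  shell_h <- 0.80 * body_height
  shell_z <- c(z0 + 0.10 * body_height, z0 + 0.90 * body_height)
  gap <- 35 * pi / 180        # posterior soft-tissue bridge through the fat
  f <- sqrt(1 - sub_v /
              ((1 - gap / (2 * pi)) * pi * prod(out_ax) * shell_h))
  nc_assert(is.finite(f) && f > 0.3, "fat target too large for this body",
            "neckct_spec_error")
  sub <- phantom_shell(c(cx, cy), out_ax, f * out_ax, shell_z, hu = -90,
                       gap_angle = gap, gap_center = pi / 2)

  # posterior ellipsoid (27%): semi-axis ratios (1.2, 1, 1.5) * bb
  post_v <- 0.27 * fat_target
  bb <- (post_v / (4 / 3 * pi * 1.2 * 1.5))^(1 / 3)
  post <- phantom_ellipsoid(c(cx, cy + 0.40 * b, z0 + 0.72 * body_height),
                            c(1.2, 1, 1.5) * bb, hu = -90)

  # perivertebral ellipsoid (18%): ratios (1.1, 1, 1.5) * pb, caudal band
  peri_v <- 0.18 * fat_target
  pb <- (peri_v / (4 / 3 * pi * 1.1 * 1.5))^(1 / 3)
  peri <- phantom_ellipsoid(c(cx, cy + 0.30 * b, z0 + 0.28 * body_height),
                            c(1.1, 1, 1.5) * pb, hu = -90)

  aw_z <- c(z0 + 0.15 * body_height, z0 + 0.95 * body_height)
  r <- if (is.null(airway_radius)) sqrt(awv_target / (pi * diff(aw_z)))
       else airway_radius
  # wide validation tubes sit more anterior to clear the deep fat
  aw_y <- cy - (if (r > 12) 0.45 else 0.25) * b
  airway <- phantom_tube(c(cx, aw_y), r, aw_z, hu = -1000,
                         bend_amplitude = min(3, 0.1 * b),
                         bend_wavelength = 0.6 * body_height)

  bone <- phantom_cylinder(c(cx, cy + 0.42 * b), c(10, 10),
                           c(z0, z1), hu = 700)

  phantom_spec(grid_shape = grid, spacing = spacing, body = body,
               fat_structures = list(subcutaneous = sub, posterior = post,
                                     perivertebral = peri),
               airway = airway, bone = bone, noise_sd = noise_sd,
               seed = seed)
}

#' Accuracy-study phantom
#'
#' A phantom family for voxelization-accuracy studies: identical in
#' construction to [default_cohort_spec()] but with an airway tube of
#' radius 20 mm, so that every structure radius is >= 20 mm and the
#' voxel-center discretization error at 1 mm isotropic spacing stays
#' within the surface-term bound (about 1.5% for volumes, 1% for areas).
#' The airway volume is then deliberately unphysiological.
#'
#' @param seed integer seed.
#' @param spacing voxel size in mm, default 1 mm isotropic.
#' @param noise_sd HU noise SD (default 0).
#' @return a [phantom_spec()].
#' @export
accuracy_phantom_spec <- function(seed = 1L, spacing = c(1, 1, 1),
                                  noise_sd = 0) {
  with_seed(seed, {
    anchor <- sample(NATV_CLASS_ANCHORS, 1)
    ax <- switch(names(anchor), lean = c(72, 62),
                 overweight = c(82, 70), obese = c(90, 76))
    fat_target <- anchor * runif(1, 0.96, 1.04) * 1000
    scale <- runif(1, 0.98, 1.02)
    build_neck_spec(body_semi_axes = ax * scale, fat_target = fat_target,
                    awv_target = NA, spacing = spacing, noise_sd = noise_sd,
                    seed = seed, airway_radius = 20)
  })
}

#' Serialize / deserialize a phantom spec as JSON
#'
#' @param spec a [phantom_spec()].
#' @param path JSON file path.
#' @return `path` invisibly (`write_phantom_spec`); a [phantom_spec()]
#'   (`read_phantom_spec`).
#' @export
write_phantom_spec <- function(spec, path) {
  nc_assert(inherits(spec, "phantom_spec"), "not a phantom_spec",
            "neckct_spec_error")
  ser_shape <- function(s) unclass(s)
  out <- list(
    grid_shape = spec$grid_shape, spacing = spec$spacing,
    origin = spec$origin, body = ser_shape(spec$body),
    fat_structures = lapply(spec$fat_structures, ser_shape),
    airway = if (is.null(spec$airway)) NULL else ser_shape(spec$airway),
    bone = if (is.null(spec$bone)) NULL else ser_shape(spec$bone),
    noise_sd = spec$noise_sd, seed = spec$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  nc_assert(file.exists(path), paste0("no such spec file: ", path),
            "neckct_input_error")
  js <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                 error = function(e)
                   nc_stop(paste0("malformed phantom spec JSON: ",
                                  conditionMessage(e)),
                           "neckct_schema_error"))
  de_shape <- function(s) {
    if (is.null(s)) return(NULL)
    switch(s$type,
      ellipsoid = phantom_ellipsoid(s$center, s$semi_axes, s$hu),
      cylinder = phantom_cylinder(s$center_xy, s$semi_axes, s$z_range, s$hu),
      shell = phantom_shell(s$center_xy, s$outer, s$inner, s$z_range, s$hu,
                            s$gap_angle %||% 0, s$gap_center %||% (pi / 2)),
      tube = phantom_tube(s$center_xy, s$radius, s$z_range, s$hu,
                          s$bend_amplitude, s$bend_wavelength),
      nc_stop(paste0("unknown shape type in spec JSON: ", s$type),
              "neckct_schema_error"))
  }
  for (fld in c("grid_shape", "spacing", "body", "fat_structures"))
    if (is.null(js[[fld]]))
      nc_stop(paste0("phantom spec JSON missing field: ", fld),
              "neckct_schema_error")
  fats <- js$fat_structures
  # read_json returns a data.frame-less list of lists here
  if (!is.null(names(fats)) || (length(fats) && is.list(fats[[1]]))) {
    fats <- lapply(fats, de_shape)
  } else {
    fats <- list(de_shape(fats))
  }
  phantom_spec(grid_shape = unlist(js$grid_shape),
               spacing = unlist(js$spacing),
               origin = if (is.null(js$origin)) c(0, 0, 0) else unlist(js$origin),
               body = de_shape(js$body), fat_structures = fats,
               airway = de_shape(js$airway), bone = de_shape(js$bone),
               noise_sd = js$noise_sd %||% 0, seed = js$seed %||% 1L)
}
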