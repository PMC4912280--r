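# a landmark set whose crop covers the whole grid of a small test volume
full_crop_landmarks <- function(dims = c(10, 10, 10), spacing = c(1, 1, 1),
                                seed_pt = c(5, 5, 5)) {
  ext <- (dims - 1) * spacing
  landmark_set(
    z_orbit_roof = ext[3], z_sternal_angle = 0,
    x_left_midclavicle = ext[1], x_right_midclavicle = 0,
    z_hard_palate = ext[3], z_first_tracheal_ring = 0,
    z_soft_palate_tip = ext[3] / 2, z_thyroid_cartilage = ext[3] / 4,
    airway_seed = seed_pt)
}

test_that("fat_mask applies the closed HU window", {
  lm <- full_crop_landmarks()
  u <- function(hu) ct_volume(array(hu, c(10, 10, 10)), c(1, 1, 1))
  expect_true(all(fat_mask(u(-90), hu_window(), lm)$voxels))
  expect_false(any(fat_mask(u(40), hu_window(), lm)$voxels))
  # boundary inclusivity: -150 and -30 in, -151 and -29.999 out
  expect_true(all(fat_mask(u(-150), hu_window(), lm)$voxels))
  expect_true(all(fat_mask(u(-30), hu_window(), lm)$voxels))
  expect_false(any(fat_mask(u(-151), hu_window(), lm)$voxels))
  expect_false(any(fat_mask(u(-29.999), hu_window(), lm)$voxels))
})

test_that("fat_mask crops to the anatomic box on voxel centers", {
  vox <- array(-90, c(10, 10, 10))
  v <- ct_volume(vox, c(1, 1, 1))
  lm <- landmark_set(
    z_orbit_roof = 7, z_sternal_angle = 3,
    x_left_midclavicle = 6, x_right_midclavicle = 2,
    z_hard_palate = 7, z_first_tracheal_ring = 3,
    z_soft_palate_tip = 6, z_thyroid_cartilage = 4,
    airway_seed = c(4, 4, 5))
  m <- fat_mask(v, hu_window(), lm)
  idx <- which(m$voxels, arr.ind = TRUE)
  # closed crop on centers: x in [2, 6] -> i in 3..7; z in [3, 7] -> k in 4..8
  expect_setequal(unique(idx[, 1]), 3:7)
  expect_setequal(unique(idx[, 3]), 4:8)
  expect_setequal(unique(idx[, 2]), 1:10)   # y unconstrained

  lm_bad <- landmark_set(
    z_orbit_roof = 8.7, z_sternal_angle = 8.4,
    x_left_midclavicle = 6, x_right_midclavicle = 2,
    z_hard_palate = 8.7, z_first_tracheal_ring = 8.4,
    z_soft_palate_tip = 8.6, z_thyroid_cartilage = 8.5,
    airway_seed = c(4, 4, 8.5))
  expect_error(fat_mask(v, hu_window(), lm_bad),
               class = "neckct_landmark_error")
})

test_that("fat_mask is monotone in the window and idempotent", {
  set.seed(11)
  v <- ct_volume(array(runif(8000, -300, 100), c(20, 20, 20)), c(1, 1, 1))
  lm <- full_crop_landmarks(c(20, 20, 20))
  narrow <- fat_mask(v, hu_window(-120, -60), lm)
  wide <- fat_mask(v, hu_window(-150, -30), lm)
  expect_true(all(wide$voxels[narrow$voxels]))
  expect_identical(fat_mask(v, hu_window(), lm)$voxels, wide$voxels)
})

test_that("airway_mask grows only the seeded component within the z-clip", {
  # two disjoint air tubes in a soft-tissue block; brute-force component
  # check: only the seeded tube voxels are returned
  vox <- array(40, c(20, 20, 20))
  vox[5:7, 5:7, ] <- -1000       # tube A
  vox[14:16, 14:16, ] <- -1000   # tube B
  v <- ct_volume(vox, c(1, 1, 1))
  lm <- full_crop_landmarks(c(20, 20, 20), seed_pt = c(5, 5, 10))
  m <- airway_mask(v, lm)
  expect_identical(sum(m$voxels), sum(vox[5:7, 5:7, ] < -500))
  expect_false(any(m$voxels[14:16, 14:16, ]))

  # seed in soft tissue -> seed error
  lm2 <- full_crop_landmarks(c(20, 20, 20), seed_pt = c(10, 10, 10))
  expect_error(airway_mask(v, lm2), class = "neckct_seed_error")
})

test_that("airway_mask clips strictly to the landmark z-interval", {
  vox <- array(40, c(12, 12, 30))
  vox[5:7, 5:7, ] <- -1000
  v <- ct_volume(vox, c(1, 1, 1))
  lm <- landmark_set(
    z_orbit_roof = 29, z_sternal_angle = 0,
    x_left_midclavicle = 11, x_right_midclavicle = 0,
    z_hard_palate = 20, z_first_tracheal_ring = 8,
    z_soft_palate_tip = 15, z_thyroid_cartilage = 10,
    airway_seed = c(5, 5, 14))
  m <- airway_mask(v, lm)
  ks <- unique(which(m$voxels, arr.ind = TRUE)[, 3])
  expect_setequal(ks, 9:21)   # slice centers 8..20 inclusive
  # recovered volume = 9 voxels/slice * 13 slices
  expect_equal(sum(m$voxels), 9 * 13)
})

test_that("airway recovery on a phantom tube is within 2% of pi r^2 L", {
  spec <- default_cohort_spec("overweight", seed = 4, spacing = c(1, 1, 1))
  ph <- generate_phantom(spec)
  m <- airway_mask(ph$volume, ph$truth$landmarks)
  expect_lt(abs(mask_volume_cc(m) - ph$truth$airway_volume_cc) /
              ph$truth$airway_volume_cc, 0.02)
})

test_that("body_mask_slice fills holes and drops satellites", {
  # disc of +40 HU in air
  vox <- array(-1000, c(40, 40, 3))
  X <- matrix(seq_len(40), 40, 40); Y <- t(X)
  disc <- (X - 20)^2 + (Y - 20)^2 <= 12^2
  for (k in 1:3) vox[, , k][disc] <- 40
  v <- ct_volume(vox, c(1, 1, 1))
  expect_identical(body_mask_slice(v, 2), disc)

  # internal air hole is filled
  hole <- (X - 20)^2 + (Y - 20)^2 <= 3^2
  vox2 <- vox; for (k in 1:3) vox2[, , k][hole] <- -1000
  v2 <- ct_volume(vox2, c(1, 1, 1))
  expect_identical(body_mask_slice(v2, 2), disc)

  # a small disjoint satellite blob (ear-like) is excluded:
  # component-size oracle says the disc (449 px) beats the blob (9 px)
  vox3 <- vox
  blob <- (X - 36)^2 + (Y - 20)^2 <= 1.5^2
  for (k in 1:3) vox3[, , k][blob] <- 40
  v3 <- ct_volume(vox3, c(1, 1, 1))
  expect_identical(body_mask_slice(v3, 2), disc)
  expect_gt(sum(disc), sum(blob))

  # nothing above threshold
  v4 <- ct_volume(array(-1000, c(5, 5, 2)), c(1, 1, 1))
  expect_error(body_mask_slice(v4, 1), class = "neckct_empty_body_error")
})

test_that("noiseless phantom fat mask equals truth inside crop within 1.5%", {
  spec <- default_cohort_spec("obese", seed = 6, spacing = c(1, 1, 1))
  ph <- generate_phantom(spec)
  m <- fat_mask(ph$volume, hu_window(), ph$truth$landmarks)
  expect_identical(m$voxels, ph$truth$fat_mask$voxels)  # crop covers all fat
  expect_lt(abs(mask_volume_cc(m) - ph$truth$fat_volume_cc) /
              ph$truth$fat_volume_cc, 0.015)
})

test_that("noise at SD 20 HU leaves fat and airway volumes within 2%", {
  spec <- default_cohort_spec("overweight", seed = 8,
                              spacing = c(1, 1, 1), noise_sd = 20)
  ph <- generate_phantom(spec)
  fm <- fat_mask(ph$volume, hu_window(), ph$truth$landmarks)
  am <- airway_mask(ph$volume, ph$truth$landmarks)
  expect_lt(abs(mask_volume_cc(fm) - ph$truth$fat_volume_cc) /
              ph$truth$fat_volume_cc, 0.02)
  expect_lt(abs(mask_volume_cc(am) - ph$truth$airway_volume_cc) /
              ph$truth$airway_volume_cc, 0.02)
})

test_that("compartment_volumes intersects labels with the fat mask", {
  dims <- c(10, 10, 4)
  fatvox <- array(FALSE, dims); fatvox[1:6, , ] <- TRUE
  fat <- binary_mask(fatvox, c(1, 1, 2))
  vox_cc <- prod(c(1, 1, 2)) / 1000

  all_sub <- array(1L, dims)
  v <- compartment_volumes(fat, all_sub)
  expect_equal(unname(v["subcutaneous"]), sum(fatvox) * vox_cc)
  expect_equal(unname(v["posterior"] + v["perivertebral"]), 0)

  expect_equal(unname(compartment_volumes(fat, array(0L, dims))),
               c(0, 0, 0))

  labels <- array(0L, dims)
  labels[1:3, , ] <- 1L; labels[4:5, , ] <- 2L; labels[7:10, , ] <- 3L
  v2 <- compartment_volumes(fat, labels)
  expect_equal(unname(v2["subcutaneous"]), 3 * 10 * 4 * vox_cc)
  expect_equal(unname(v2["posterior"]), 2 * 10 * 4 * vox_cc)
  expect_equal(unname(v2["perivertebral"]), 0)  # labels outside fat ignored
  expect_lte(sum(v2), mask_volume_cc(fat))

  expect_error(compartment_volumes(fat, array(0L, c(2, 2, 2))),
               class = "neckct_alignment_error")
})

test_that("phantom compartment volumes match the per-shape analytics", {
  spec <- default_cohort_spec("lean", seed = 12, spacing = c(1, 1, 1))
  ph <- generate_phantom(spec)
  # build labels from the spec's own shapes (disjoint by construction)
  lm <- ph$truth$landmarks
  labels <- array(0L, dim(ph$volume$voxels))
  for (i in seq_along(spec$fat_structures)) {
    sub <- phantom_spec(spec$grid_shape, spec$spacing, spec$body,
                        spec$fat_structures[i], airway = NULL)
    labels[generate_phantom(sub)$truth$fat_mask$voxels] <- i
  }
  fm <- fat_mask(ph$volume, hu_window(), lm)
  v <- compartment_volumes(fm, labels)
  truth <- vapply(spec$fat_structures, `[[`, 0, "volume_mm3") / 1000
  expect_equal(length(v), length(truth))
  for (i in seq_along(truth))
    expect_lt(abs(v[[i]] - truth[[i]]) / truth[[i]], 0.015)
})
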