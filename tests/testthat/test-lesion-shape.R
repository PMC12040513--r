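test_that("minimum-volume rule keeps and excludes lesions in world mm", {
  arr <- array(0L, dim = c(10, 10, 10))
  arr[2:6, 3, 3] <- 1L  # 10 voxels? no: 5 voxels along x
  arr[2:6, 4, 3] <- 1L  # total 10 voxels at 1 mm^3
  arr[8, 8, 8] <- 2L
  arr[8, 9, 8] <- 2L    # 2 voxels -> 2 mm^3, below the 3 mm^3 floor
  lv <- label_volume(arr, diag(4))
  ex <- extract_lesions(lv, min_volume = 3)
  expect_named(ex$lesions, "1")
  expect_equal(ex$excluded$lesion_id, 2L)
  expect_match(ex$excluded$reason, "below minimum")

  # min_volume 0 keeps everything
  ex0 <- extract_lesions(lv, min_volume = 0)
  expect_setequal(names(ex0$lesions), c("1", "2"))

  # anisotropic voxels: a single 1x1x3 mm voxel is 3 mm^3, kept at the floor
  arr1 <- array(0L, dim = c(5, 5, 5)); arr1[3, 3, 3] <- 1L
  lv1 <- label_volume(arr1, diag(c(1, 1, 3, 1)))
  ex1 <- extract_lesions(lv1, min_volume = 3)
  expect_named(ex1$lesions, "1")
  expect_equal(abs(det(diag(c(1, 1, 3)))), 3) # voxel-volume oracle
  expect_error(extract_lesions(label_volume(array(0L, c(3, 3, 3)), diag(4))),
               class = "ldr_error_empty_labels")
})

test_that("ellipsoid fit recovers size and orientation of digitized solids", {
  # solid sphere radius 6 mm: all axis lengths ~ 12 mm
  vox <- digitize_ellipsoid(c(6, 6, 6))
  f <- fit_ellipsoid(vox, diag(4))
  expect_true(all(abs(f$lambda - 12) / 12 < 0.05))
  expect_equal(f$centroid, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(f$volume_mm3, nrow(vox))

  # axis-aligned (10, 4, 4) mm ellipsoid
  vox <- digitize_ellipsoid(c(10, 4, 4))
  f <- fit_ellipsoid(vox, diag(4))
  expect_lt(axial_deg(f$evecs[, 1], c(1, 0, 0)), 3)
  expect_lt(abs(f$lambda[1] / f$lambda[2] - 2.5) / 2.5, 0.10)

  # same ellipsoid rotated 30 degrees about z: fit-then-rotate oracle
  R <- matrix(c(cos(pi / 6), sin(pi / 6), 0,
                -sin(pi / 6), cos(pi / 6), 0,
                0, 0, 1), 3, 3)
  voxr <- digitize_ellipsoid(c(10, 4, 4), R = R)
  fr <- fit_ellipsoid(voxr, diag(4))
  expect_lt(axial_deg(fr$evecs[, 1], c(cos(pi / 6), sin(pi / 6), 0)), 3)

  expect_error(fit_ellipsoid(matrix(numeric(0), 0, 3), diag(4)),
               class = "ldr_error_empty_lesion")
  # single voxel: isotropic at voxel scale, flagged
  f1 <- fit_ellipsoid(matrix(c(2, 2, 2), 1), diag(4))
  expect_true("single_voxel" %in% f1$qc)
  expect_gt(f1$lambda[3], 0)
})

test_that("fit agrees with the brute-force moment oracle to 1e-9", {
  R <- matrix(c(cos(0.4), sin(0.4), 0, -sin(0.4), cos(0.4), 0, 0, 0, 1), 3, 3)
  vox <- digitize_ellipsoid(c(8, 4, 2.5), R = R, voxel_mm = c(1, 1, 2))
  aff <- diag(c(1, 1, 2, 1)); aff[1:3, 4] <- c(-3, 7, 0.5)
  f <- fit_ellipsoid(vox, aff)
  oracle <- brute_force_moments(vox, aff)
  for (k in 1:3) {
    expect_lt(1 - abs(sum(f$evecs[, k] * oracle$vectors[, k])), 1e-9)
    expect_lt(abs(f$moments[k] - oracle$values[k]) / oracle$values[k], 1e-9)
  }
})

test_that("anisotropy matches the closed form and its limits", {
  expect_equal(anisotropy(2, 2, 2), 0)
  expect_equal(anisotropy(5, 1e-9, 1e-10), 1, tolerance = 1e-6)
  # direct evaluation of the closed form at (3, 2, 1)
  expect_equal(anisotropy(3, 2, 1),
               sqrt(0.5) * sqrt((3 - 2)^2 + (2 - 1)^2 + (1 - 3)^2) /
                 sqrt(9 + 4 + 1))
  expect_equal(round(anisotropy(3, 2, 1), 5), 0.46291)
  expect_error(anisotropy(3, 2, 0), class = "ldr_error_eigenvalues")
  expect_error(anisotropy(1, 2, 3), class = "ldr_error_eigenvalues")
})

test_that("shape fitting is rotation-equivariant and scale-covariant", {
  rot_mat <- function(k, th_deg) {
    ku <- k / sqrt(sum(k^2)); th <- th_deg * pi / 180
    K <- matrix(c(0, ku[3], -ku[2], -ku[3], 0, ku[1], ku[2], -ku[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  # axis equivariance on a typical lesion-sized ellipsoid
  semi <- c(9, 4, 3)
  withr::with_seed(21, {
    for (i in 1:4) {
      R <- rot_mat(rnorm(3), runif(1, 10, 80))
      f <- fit_ellipsoid(digitize_ellipsoid(semi, R = R), diag(4))
      expect_lt(axial_deg(f$evecs[, 1], R[, 1]), 3)
    }
  })
  # anisotropy invariance to 2%: needs enough voxels that digitization
  # noise sits below the tolerance
  semi_big <- c(16, 8, 5.5)
  base <- fit_ellipsoid(digitize_ellipsoid(semi_big), diag(4))
  fa0 <- anisotropy(base$lambda[1], base$lambda[2], base$lambda[3])
  withr::with_seed(22, {
    for (i in 1:3) {
      R <- rot_mat(rnorm(3), runif(1, 10, 80))
      f <- fit_ellipsoid(digitize_ellipsoid(semi_big, R = R), diag(4))
      fa <- anisotropy(f$lambda[1], f$lambda[2], f$lambda[3])
      expect_lt(abs(fa - fa0) / fa0, 0.02)
    }
  })
  # uniform scaling: same voxel set on a 2 mm grid doubles lambda, FA unchanged
  vox <- digitize_ellipsoid(semi)
  f1 <- fit_ellipsoid(vox, diag(4))
  f2 <- fit_ellipsoid(vox, diag(c(2, 2, 2, 1)))
  expect_equal(f2$lambda, 2 * f1$lambda, tolerance = 1e-12)
  expect_equal(anisotropy(f2$lambda[1], f2$lambda[2], f2$lambda[3]),
               anisotropy(f1$lambda[1], f1$lambda[2], f1$lambda[3]),
               tolerance = 1e-12)
})

test_that("axes computed in world mm are stable across grid anisotropy", {
  # same world-space ellipsoid sampled on 1 mm and 1x1x3 mm grids
  R <- matrix(c(cos(0.5), 0, -sin(0.5), 0, 1, 0, sin(0.5), 0, cos(0.5)), 3, 3)
  f_iso <- fit_ellipsoid(digitize_ellipsoid(c(10, 4, 4), R = R), diag(4))
  f_ani <- fit_ellipsoid(digitize_ellipsoid(c(10, 4, 4), R = R,
                                            voxel_mm = c(1, 1, 3)),
                         diag(c(1, 1, 3, 1)))
  expect_lt(axial_deg(f_iso$evecs[, 1], f_ani$evecs[, 1]), 5)
})

test_that("volume never decreases when voxels are added", {
  vox <- digitize_ellipsoid(c(5, 3, 3))
  f_all <- fit_ellipsoid(vox, diag(4))
  f_sub <- fit_ellipsoid(vox[1:(nrow(vox) - 10), ], diag(4))
  expect_gt(f_all$volume_mm3, f_sub$volume_mm3)
})

test_that("lesion_shapes returns a tidy per-lesion table", {
  emb <- as_label_volume(digitize_ellipsoid(c(6, 3, 3)))
  tbl <- lesion_shapes(emb$volume, patient_id = "PX")
  expect_s3_class(tbl, "tbl_df")
  expect_equal(nrow(tbl), 1)
  expect_equal(tbl$patient_id, "PX")
  expect_true(tbl$lambda1_mm >= tbl$lambda2_mm &&
                tbl$lambda2_mm >= tbl$lambda3_mm && tbl$lambda3_mm > 0)
  expect_true(tbl$anisotropy > 0 && tbl$anisotropy < 1)
  # the moment-based anisotropy switch gives a different (larger) value
  tblm <- lesion_shapes(emb$volume, anisotropy_on = "moments")
  expect_gt(tblm$anisotropy, tbl$anisotropy)
})
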