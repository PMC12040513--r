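make_sphere_mask <- function(dims, centre, radius, voxel_mm = c(1, 1, 1)) {
  ax <- lapply(1:3, function(k) (seq_len(dims[k]) - 1) * voxel_mm[k])
  d2 <- outer(outer((ax[[1]] - centre[1])^2, (ax[[2]] - centre[2])^2, `+`),
              (ax[[3]] - centre[3])^2, `+`)
  label_volume(array(as.integer(d2 <= radius^2), dims), diag(c(voxel_mm, 1)))
}

test_that("surface-in field of a spherical ventricle is radial and unit norm", {
  vent <- make_sphere_mask(c(41, 41, 41), c(20, 20, 20), 6)
  f <- surface_in_field(vent)
  # sample off-mask voxels away from grid edges and from the centre ridge
  withr::with_seed(5, idx <- matrix(sample(6:34, 300, replace = TRUE), ncol = 3))
  ctr <- c(20, 20, 20)
  n_checked <- 0; n_good <- 0; norms <- c()
  for (i in seq_len(nrow(idx))) {
    p <- idx[i, ]
    r <- sqrt(sum((p - ctr)^2))
    if (r < 8) next
    u <- f$data[p[1] + 1, p[2] + 1, p[3] + 1, ]
    if (sum(u^2) == 0) next
    n_checked <- n_checked + 1
    norms <- c(norms, sqrt(sum(u^2)))
    if (axial_deg(u, p - ctr) < 3) n_good <- n_good + 1
  }
  expect_gt(n_checked, 50)
  expect_gte(n_good / n_checked, 0.99)
  expect_true(all(abs(norms - 1) < 1e-6))
  expect_error(surface_in_field(label_volume(array(0L, c(5, 5, 5)), diag(4))),
               class = "ldr_error_empty_mask")
})

test_that("surface-in field of a slab ventricle is the slab normal", {
  arr <- array(0L, dim = c(20, 20, 40)); arr[, , 1:10] <- 1L
  vent <- label_volume(arr, diag(4))
  f <- surface_in_field(vent)
  # far half-space, away from lateral edges
  for (p in list(c(10, 10, 25), c(5, 15, 30), c(15, 5, 35))) {
    u <- f$data[p[1] + 1, p[2] + 1, p[3] + 1, ]
    expect_lt(axial_deg(u, c(0, 0, 1)), 1)
    expect_gt(u[3], 0) # signed outward, away from the slab
  }
  # inside the mask: undefined
  expect_equal(f$data[5, 5, 5, ], c(0, 0, 0))
})

test_that("per-lesion gradient axis averages signed vectors component-wise", {
  vox <- matrix(c(0, 0, 0, 1, 0, 0), ncol = 3, byrow = TRUE)
  uni <- constant_field(c(3, 3, 3), c(0, 1, 0))
  r <- lesion_gradient_axis(vox, uni)
  expect_true(r$defined)
  expect_equal(r$axis, c(0, 1, 0))

  # two voxels 30 degrees apart -> bisector (closed-form vector mean)
  arr <- array(0, dim = c(3, 3, 3, 3))
  arr[1, 1, 1, ] <- c(1, 0, 0)
  arr[2, 1, 1, ] <- c(cos(pi / 6), sin(pi / 6), 0)
  fld <- vector_volume(arr, diag(4), semantics = "gradient")
  r2 <- lesion_gradient_axis(vox, fld)
  bisector <- (c(1, 0, 0) + c(cos(pi / 6), sin(pi / 6), 0))
  expect_lt(axial_deg(r2$axis, bisector), 1e-6)

  # opposing vectors cancel -> undefined with dispersion flag
  arr[2, 1, 1, ] <- c(-1, 0, 0)
  fld3 <- vector_volume(arr, diag(4), semantics = "gradient")
  r3 <- lesion_gradient_axis(vox, fld3)
  expect_false(r3$defined)
  expect_true("high_dispersion" %in% r3$qc)

  zero <- constant_field(c(3, 3, 3), c(0, 0, 0))
  expect_error(lesion_gradient_axis(vox, zero),
               class = "ldr_error_no_field_values")
})

test_that("tract axis is a sign-free dyadic mean with a crossing-fibre flag", {
  vox <- as.matrix(expand.grid(0:3, 0:3, 0)) # 16 voxels
  uni <- constant_field(c(5, 5, 3), c(0, 1, 0), semantics = "axis")
  r <- lesion_tract_axis(vox, uni)
  expect_equal(r$axis, c(0, 1, 0))
  expect_length(r$qc, 0)

  # half u, half -u must not cancel (axis semantics canonicalizes, but the
  # dyadic mean is sign-free regardless: feed a raw gradient-tagged field)
  arr <- array(0, dim = c(5, 5, 3, 3))
  u <- c(1, 2, 2) / 3
  for (i in 1:4) for (j in 1:4)
    arr[i, j, 1, ] <- if ((i + j) %% 2 == 0) u else -u
  mixed <- vector_volume(arr, diag(4), semantics = "gradient")
  rm <- lesion_tract_axis(vox, mixed)
  expect_lt(axial_deg(rm$axis, u), 1e-9)

  # 50/50 orthogonal x / y vectors: no dominant direction
  for (i in 1:4) for (j in 1:4)
    arr[i, j, 1, ] <- if ((i + j) %% 2 == 0) c(1, 0, 0) else c(0, 1, 0)
  crossing <- vector_volume(arr, diag(4), semantics = "gradient")
  rc <- lesion_tract_axis(vox, crossing)
  expect_true("crossing_fibres" %in% rc$qc)
  # dyadic-tensor eigenvalue oracle: top two eigenvalues of sum u u^T tie
  T <- matrix(0, 3, 3)
  for (i in 1:4) for (j in 1:4) {
    v <- arr[i, j, 1, ]; T <- T + v %*% t(v)
  }
  ev <- eigen(T, symmetric = TRUE)$values
  expect_lt((ev[1] - ev[2]) / ev[1], 0.2)
  expect_error(lesion_tract_axis(vox, constant_field(c(5, 5, 3), c(0, 0, 0))),
               class = "ldr_error_no_field_values")
})

test_that("vein axis comes from pooled moments of intersecting vein voxels", {
  # lesion = 9x9x13 block, vein = 1-voxel-wide tube along z through it
  lesion_vox <- as.matrix(expand.grid(0:8, 0:8, 0:12))
  arr <- array(0L, dim = c(9, 9, 13))
  arr[5, 5, ] <- 1L
  veins <- label_volume(arr, diag(4))
  r <- lesion_vein_axis(lesion_vox, veins)
  expect_true(r$defined)
  expect_equal(r$n_voxels, 13L)
  expect_lt(axial_deg(r$axis, c(0, 0, 1)), 3)
  # moment oracle on the tube voxels
  tube <- cbind(4, 4, 0:12)
  or <- brute_force_moments(tube, diag(4))
  expect_lt(axial_deg(r$axis, or$vectors[, 1]), 1e-6)

  # two parallel tubes, 2 mm apart: pooled axis still the tube direction
  arr2 <- arr; arr2[7, 5, ] <- 1L
  r2 <- lesion_vein_axis(lesion_vox, label_volume(arr2, diag(4)))
  expect_lt(axial_deg(r2$axis, c(0, 0, 1)), 3)

  # fewer than 3 intersecting voxels: undefined, not an error
  arr3 <- array(0L, dim = c(9, 9, 13)); arr3[5, 5, 6:7] <- 1L
  r3 <- lesion_vein_axis(lesion_vox, label_volume(arr3, diag(4)))
  expect_false(r3$defined)
  expect_true("too_few_vein_voxels" %in% r3$qc)
})

test_that("orthogonal-to-vein axis projects the major axis into the vein plane", {
  z <- c(0, 0, 1); x <- c(1, 0, 0)
  expect_equal(orthogonal_vein_axis(z, x)$axis, x)
  expect_equal(orthogonal_vein_axis(z, c(1, 0, 1) / sqrt(2))$axis, x)
  # degenerate: major axis along the vein -> deterministic fallback, flagged
  rd <- orthogonal_vein_axis(z, z)
  expect_true("v90_degenerate" %in% rd$qc)
  expect_lt(abs(sum(rd$axis * z)), 1e-12)
  expect_equal(sqrt(sum(rd$axis^2)), 1, tolerance = 1e-12)
  expect_error(orthogonal_vein_axis(c(NA, NA, NA), x),
               class = "ldr_error_undefined_axis")
})

test_that("axis outputs are invariant to global sign flips of input fields", {
  vox <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  withr::with_seed(9, {
    for (i in 1:5) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      f <- constant_field(c(5, 5, 5), u, semantics = "gradient")
      fneg <- constant_field(c(5, 5, 5), -u, semantics = "gradient")
      expect_equal(lesion_tract_axis(vox, f)$axis,
                   lesion_tract_axis(vox, fneg)$axis)
    }
  })
})

test_that("tract and vein estimators agree on the same synthetic tube", {
  dims <- c(9, 9, 15)
  arr <- array(0L, dim = dims); arr[5, 5, 2:14] <- 1L
  veins <- label_volume(arr, diag(4))
  lesion_vox <- as.matrix(expand.grid(2:6, 2:6, 3:11))
  truth <- c(0, 0, 1)
  rv <- lesion_vein_axis(lesion_vox, veins)
  rt <- lesion_tract_axis(lesion_vox, constant_field(dims, truth, "axis"))
  expect_lt(axial_deg(rv$axis, truth), 3)
  expect_lt(axial_deg(rt$axis, truth), 3)
  expect_lt(axial_deg(rv$axis, rt$axis), 3)
})
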