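# fixtures and independent oracles built in code

# digitize a solid ellipsoid (semi-axes `semi` mm, rotation R, centre mm)
# on a grid with diagonal affine `voxel_mm`; returns 0-based voxel coords
digitize_ellipsoid <- function(semi, R = diag(3), centre = c(0, 0, 0),
                               voxel_mm = c(1, 1, 1), pad = 2) {
  half <- max(semi) + pad
  idx <- lapply(1:3, function(k) {
    seq(floor((centre[k] - half) / voxel_mm[k]),
        ceiling((centre[k] + half) / voxel_mm[k]))
  })
  grid <- as.matrix(expand.grid(idx[[1]], idx[[2]], idx[[3]]))
  world <- sweep(grid, 2, voxel_mm, `*`)
  loc <- sweep(world, 2, centre) %*% R
  inside <- (loc[, 1] / semi[1])^2 + (loc[, 2] / semi[2])^2 +
    (loc[, 3] / semi[3])^2 <= 1
  grid[inside, , drop = FALSE]
}

# brute-force second central moment matrix of world voxel centres,
# accumulated by explicit double loop (independent of the crossprod path)
brute_force_moments <- function(voxels, affine, voxel_moment = TRUE) {
  A3 <- affine[1:3, 1:3]
  n <- nrow(voxels)
  world <- matrix(0, n, 3)
  for (i in seq_len(n))
    world[i, ] <- (A3 %*% voxels[i, ] + affine[1:3, 4])[, 1]
  ctr <- colSums(world) / n
  C <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    d <- world[i, ] - ctr
    for (r in 1:3) for (s in 1:3) C[r, s] <- C[r, s] + d[r] * d[s]
  }
  C <- C / n
  if (voxel_moment) C <- C + (A3 %*% t(A3)) / 12
  eigen(C, symmetric = TRUE)
}

# embed 0-based voxel coords as a single-label volume on a grid that
# contains them (with margin), returning the label_volume and the shifted
# coords
as_label_volume <- function(voxels, voxel_mm = c(1, 1, 1), margin = 2L) {
  shift <- apply(voxels, 2, min) - margin
  v <- sweep(voxels, 2, shift)
  dims <- apply(v, 2, max) + margin + 1L
  arr <- array(0L, dim = dims)
  arr[v + 1L] <- 1L
  affine <- diag(c(voxel_mm, 1))
  affine[1:3, 4] <- shift * voxel_mm
  list(volume = label_volume(arr, affine), voxels = v, affine = affine)
}

# uniform-stretch displacement field u(x) = (S - I) x on a grid
stretch_field <- function(dims, S, voxel_mm = c(1, 1, 1)) {
  ax <- lapply(1:3, function(k) (seq_len(dims[k]) - 1) * voxel_mm[k])
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  u <- pts %*% t(S - diag(3))
  vector_volume(array(u, dim = c(dims, 3L)), diag(c(voxel_mm, 1)),
                semantics = "displacement")
}

# constant-vector field with given semantics
constant_field <- function(dims, v, semantics = "gradient",
                           voxel_mm = c(1, 1, 1)) {
  arr <- array(0, dim = c(dims, 3L))
  for (k in 1:3) arr[, , , k] <- v[k]
  vector_volume(arr, diag(c(voxel_mm, 1)), semantics = semantics)
}

# axial angle in degrees between two axes (independent tiny helper so
# tests do not route everything through the same code path under test)
axial_deg <- function(a, b) {
  acos(min(1, abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)))) * 180 / pi
}

# a random unit axis (independent of the package's sphere sampler)
sample_axes_for_test <- function(n) {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}
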