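# small geometry helpers shared across modules

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-300) ldr_abort("cannot normalize a zero vector", "ldr_error_zero_vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# rotation by `deg` degrees about unit axis k (Rodrigues)
rotation_about <- function(k, deg) {
  k <- unit(k)
  th <- deg * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# deterministic right-handed orthonormal basis with first column e1
complete_basis <- function(e1) {
  e1 <- unit(e1)
  i <- which.min(abs(e1))
  helper <- c(0, 0, 0); helper[i] <- 1
  e2 <- unit(cross3(e1, helper))
  e3 <- cross3(e1, e2)
  cbind(e1, e2, e3, deparse.level = 0)
}

# n uniformly distributed unit vectors on the sphere (rows)
sample_sphere <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# index a 4D vector array at an (n x 3) matrix of 0-based voxel coords,
# returning an n x 3 matrix of vectors
vectors_at <- function(field, voxels) {
  d <- dim(field$data)
  m <- vec_as_matrix(field$data)
  lin <- 1L + voxels[, 1] + d[1] * (voxels[, 2] + d[2] * voxels[, 3])
  m[lin, , drop = FALSE]
}

# index a 3D array at 0-based voxel coords
values_at <- function(data, voxels) {
  d <- dim(data)
  lin <- 1L + voxels[, 1] + d[1] * (voxels[, 2] + d[2] * voxels[, 3])
  data[lin]
}

deg <- function(rad) rad * 180 / pi
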