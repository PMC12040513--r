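#' @useDynLib lesiondir, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

ldr_abort <- function(msg, class) abort(msg, class = c(class, "lesiondir_error"))

# 3x3 voxel-to-world linear part
affine3 <- function(affine) affine[1:3, 1:3, drop = FALSE]

check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine)))
    ldr_abort("`affine` must be a finite 4x4 matrix", "ldr_error_affine")
  if (abs(det(affine3(affine))) < 1e-12)
    ldr_abort("voxel-to-world affine is not invertible", "ldr_error_affine")
  invisible(affine)
}

#' Image, label and vector volumes
#'
#' Light containers for co-registered 3D data: a scalar grid
#' (`image_volume`), an integer label grid (`label_volume`), or a grid of
#' per-voxel 3-vectors stored as a 4D array with the vector components on
#' the fourth axis (`vector_volume`). Every volume carries a 4x4
#' voxel-to-world affine in millimetres (RAS orientation, 0-based voxel
#' indices, NIfTI convention); all geometry downstream is computed in world
#' millimetres so that voxel anisotropy does not distort directions.
#'
#' Vector volumes carry a `semantics` tag:
#' \describe{
#'   \item{`"axis"`}{sign-free directions (eigenvector maps); each vector is
#'     an equivalence class \{u, -u\} and is stored with its
#'     largest-magnitude component non-negative. Unit norm or exactly zero
#'     (zero marks an undefined voxel).}
#'   \item{`"gradient"`}{signed unit directions with a consistent
#'     orientation (e.g. outward surface-in gradients); zero = undefined.}
#'   \item{`"displacement"`}{signed world-mm displacement vectors.}
#' }
#'
#' @param data 3D numeric array (4D `[X, Y, Z, 3]` for `vector_volume`).
#' @param affine 4x4 voxel-to-world matrix (mm); must be invertible.
#' @param units free-text unit tag, e.g. `"pu"`, `"mm"`, `"unitless"`.
#' @param semantics `"axis"`, `"gradient"` or `"displacement"`.
#' @param frame coordinate frame of the vectors; only `"world-mm"` is used
#'   by the pipeline.
#' @return An object of class `image_volume`, `label_volume` or
#'   `vector_volume` (all inherit from `ldr_volume`), a list with elements
#'   `data` and `affine` plus the metadata above.
#' @examples
#' vol <- image_volume(array(0, c(4, 4, 4)), diag(4))
#' dim(vol$data)
#' @export
image_volume <- function(data, affine, units = "unitless") {
  check_affine(affine)
  if (length(dim(data)) != 3L)
    ldr_abort("image_volume data must be a 3D array", "ldr_error_dim_mismatch")
  structure(list(data = data, affine = affine, units = units),
            class = c("image_volume", "ldr_volume"))
}

#' @rdname image_volume
#' @export
label_volume <- function(data, affine) {
  check_affine(affine)
  if (length(dim(data)) != 3L)
    ldr_abort("label_volume data must be a 3D array", "ldr_error_dim_mismatch")
  if (any(data < 0) || any(data != round(data)))
    ldr_abort("labels must be non-negative integers", "ldr_error_labels")
  storage.mode(data) <- "integer"
  structure(list(data = data, affine = affine),
            class = c("label_volume", "ldr_volume"))
}

#' @rdname image_volume
#' @export
vector_volume <- function(data, affine,
                          semantics = c("axis", "gradient", "displacement"),
                          frame = "world-mm") {
  check_affine(affine)
  semantics <- match.arg(semantics)
  d <- dim(data)
  if (length(d) != 4L || d[4] != 3L)
    ldr_abort("vector_volume data must be a 4D array with 3 components on the 4th axis",
              "ldr_error_dim_mismatch")
  if (semantics == "displacement" && !all(is.finite(data)))
    ldr_abort("displacement vectors must be finite", "ldr_error_values")
  if (semantics == "axis")
    data <- canonicalize_axis_field(data)
  structure(list(data = data, affine = affine, semantics = semantics, frame = frame),
            class = c("vector_volume", "ldr_volume"))
}

#' @export
print.ldr_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %s", class(x)[1], paste(d, collapse = " x ")))
  sp <- sqrt(colSums(affine3(x$affine)^2))
  cat(sprintf(" | voxel %s mm", paste(signif(sp, 3), collapse = " x ")))
  if (!is.null(x$semantics)) cat(" |", x$semantics)
  if (!is.null(x$units)) cat(" |", x$units)
  cat("\n")
  invisible(x)
}

# flatten the spatial dims of a 4D vector array to an (nvox x 3) matrix
vec_as_matrix <- function(data) {
  d <- dim(data)
  dim(data) <- c(prod(d[1:3]), 3L)
  data
}

canonicalize_axis_field <- function(data) {
  m <- vec_as_matrix(data)
  m <- canonical_axes(m)
  array(m, dim = dim(data))
}

#' Canonical sign representative of an axis
#'
#' Sign-free axes are stored with their largest-magnitude component
#' non-negative (first such component on exact ties), so that \{u, -u\}
#' always maps to the same vector before any comparison or averaging.
#'
#' @param v numeric length-3 vector (an axis; need not be unit norm).
#' @return The vector or its negation.
#' @export
canonical_axis <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

# row-wise canonical_axis for an n x 3 matrix
canonical_axes <- function(m) {
  i <- max.col(abs(m), ties.method = "first")
  s <- m[cbind(seq_len(nrow(m)), i)]
  m * ifelse(s < 0, -1, 1)
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/2 file into the container matching `expected_semantics`,
#' preserving the stored affine exactly. 4D files are accepted only for
#' vector semantics and must have exactly 3 components on the fourth axis.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param expected_semantics one of `"image"`, `"label"`, `"axis"`,
#'   `"gradient"`, `"displacement"`.
#' @param units unit tag attached to scalar images.
#' @return An [image_volume()], [label_volume()] or [vector_volume()].
#'   Failure modes raise distinct condition classes:
#'   `ldr_error_missing_file`, `ldr_error_dim_mismatch`, `ldr_error_affine`.
#' @seealso [write_volume()]
#' @export
read_volume <- function(path,
                        expected_semantics = c("image", "label", "axis",
                                               "gradient", "displacement"),
                        units = "unitless") {
  expected_semantics <- match.arg(expected_semantics)
  if (!file.exists(path))
    ldr_abort(sprintf("file not found: %s", path), "ldr_error_missing_file")
  img <- RNifti::readNifti(path)
  affine <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  affine <- matrix(as.numeric(affine), 4, 4)
  d <- dim(img)
  dat <- array(as.vector(img), dim = d) # plain array, no NIfTI attributes
  if (expected_semantics %in% c("image", "label")) {
    if (length(d) == 4L && d[4] == 1L) { dim(dat) <- d[1:3]; d <- d[1:3] }
    if (length(d) != 3L)
      ldr_abort(sprintf("expected a 3D volume, got %d dimensions", length(d)),
                "ldr_error_dim_mismatch")
    if (expected_semantics == "label") return(label_volume(dat, affine))
    return(image_volume(dat, affine, units = units))
  }
  if (length(d) != 4L || d[4] != 3L)
    ldr_abort(sprintf("expected a 4D volume with 3 components on axis 4, got [%s]",
                      paste(d, collapse = ", ")), "ldr_error_dim_mismatch")
  vector_volume(dat, affine, semantics = expected_semantics)
}

#' Write a volume to NIfTI
#'
#' Round-trips through [read_volume()] bit-exactly for the affine and
#' losslessly for the data (labels as int32, everything else as float64).
#'
#' @param vol an `ldr_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ldr_volume"))
  datatype <- if (inherits(vol, "label_volume")) "int32" else "double"
  img <- RNifti::asNifti(vol$data, datatype = datatype)
  # sform only: it stores the full matrix exactly (qform quantizes through
  # a quaternion + pixdim and cannot round-trip every affine bit-exact)
  RNifti::`sform<-`(img, structure(vol$affine, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Voxel/world coordinate mapping
#'
#' Maps 0-based voxel indices to world millimetres through the volume
#' affine (`world = A %*% c(voxel, 1)`), and back. When `dim` is supplied,
#' coordinates outside the grid raise an `ldr_error_out_of_grid` condition.
#'
#' @param voxels integer matrix (n x 3) of 0-based voxel indices, or a
#'   length-3 vector.
#' @param affine 4x4 voxel-to-world matrix.
#' @param dim optional grid dimensions for bounds checking.
#' @return n x 3 numeric matrix of world coordinates (mm).
#' @examples
#' resolve_to_world(c(3, 4, 5), diag(4))
#' @export
resolve_to_world <- function(voxels, affine, dim = NULL) {
  check_affine(affine)
  if (is.null(base::dim(voxels))) voxels <- matrix(voxels, ncol = 3)
  if (!is.null(dim)) {
    bad <- voxels < 0 | sweep(voxels, 2, dim, ">=")
    if (any(bad))
      ldr_abort("voxel coordinates outside the grid", "ldr_error_out_of_grid")
  }
  t(affine3(affine) %*% t(voxels) + affine[1:3, 4])
}

#' @rdname resolve_to_world
#' @param world numeric matrix (n x 3) of world coordinates (mm).
#' @export
world_to_voxel <- function(world, affine) {
  check_affine(affine)
  if (is.null(base::dim(world))) world <- matrix(world, ncol = 3)
  t(solve(affine3(affine)) %*% (t(world) - affine[1:3, 4]))
}

# world-mm voxel spacing along each grid axis
voxel_spacing <- function(affine) sqrt(colSums(affine3(affine)^2))

# world-mm volume of one voxel
voxel_volume <- function(affine) abs(det(affine3(affine)))

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data)[1:3], dim(b$data)[1:3]) &&
    max(abs(a$affine - b$affine)) < tol
}
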