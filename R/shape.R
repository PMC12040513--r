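#' Extract per-lesion voxel sets from a label volume
#'
#' Splits a labelled lesion mask into one voxel set per label and applies
#' the minimum-volume inclusion rule in world millimetres (default 3 mm^3,
#' the conventional floor for MS lesion analyses). Labels below the floor
#' are not dropped silently: they are returned in an `excluded` table with
#' their volume and reason. Connectivity is deliberately ignored — labels
#' are taken as given, so confluent lesions stay single objects.
#'
#' @param labels a [label_volume()].
#' @param min_volume minimum lesion volume in mm^3 (strictly smaller
#'   lesions are excluded).
#' @return A list with `lesions` (named list of n x 3 integer matrices of
#'   0-based voxel coordinates, names = label ids) and `excluded`
#'   (tibble: `lesion_id`, `n_voxels`, `volume_mm3`, `reason`).
#' @export
extract_lesions <- function(labels, min_volume = 3) {
  stopifnot(inherits(labels, "label_volume"))
  idx <- which(labels$data > 0L)
  if (length(idx) == 0L)
    ldr_abort("label volume contains no lesions", "ldr_error_empty_labels")
  vox <- arrayInd(idx, dim(labels$data)) - 1L
  ids <- labels$data[idx]
  vv <- voxel_volume(labels$affine)
  sets <- lapply(split(seq_along(ids), ids), function(i) vox[i, , drop = FALSE])
  nvox <- vapply(sets, nrow, integer(1))
  vol <- nvox * vv
  keep <- vol >= min_volume
  excluded <- tibble(
    lesion_id = as.integer(names(sets))[!keep],
    n_voxels = nvox[!keep],
    volume_mm3 = vol[!keep],
    reason = sprintf("volume %.3g mm^3 below minimum %.3g mm^3",
                     vol[!keep], min_volume)
  )
  list(lesions = sets[keep], excluded = excluded)
}

#' Ellipsoid summary of a lesion
#'
#' Summarizes a voxel set as a solid uniform ellipsoid: the centroid is the
#' mean of the world-mm voxel centres, the principal directions are the
#' eigenvectors of the 3x3 second central moment matrix of those centres,
#' and the principal axis *lengths* follow the solid-ellipsoid convention
#' `lambda_i = 2 * sqrt(5 * m_i)` relating moment eigenvalues `m_i` to full
#' axis lengths (the convention of the usual 3D region-properties
#' toolboxes). Each voxel additionally contributes the second moment of a
#' uniform cube of its own size (`(1/12) A3 A3^T` in world coordinates,
#' parallel-axis theorem), which keeps all three axis lengths strictly
#' positive for flat or single-voxel lesions; disable with
#' `voxel_moment = FALSE` to use bare voxel-centre moments.
#'
#' The first eigenvector `e1` (largest eigenvalue) is the lesion major
#' axis. When the top two axis lengths agree within 1% the major axis is
#' flagged `major_axis_ill_defined`: the lesion is still processed but any
#' angle to its major axis is noise.
#'
#' @param voxels n x 3 integer matrix of 0-based voxel coordinates.
#' @param affine 4x4 voxel-to-world matrix (mm).
#' @param voxel_moment add the per-voxel cube moment (default `TRUE`).
#' @return A list: `centroid` (mm), `lambda` (descending axis lengths, mm),
#'   `evecs` (3x3, columns = unit axes, sign-canonical), `moments`
#'   (descending moment eigenvalues), `volume_mm3`, `n_voxels`, `qc`
#'   (character vector of flags).
#' @export
fit_ellipsoid <- function(voxels, affine, voxel_moment = TRUE) {
  if (is.null(dim(voxels))) voxels <- matrix(voxels, ncol = 3)
  n <- nrow(voxels)
  if (n < 1L) ldr_abort("lesion has no voxels", "ldr_error_empty_lesion")
  qc <- character(0)
  if (n == 1L) qc <- c(qc, "single_voxel")
  w <- resolve_to_world(voxels, affine)
  centroid <- colMeans(w)
  cw <- sweep(w, 2, centroid)
  C <- crossprod(cw) / n
  if (voxel_moment) {
    A3 <- affine3(affine)
    C <- C + (A3 %*% t(A3)) / 12
  }
  eg <- eigen(C, symmetric = TRUE)
  m <- pmax(eg$values, 0)
  lambda <- 2 * sqrt(5 * m)
  evecs <- apply(eg$vectors, 2, canonical_axis)
  if (lambda[1] <= 0 || (lambda[1] - lambda[2]) / lambda[1] < 0.01)
    qc <- c(qc, "major_axis_ill_defined")
  list(centroid = centroid, lambda = lambda, evecs = evecs, moments = m,
       volume_mm3 = n * voxel_volume(affine), n_voxels = n, qc = qc)
}

#' Shape anisotropy from ellipsoid axis lengths
#'
#' Fractional-anisotropy-style scalar over the three principal axis
#' lengths, `sqrt(1/2) * sqrt(((l1-l2)^2 + (l2-l3)^2 + (l3-l1)^2) /
#' (l1^2 + l2^2 + l3^2))`: 0 for a sphere, approaching 1 for a
#' maximally elongated lesion. Invariant to any uniform scaling of the
#' axis lengths, so the choice of axis-length convention does not affect
#' it.
#'
#' @param lambda1,lambda2,lambda3 principal axis lengths, sorted
#'   descending, all positive. Vectorized.
#' @return Anisotropy in `[0, 1]`.
#' @examples
#' anisotropy(3, 2, 1)
#' @export
anisotropy <- function(lambda1, lambda2, lambda3) {
  if (any(lambda3 <= 0) || any(lambda1 < lambda2) || any(lambda2 < lambda3))
    ldr_abort("axis lengths must satisfy lambda1 >= lambda2 >= lambda3 > 0",
              "ldr_error_eigenvalues")
  sqrt(0.5) * sqrt((lambda1 - lambda2)^2 + (lambda2 - lambda3)^2 +
                     (lambda3 - lambda1)^2) /
    sqrt(lambda1^2 + lambda2^2 + lambda3^2)
}

#' Per-lesion shape table
#'
#' Runs [extract_lesions()], [fit_ellipsoid()] and [anisotropy()] over a
#' label volume and returns one tidy row per included lesion.
#'
#' @inheritParams extract_lesions
#' @param patient_id identifier copied into every row.
#' @param anisotropy_on `"axis_lengths"` (default) evaluates the
#'   anisotropy formula on the axis lengths; `"moments"` evaluates it on
#'   the raw moment eigenvalues (which differ by a square; the two give
#'   different numbers for the same lesion).
#' @param voxel_moment passed to [fit_ellipsoid()].
#' @return A tibble with columns `lesion_id`, `patient_id`, `n_voxels`,
#'   `volume_mm3`, `centroid_{x,y,z}_mm`, `lambda{1,2,3}_mm`,
#'   `e1_{x,y,z}` .. `e3_{x,y,z}`, `anisotropy`, `qc_flags`, plus an
#'   `excluded` attribute carrying the sub-threshold label table.
#' @export
lesion_shapes <- function(labels, min_volume = 3, patient_id = NA_character_,
                          anisotropy_on = c("axis_lengths", "moments"),
                          voxel_moment = TRUE) {
  anisotropy_on <- match.arg(anisotropy_on)
  ex <- extract_lesions(labels, min_volume = min_volume)
  rows <- purrr::imap(ex$lesions, function(vox, id) {
    f <- fit_ellipsoid(vox, labels$affine, voxel_moment = voxel_moment)
    a <- if (anisotropy_on == "axis_lengths") {
      anisotropy(f$lambda[1], f$lambda[2], f$lambda[3])
    } else {
      anisotropy(f$moments[1], f$moments[2], f$moments[3])
    }
    tibble(
      lesion_id = as.integer(id), patient_id = patient_id,
      n_voxels = f$n_voxels, volume_mm3 = f$volume_mm3,
      centroid_x_mm = f$centroid[1], centroid_y_mm = f$centroid[2],
      centroid_z_mm = f$centroid[3],
      lambda1_mm = f$lambda[1], lambda2_mm = f$lambda[2], lambda3_mm = f$lambda[3],
      e1_x = f$evecs[1, 1], e1_y = f$evecs[2, 1], e1_z = f$evecs[3, 1],
      e2_x = f$evecs[1, 2], e2_y = f$evecs[2, 2], e2_z = f$evecs[3, 2],
      e3_x = f$evecs[1, 3], e3_y = f$evecs[2, 3], e3_z = f$evecs[3, 3],
      anisotropy = a,
      qc_flags = paste(f$qc, collapse = ";")
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "excluded") <- ex$excluded
  out
}
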