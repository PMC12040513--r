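# finite differences along one axis of a 3D array, in voxel units:
# central differences in the interior, one-sided at the boundary slices
diff_axis <- function(a, axis) {
  d <- dim(a)
  n <- d[axis]
  if (n < 3L)
    ldr_abort("grid too small for finite differences (< 3 voxels along an axis)",
              "ldr_error_grid_too_small")
  up <- c(2:n, n)
  lo <- c(1L, 1:(n - 1L))
  g <- switch(axis,
              a[up, , , drop = FALSE] - a[lo, , , drop = FALSE],
              a[, up, , drop = FALSE] - a[, lo, , drop = FALSE],
              a[, , up, drop = FALSE] - a[, , lo, drop = FALSE])
  denom <- rep(2, n); denom[c(1L, n)] <- 1
  sweep(g, axis, denom, "/")
}

# Euclidean distance transform (mm) from the TRUE voxels of a 3D mask,
# measured between voxel centres with per-axis world spacing
distance_from_mask <- function(mask, affine) {
  sp <- voxel_spacing(affine)
  d <- .edt3d(as.logical(mask), as.integer(dim(mask)), as.numeric(sp))
  dim(d) <- dim(mask)
  d
}

# separable Gaussian smoothing of a 3D array, sigma in mm per axis;
# clamped (replicated) boundaries
gauss_smooth3 <- function(arr, affine, sigma_mm) {
  sp <- voxel_spacing(affine)
  for (axis in 1:3) {
    sv <- sigma_mm / sp[axis]
    if (sv <= 0) next
    r <- max(1L, ceiling(3 * sv))
    w <- stats::dnorm(-r:r, sd = sv)
    w <- w / sum(w)
    n <- dim(arr)[axis]
    acc <- array(0, dim(arr))
    for (j in -r:r) {
      sh <- pmin(pmax(seq_len(n) + j, 1L), n)
      acc <- acc + w[j + r + 1] * switch(axis,
                                         arr[sh, , , drop = FALSE],
                                         arr[, sh, , drop = FALSE],
                                         arr[, , sh, drop = FALSE])
    }
    arr <- acc
  }
  arr
}

#' Surface-in gradient field from a ventricle mask
#'
#' Computes, at every voxel outside the ventricles, the unit direction
#' orthogonal to the ventricular surface: the normalized world-coordinate
#' gradient of the Euclidean distance transform from the ventricle mask.
#' On the surface this equals the outward surface normal, and it remains
#' defined throughout the white matter, which is what per-lesion averaging
#' needs for lesions far from the ventricles. Voxels inside the mask, and
#' voxels where the gradient is numerically degenerate (ridges of the
#' distance map, where fronts from different parts of the surface collide
#' and the gradient norm collapses), carry the zero vector (= undefined).
#'
#' The result is signed — consistently outward from the ventricle — so
#' component-wise averaging within a lesion is well defined
#' ([lesion_gradient_axis()]).
#'
#' @param ventricles a [label_volume()] or [image_volume()]; voxels `> 0`
#'   form the ventricle mask.
#' @param degenerate_norm gradient-norm floor below which a voxel is
#'   marked undefined (the distance gradient has unit norm almost
#'   everywhere; 0.5 marks ridge voxels without touching smooth regions).
#' @param smooth_sigma_mm Gaussian smoothing of the distance map before
#'   differentiation (mm; 0 disables). The raw transform measures
#'   distance to discrete surface voxel centres, which quantizes gradient
#'   directions by several degrees; two voxels' worth of smoothing
#'   restores smooth normals without displacing them (symmetric kernels
#'   leave planar and spherical surface normals unbiased).
#' @return A [vector_volume()] with `"gradient"` semantics.
#' @export
surface_in_field <- function(ventricles, degenerate_norm = 0.5,
                             smooth_sigma_mm = 2) {
  stopifnot(inherits(ventricles, "ldr_volume"))
  mask <- ventricles$data > 0
  if (!any(mask))
    ldr_abort("ventricle mask is empty", "ldr_error_empty_mask")
  dist <- distance_from_mask(mask, ventricles$affine)
  if (smooth_sigma_mm > 0)
    dist <- gauss_smooth3(dist, ventricles$affine, smooth_sigma_mm)
  gx <- diff_axis(dist, 1L); gy <- diff_axis(dist, 2L); gz <- diff_axis(dist, 3L)
  # chain rule: grad in world = A^{-T} grad in voxel index units
  Ainv <- solve(affine3(ventricles$affine))
  G <- cbind(as.vector(gx), as.vector(gy), as.vector(gz)) %*% Ainv
  nrm <- sqrt(rowSums(G^2))
  ok <- nrm >= degenerate_norm & !as.vector(mask)
  G[ok, ] <- G[ok, , drop = FALSE] / nrm[ok]
  G[!ok, ] <- 0
  vector_volume(array(G, dim = c(dim(dist), 3L)), ventricles$affine,
                semantics = "gradient")
}

# uniform S3-ish return for the per-lesion axis estimators
lesion_axis_result <- function(axis, defined, qc = character(0), n_voxels = 0L,
                               dispersion = NA_real_) {
  list(axis = if (defined) canonical_axis(axis) else c(NA_real_, NA_real_, NA_real_),
       defined = defined, qc = qc, n_voxels = as.integer(n_voxels),
       dispersion = dispersion)
}

#' Per-lesion surface-in gradient axis
#'
#' Component-wise mean of the signed (outward) surface-in gradient vectors
#' over the lesion voxels, renormalized. Signed averaging is appropriate
#' here — and only here — because the distance-transform gradient has a
#' consistent outward orientation; a short mean vector means the lesion
#' straddles directions that nearly cancel, and the axis is reported
#' undefined with a `high_dispersion` flag.
#'
#' @param voxels n x 3 integer matrix of 0-based lesion voxel coordinates.
#' @param field the [surface_in_field()] output.
#' @param min_mean_norm mean-vector norm below which the axis is declared
#'   undefined (default 0.2).
#' @return A list: `axis` (unit, sign-canonical, or `NA`s), `defined`,
#'   `qc`, `n_voxels` (voxels with a defined field value), `dispersion`
#'   (`1 - mean vector norm`).
#' @export
lesion_gradient_axis <- function(voxels, field, min_mean_norm = 0.2) {
  stopifnot(inherits(field, "vector_volume"))
  u <- vectors_at(field, voxels)
  ok <- rowSums(u^2) > 1e-12
  if (!any(ok))
    ldr_abort("no defined surface-in gradient voxels inside the lesion",
              "ldr_error_no_field_values")
  m <- colMeans(u[ok, , drop = FALSE])
  nm <- vnorm(m)
  if (nm < min_mean_norm)
    return(lesion_axis_result(NULL, FALSE, qc = "high_dispersion",
                              n_voxels = sum(ok), dispersion = 1 - nm))
  lesion_axis_result(m / nm, TRUE, n_voxels = sum(ok), dispersion = 1 - nm)
}

# principal eigenvector of the dyadic (orientation) tensor sum w_i u_i u_i^T
dyadic_principal <- function(u, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(u))
  T <- crossprod(u * sqrt(weights))
  eg <- eigen(T, symmetric = TRUE)
  list(axis = canonical_axis(eg$vectors[, 1]), values = eg$values)
}

#' Per-lesion white-matter tract axis
#'
#' Dominant fibre direction over the lesion: the principal eigenvector of
#' the orientation (dyadic) tensor `sum_i u_i u_i^T` of the nonzero tract
#' vectors at the lesion voxels. DTI primary eigenvectors carry arbitrary
#' signs, so component-wise averaging would be ill-defined; the dyadic
#' tensor is sign-free by construction. When the tensor's top two
#' eigenvalues differ by less than 20% (relative), no single direction
#' dominates and a `crossing_fibres` flag is set (the axis is still
#' returned).
#'
#' @param voxels n x 3 integer matrix of 0-based lesion voxel coordinates.
#' @param tract_field a [vector_volume()] with `"axis"` semantics (zero
#'   vectors = no fibre estimate at that voxel).
#' @param crossing_tol relative eigenvalue gap below which the
#'   crossing-fibre flag is raised (default 0.2).
#' @return As [lesion_gradient_axis()]; `dispersion` is the relative gap
#'   `(ev1 - ev2) / ev1`.
#' @export
lesion_tract_axis <- function(voxels, tract_field, crossing_tol = 0.2) {
  stopifnot(inherits(tract_field, "vector_volume"))
  u <- vectors_at(tract_field, voxels)
  ok <- rowSums(u^2) > 1e-12
  if (!any(ok))
    ldr_abort("no nonzero tract vectors inside the lesion",
              "ldr_error_no_field_values")
  dp <- dyadic_principal(u[ok, , drop = FALSE])
  gap <- (dp$values[1] - dp$values[2]) / dp$values[1]
  qc <- if (gap < crossing_tol) "crossing_fibres" else character(0)
  lesion_axis_result(dp$axis, TRUE, qc = qc, n_voxels = sum(ok),
                     dispersion = gap)
}

#' Per-lesion vein axis
#'
#' Intersects the lesion voxel set with the binarized vein mask and, when
#' at least `min_voxels` vein voxels fall inside the lesion, returns the
#' principal axis of the pooled intersecting vein voxels via the same
#' second-central-moment eigen-decomposition used for lesion shape.
#' Fewer intersecting voxels cannot determine a line direction above
#' discretization noise, so the axis is reported undefined — such lesions
#' are excluded from vein-dependent classification downstream, mirroring
#' the exclusion of lesions whose vein direction cannot be assessed.
#'
#' @param voxels n x 3 integer matrix of 0-based lesion voxel coordinates.
#' @param veins a [label_volume()] or [image_volume()]; voxels `> 0` are
#'   vein.
#' @param min_voxels minimum intersecting vein voxels (default 3).
#' @return As [lesion_gradient_axis()]; `n_voxels` is the vein voxel
#'   count; undefined is a valid outcome, not an error.
#' @export
lesion_vein_axis <- function(voxels, veins, min_voxels = 3L) {
  stopifnot(inherits(veins, "ldr_volume"))
  inside <- values_at(veins$data, voxels) > 0
  n <- sum(inside)
  if (n < min_voxels)
    return(lesion_axis_result(NULL, FALSE, qc = "too_few_vein_voxels",
                              n_voxels = n))
  f <- fit_ellipsoid(voxels[inside, , drop = FALSE], veins$affine)
  lesion_axis_result(f$evecs[, 1], TRUE, n_voxels = n,
                     dispersion = (f$moments[1] - f$moments[2]) /
                       max(f$moments[1], 1e-300))
}

#' Orthogonal-to-vein axis
#'
#' Constructs the axis perpendicular to the vein used to test whether a
#' lesion (or its expansion) runs across, rather than along, its vein.
#' The default construction projects the reference axis (normally the
#' lesion major axis) onto the plane orthogonal to the vein axis and
#' renormalizes: the unique in-plane direction nearest the reference
#' axis. When the reference axis is parallel to the vein within
#' `parallel_tol_deg` the projection is degenerate; a fixed deterministic
#' in-plane axis (`v x e`, `e` = canonical basis vector least aligned
#' with `v`) is returned with a `v90_degenerate` flag.
#'
#' @param v unit vein axis.
#' @param e1 unit reference axis (lesion major axis or expansion axis).
#' @param parallel_tol_deg degeneracy tolerance in degrees (default 1).
#' @return A list: `axis` (unit, orthogonal to `v` to machine precision),
#'   `defined`, `qc`.
#' @export
orthogonal_vein_axis <- function(v, e1, parallel_tol_deg = 1) {
  if (is.null(v) || any(!is.finite(v)))
    ldr_abort("vein axis is undefined", "ldr_error_undefined_axis")
  if (is.null(e1) || any(!is.finite(e1)))
    ldr_abort("reference axis is undefined", "ldr_error_undefined_axis")
  v <- unit(v)
  e1 <- unit(e1)
  if (abs(sum(v * e1)) > cos(parallel_tol_deg * pi / 180)) {
    i <- which.min(abs(v))
    e <- c(0, 0, 0); e[i] <- 1
    return(lesion_axis_result(unit(cross3(v, e)), TRUE, qc = "v90_degenerate"))
  }
  p <- e1 - sum(e1 * v) * v
  lesion_axis_result(unit(p), TRUE)
}

#' Per-lesion feature-axis table
#'
#' Computes, for every included lesion, the four reference axes the
#' directional taxonomy compares against: `g` (surface-in gradient), `w`
#' (white-matter tract), `v` (vein) and `v90` (orthogonal-to-vein,
#' constructed from the lesion major axis). Any axis can be undefined;
#' `v90` is defined exactly when `v` is.
#'
#' @param labels a [label_volume()] of lesion ids.
#' @param shapes the [lesion_shapes()] table (provides each lesion's major
#'   axis for the `v90` construction).
#' @param ventricles ventricle mask volume, or `NULL` to skip `g`.
#' @param tract_field tract axis [vector_volume()], or `NULL` to skip `w`.
#' @param veins vein mask volume, or `NULL` to skip `v`/`v90`.
#' @param min_volume same inclusion rule as [lesion_shapes()].
#' @param min_vein_voxels passed to [lesion_vein_axis()].
#' @param surface_field optionally a precomputed [surface_in_field()].
#' @return A tibble with one row per lesion: `{g,w,v,v90}_{x,y,z}`,
#'   `{g,w,v,v90}_defined`, `{g,w,v,v90}_qc`, `vein_voxel_count`.
#' @export
feature_axes <- function(labels, shapes, ventricles = NULL, tract_field = NULL,
                         veins = NULL, min_volume = 3, min_vein_voxels = 3L,
                         surface_field = NULL) {
  ex <- extract_lesions(labels, min_volume = min_volume)
  if (is.null(surface_field) && !is.null(ventricles))
    surface_field <- surface_in_field(ventricles)
  e1m <- as.matrix(shapes[, c("e1_x", "e1_y", "e1_z")])
  rownames(e1m) <- shapes$lesion_id
  rows <- purrr::imap(ex$lesions, function(vox, id) {
    g <- if (!is.null(surface_field)) {
      tryCatch(lesion_gradient_axis(vox, surface_field),
               ldr_error_no_field_values = function(e)
                 lesion_axis_result(NULL, FALSE, qc = "no_field_values"))
    } else lesion_axis_result(NULL, FALSE, qc = "not_computed")
    w <- if (!is.null(tract_field)) {
      tryCatch(lesion_tract_axis(vox, tract_field),
               ldr_error_no_field_values = function(e)
                 lesion_axis_result(NULL, FALSE, qc = "no_field_values"))
    } else lesion_axis_result(NULL, FALSE, qc = "not_computed")
    v <- if (!is.null(veins)) {
      lesion_vein_axis(vox, veins, min_voxels = min_vein_voxels)
    } else lesion_axis_result(NULL, FALSE, qc = "not_computed")
    v90 <- if (v$defined && id %in% rownames(e1m)) {
      orthogonal_vein_axis(v$axis, e1m[id, ])
    } else lesion_axis_result(NULL, FALSE, qc = "vein_undefined")
    tibble(
      lesion_id = as.integer(id),
      g_x = g$axis[1], g_y = g$axis[2], g_z = g$axis[3],
      g_defined = g$defined, g_qc = paste(g$qc, collapse = ";"),
      w_x = w$axis[1], w_y = w$axis[2], w_z = w$axis[3],
      w_defined = w$defined, w_qc = paste(w$qc, collapse = ";"),
      v_x = v$axis[1], v_y = v$axis[2], v_z = v$axis[3],
      v_defined = v$defined, v_qc = paste(v$qc, collapse = ";"),
      vein_voxel_count = v$n_voxels,
      v90_x = v90$axis[1], v90_y = v90$axis[2], v90_z = v90$axis[3],
      v90_defined = v90$defined, v90_qc = paste(v90$qc, collapse = ";")
    )
  })
  dplyr::bind_rows(rows)
}
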