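#' Magnetization transfer ratio map
#'
#' Voxelwise `((MToff - MTon) / MToff) * 100`, in percentage units (pu).
#' Voxels where the MT-off signal is not strictly positive have no defined
#' ratio; they are set to `NA` (not an error) and counted. Values outside
#' the physically plausible `[-10, 100]` pu band are counted as suspect
#' acquisition artefacts but deliberately not clipped.
#'
#' @param mt_off,mt_on co-registered [image_volume()]s on the same grid.
#' @return An [image_volume()] with `units = "pu"` and attributes
#'   `n_undefined` (MToff <= 0 voxels) and `n_out_of_range`.
#' @examples
#' off <- image_volume(array(1, c(3, 3, 3)), diag(4))
#' on <- image_volume(array(0.6, c(3, 3, 3)), diag(4))
#' compute_mtr(off, on)$data[1] # 40
#' @export
compute_mtr <- function(mt_off, mt_on) {
  stopifnot(inherits(mt_off, "image_volume"), inherits(mt_on, "image_volume"))
  if (!same_grid(mt_off, mt_on))
    ldr_abort("MT-on and MT-off are not on the same grid", "ldr_error_grid_mismatch")
  off <- mt_off$data
  mtr <- (off - mt_on$data) / off * 100
  undef <- off <= 0
  mtr[undef] <- NA_real_
  out <- image_volume(mtr, mt_off$affine, units = "pu")
  attr(out, "n_undefined") <- sum(undef)
  attr(out, "n_out_of_range") <- sum(mtr < -10 | mtr > 100, na.rm = TRUE)
  out
}

#' Jacobian determinant of a displacement field
#'
#' Local volume-change factor `det(I + du/dx)` of the mapping
#' `x -> x + u(x)`, with the displacement gradient taken by central
#' differences (one-sided at grid boundaries) in world coordinates, the
#' standard tensor-based-morphometry stencil. Values above 1 mark local
#' expansion of baseline tissue between the two timepoints, below 1
#' contraction; a rigid translation of the whole field changes nothing.
#'
#' @param displacement a [vector_volume()] with `"displacement"`
#'   semantics: world-mm displacement vectors on the baseline grid.
#' @return A unitless [image_volume()] of the same shape.
#' @export
jacobian_determinant <- function(displacement) {
  stopifnot(inherits(displacement, "vector_volume"))
  if (displacement$semantics != "displacement")
    ldr_abort("expected a displacement-semantics vector volume",
              "ldr_error_semantics")
  d <- dim(displacement$data)
  if (any(d[1:3] < 3L))
    ldr_abort("grid too small for finite differences (< 3 voxels along an axis)",
              "ldr_error_grid_too_small")
  Ainv <- solve(affine3(displacement$affine))
  # F[i][j] = d(x_i + u_i)/d(world_j), accumulated as flat vectors
  nvox <- prod(d[1:3])
  F <- vector("list", 9)
  for (i in 1:3) {
    ui <- displacement$data[, , , i]
    gv <- cbind(as.vector(diff_axis(ui, 1L)),
                as.vector(diff_axis(ui, 2L)),
                as.vector(diff_axis(ui, 3L))) %*% Ainv
    for (j in 1:3)
      F[[(i - 1) * 3 + j]] <- gv[, j] + (i == j)
  }
  detv <- F[[1]] * (F[[5]] * F[[9]] - F[[6]] * F[[8]]) -
    F[[2]] * (F[[4]] * F[[9]] - F[[6]] * F[[7]]) +
    F[[3]] * (F[[4]] * F[[8]] - F[[5]] * F[[7]])
  image_volume(array(detv, dim = d[1:3]), displacement$affine,
               units = "unitless")
}

#' Expansion/contraction classes from lesion-mean Jacobians
#'
#' Applies the cohort-level dispersion rule: a lesion is `expanding` when
#' its mean Jacobian determinant is at least `k` standard deviations above
#' the mean over all included lesions of the whole cohort (pooled across
#' patients, not per patient), `contracting` when at least `k` SD below,
#' `stable` otherwise. With `k = 1` and a 6-month interval this cut
#' corresponds, in the motivating cohort, to roughly an 8% volume change.
#' A lesion exactly at the cohort mean is `stable` for any `k` (at
#' `k = 0` it is the only stable lesion). A zero-variance cohort is all
#' stable, with a warning.
#'
#' @param mean_jacobian numeric vector of per-lesion mean Jacobian
#'   determinants (>= 2 lesions).
#' @param k SD multiplier (default 1).
#' @return Factor with levels `contracting`, `stable`, `expanding`, plus
#'   attributes `mu`, `sigma`, `cut_low`, `cut_high`.
#' @export
classify_dynamics <- function(mean_jacobian, k = 1) {
  if (length(mean_jacobian) < 2L)
    ldr_abort("need at least 2 lesions to estimate the cohort dispersion",
              "ldr_error_cohort_too_small")
  mu <- mean(mean_jacobian)
  sigma <- stats::sd(mean_jacobian)
  if (sigma == 0) {
    warn("zero-variance cohort: all lesions classified stable")
    cls <- rep("stable", length(mean_jacobian))
  } else {
    hi <- mean_jacobian >= mu + k * sigma
    lo <- mean_jacobian <= mu - k * sigma
    cls <- ifelse(hi & lo, "stable", # only at k = 0 on the exact mean
                  ifelse(hi, "expanding", ifelse(lo, "contracting", "stable")))
  }
  structure(factor(cls, levels = c("contracting", "stable", "expanding")),
            mu = mu, sigma = sigma,
            cut_low = mu - k * sigma, cut_high = mu + k * sigma)
}

#' Major axis of expansion within a lesion
#'
#' Direction along which the deformation acts on the lesion: the lesion-
#' mean displacement (bulk motion and registration drift) is subtracted
#' first, then the principal eigenvector of the magnitude-weighted
#' orientation tensor `sum_i ||u_i|| u_hat_i u_hat_i^T` of the residual
#' displacements is taken (sign-free, so opposite-moving lesion ends
#' reinforce rather than cancel). When the tensor's top two eigenvalues
#' agree within `ratio_tol` (relative) there is no dominant direction —
#' e.g. isotropic radial growth — and the axis is undefined with a
#' `no_dominant_direction` flag.
#'
#' @param voxels n x 3 integer matrix of 0-based lesion voxel coordinates
#'   (>= 3 voxels).
#' @param displacement displacement [vector_volume()].
#' @param center subtract the lesion-mean displacement first (default
#'   `TRUE`).
#' @param ratio_tol relative eigenvalue-gap floor (default 0.1).
#' @return As [lesion_gradient_axis()]: `axis`, `defined`, `qc`,
#'   `n_voxels`, `dispersion` (the relative gap).
#' @export
expansion_axis <- function(voxels, displacement, center = TRUE,
                           ratio_tol = 0.1) {
  stopifnot(inherits(displacement, "vector_volume"))
  if (nrow(voxels) < 3L)
    ldr_abort("need at least 3 lesion voxels with defined displacement",
              "ldr_error_too_few_voxels")
  u <- vectors_at(displacement, voxels)
  if (center) u <- sweep(u, 2, colMeans(u))
  nrm <- sqrt(rowSums(u^2))
  ok <- nrm > 1e-12
  if (!any(ok))
    ldr_abort("all residual displacements are zero within the lesion",
              "ldr_error_zero_displacement")
  # sum ||u|| u_hat u_hat^T = sum u u^T / ||u||
  dp <- dyadic_principal(u[ok, , drop = FALSE], weights = 1 / nrm[ok])
  gap <- (dp$values[1] - dp$values[2]) / dp$values[1]
  if (gap < ratio_tol)
    return(lesion_axis_result(NULL, FALSE, qc = "no_dominant_direction",
                              n_voxels = sum(ok), dispersion = gap))
  lesion_axis_result(dp$axis, TRUE, n_voxels = sum(ok), dispersion = gap)
}

#' Classify the direction of lesion change
#'
#' Identical contract to [classify_lesion()], applied to the expansion
#' (or contraction) axis instead of the lesion major axis. The
#' orthogonal-to-vein axis is reconstructed from the axis being
#' classified (projection construction), so "expansion orthogonal to the
#' vein" is measured in the plane direction nearest the actual expansion.
#'
#' @param axis unit expansion axis.
#' @param g,w,v feature axes (`NULL` = undefined).
#' @inheritParams classify_lesion
#' @return As [classify_lesion()].
#' @export
classify_change_direction <- function(axis, g = NULL, w = NULL, v = NULL,
                                      threshold = 45,
                                      v90_mode = c("projection", "plane")) {
  v90_mode <- match.arg(v90_mode)
  if (is.null(axis) || any(!is.finite(axis)))
    ldr_abort("cannot classify an undefined axis", "ldr_error_undefined_axis")
  v90 <- NULL
  if (!is.null(v) && all(is.finite(v)) && v90_mode == "projection")
    v90 <- orthogonal_vein_axis(v, axis)$axis
  classify_lesion(axis, g = g, w = w, v = v, v90 = v90,
                  threshold = threshold, v90_mode = v90_mode)
}

#' Mean MTR change within a lesion
#'
#' Difference of the lesion-mean MTR between follow-up and baseline,
#' computed over the baseline lesion voxels where both maps are defined.
#' Positive values are conventionally read as remyelination.
#'
#' @param mtr_baseline,mtr_followup MTR [image_volume()]s (pu) on the
#'   same grid.
#' @param voxels n x 3 integer matrix of 0-based baseline lesion voxels.
#' @return A list: `delta_mtr` (pu), `mean_baseline`, `mean_followup`,
#'   `n_voxels` used.
#' @export
lesion_mtr_change <- function(mtr_baseline, mtr_followup, voxels) {
  stopifnot(inherits(mtr_baseline, "image_volume"),
            inherits(mtr_followup, "image_volume"))
  if (!same_grid(mtr_baseline, mtr_followup))
    ldr_abort("MTR maps are not on the same grid", "ldr_error_grid_mismatch")
  b <- values_at(mtr_baseline$data, voxels)
  f <- values_at(mtr_followup$data, voxels)
  ok <- is.finite(b) & is.finite(f)
  if (!any(ok))
    ldr_abort("no voxels with defined MTR at both timepoints",
              "ldr_error_no_field_values")
  list(delta_mtr = mean(f[ok]) - mean(b[ok]),
       mean_baseline = mean(b[ok]), mean_followup = mean(f[ok]),
       n_voxels = sum(ok))
}

#' Per-lesion longitudinal table
#'
#' Computes, for every included lesion: the mean Jacobian determinant
#' over its baseline voxels, the expansion axis and its alignment
#' category against the lesion's feature axes, and the MTR change.
#' Expansion/contraction *classes* need the whole cohort's dispersion and
#' are added later by [analyze_cohort()] (or directly via
#' [classify_dynamics()]).
#'
#' @param labels baseline lesion [label_volume()].
#' @param displacement displacement [vector_volume()] (world mm, baseline
#'   grid).
#' @param axes [feature_axes()] table.
#' @param mtr_baseline,mtr_followup optional MTR [image_volume()]s.
#' @inheritParams classify_lesion
#' @param min_volume inclusion rule as in [lesion_shapes()].
#' @return A tibble: `lesion_id`, `mean_jacobian`,
#'   `exp_{x,y,z}`, `exp_defined`, `exp_qc`, `direction_category`,
#'   `direction_excluded`, `delta_mtr`, `mtr_baseline`, `mtr_followup`.
#' @export
lesion_dynamics <- function(labels, displacement, axes,
                            mtr_baseline = NULL, mtr_followup = NULL,
                            threshold = 45, min_volume = 3,
                            v90_mode = c("projection", "plane")) {
  v90_mode <- match.arg(v90_mode)
  ex <- extract_lesions(labels, min_volume = min_volume)
  jac <- jacobian_determinant(displacement)
  axm <- axes
  rows <- purrr::imap(ex$lesions, function(vox, id) {
    mj <- mean(values_at(jac$data, vox))
    ea <- tryCatch(expansion_axis(vox, displacement),
                   ldr_error_zero_displacement = function(e)
                     lesion_axis_result(NULL, FALSE, qc = "zero_displacement"),
                   ldr_error_too_few_voxels = function(e)
                     lesion_axis_result(NULL, FALSE, qc = "too_few_voxels"))
    arow <- axm[axm$lesion_id == as.integer(id), ]
    dircat <- NA_character_
    direxcl <- NA
    if (ea$defined && nrow(arow) == 1L) {
      cl <- classify_change_direction(
        ea$axis,
        g = if (arow$g_defined) c(arow$g_x, arow$g_y, arow$g_z),
        w = if (arow$w_defined) c(arow$w_x, arow$w_y, arow$w_z),
        v = if (arow$v_defined) c(arow$v_x, arow$v_y, arow$v_z),
        threshold = threshold, v90_mode = v90_mode)
      dircat <- cl$category
      direxcl <- cl$excluded
    }
    dm <- list(delta_mtr = NA_real_, mean_baseline = NA_real_,
               mean_followup = NA_real_)
    if (!is.null(mtr_baseline) && !is.null(mtr_followup))
      dm <- lesion_mtr_change(mtr_baseline, mtr_followup, vox)
    tibble(lesion_id = as.integer(id), mean_jacobian = mj,
           exp_x = ea$axis[1], exp_y = ea$axis[2], exp_z = ea$axis[3],
           exp_defined = ea$defined, exp_qc = paste(ea$qc, collapse = ";"),
           direction_category = dircat, direction_excluded = direxcl,
           delta_mtr = dm$delta_mtr, mtr_baseline = dm$mean_baseline,
           mtr_followup = dm$mean_followup)
  })
  dplyr::bind_rows(rows)
}
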