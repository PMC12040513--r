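#' Intended categories the phantom generator can realize
#'
#' With the default orthogonal-to-vein construction every vein-defined
#' lesion is forced to align with V or V90 at the 45-degree rule (see
#' [phantom_spec()]), so realizable intents are the eight categories
#' containing V or V90 plus `"EXCLUDED"` (no vein).
#'
#' @return Character vector of allowed intent labels.
#' @export
realizable_categories <- function() {
  c("V", "GV", "WV", "GWV", "V90", "GV90", "WV90", "GWV90", "EXCLUDED")
}

#' Specification of a synthetic phantom
#'
#' Describes one synthetic "patient": a 3D grid with a spherical (or slab)
#' ventricle, one vein tube per lesion, a piecewise-uniform tract axis
#' field, digitized ellipsoidal lesions with prescribed orientation
#' categories, an analytic deformation field with prescribed per-lesion
#' volume ratios, and MT image pairs at two timepoints with prescribed
#' per-lesion MTR change. Everything downstream of the seed is
#' deterministic: the same spec builds bit-identical volumes.
#'
#' Because the orthogonal-to-vein axis is constructed in the plane
#' perpendicular to the vein and nearest the lesion major axis, the angle
#' to the vein and the angle to that axis always sum to 90 degrees: any
#' lesion with a measurable vein is geometrically forced to align with V
#' or V90 at the 45-degree rule. Intended categories must therefore
#' contain V or V90, or be `"EXCLUDED"` (no vein drawn, mimicking lesions
#' whose vein direction cannot be assessed); anything else is rejected at
#' validation time as unrealizable.
#'
#' @param patient_id identifier.
#' @param n_lesions number of lesions; defaults to the length of
#'   `categories`.
#' @param categories intended category per lesion, from
#'   `realizable_categories()` (recycled if scalar).
#' @param dynamics intended class per lesion: `"expanding"`, `"stable"`,
#'   `"contracting"` (recycled).
#' @param volume_ratio intended 6-month lesion volume ratio per lesion;
#'   defaults to 1.08 / 1 / 0.92 by dynamics class (the volume change
#'   that a 1-SD Jacobian cut corresponds to over 6 months).
#' @param delta_mtr intended MTR change per lesion, pu (recycled).
#' @param arm treatment arm tag.
#' @param grid,voxel_mm grid dimensions and voxel size (mm).
#' @param ventricle `list(type = "sphere", centre_mm =, radius_mm =)` or
#'   `list(type = "slab", z_mm =)` (ventricle fills `z <= z_mm`).
#' @param tract_default_axis tract axis outside lesion neighbourhoods.
#' @param minor_axis_mm range for the two minor ellipsoid semi-axes (mm).
#' @param axis_ratio range of major/minor semi-axis ratio (kept >= 2 so
#'   the major axis is always well defined).
#' @param vein_radius_mm,vein_length_mm vein tube geometry.
#' @param margin_deg minimum angular margin between every true feature
#'   angle and the 45-degree decision boundary (default 12).
#' @param lattice_pitch_mm spacing of candidate lesion centres; must
#'   exceed twice the deformation support radius so per-lesion
#'   deformations never overlap.
#' @param mtr_wm_pu,mtr_lesion_pu baseline MTR of normal-appearing tissue
#'   and of lesion tissue (pu).
#' @param deformation `list(r_in =, r_out =, translation =)`: each
#'   lesion's stretch is exact (constant gradient) within `r_in` mm of its
#'   centre, tapers to zero by `r_out`, plus a global rigid translation
#'   (mm) applied everywhere.
#' @param noise_sd Gaussian noise SD added to the MT images only
#'   (geometry stays noise-free; default 0).
#' @param threshold_deg the alignment threshold the intended categories
#'   are defined against (45).
#' @param seed integer seed; fixed seed implies a bit-identical phantom.
#' @return A `phantom_spec` list, validated.
#' @export
phantom_spec <- function(patient_id = "P01",
                         n_lesions = NULL,
                         categories = "V",
                         dynamics = "stable",
                         volume_ratio = NULL,
                         delta_mtr = 0,
                         arm = "placebo",
                         grid = c(96L, 96L, 96L),
                         voxel_mm = c(1, 1, 1),
                         ventricle = list(type = "sphere", centre_mm = NULL,
                                          radius_mm = 8),
                         tract_default_axis = c(0, 0, 1),
                         minor_axis_mm = c(2.0, 2.4),
                         axis_ratio = c(2.5, 3.0),
                         vein_radius_mm = 0.8,
                         vein_length_mm = 18,
                         margin_deg = 12,
                         lattice_pitch_mm = 24,
                         mtr_wm_pu = 30,
                         mtr_lesion_pu = 25,
                         deformation = list(r_in = 9, r_out = 11,
                                            translation = c(0, 0, 0)),
                         noise_sd = 0,
                         threshold_deg = 45,
                         seed = 1L) {
  if (is.null(n_lesions)) n_lesions <- length(categories)
  categories <- rep_len(as.character(categories), n_lesions)
  dynamics <- rep_len(as.character(dynamics), n_lesions)
  delta_mtr <- rep_len(as.numeric(delta_mtr), n_lesions)
  bad <- setdiff(unique(categories), realizable_categories())
  if (length(bad) > 0)
    ldr_abort(sprintf(
      paste("unrealizable intended categor%s: %s (with a defined vein the",
            "orthogonal-to-vein construction forces alignment with V or V90",
            "at the 45-degree rule; allowed: %s)"),
      if (length(bad) > 1) "ies" else "y", paste(bad, collapse = ", "),
      paste(realizable_categories(), collapse = ", ")),
      "ldr_error_unrealizable_category")
  if (!all(dynamics %in% c("expanding", "stable", "contracting")))
    ldr_abort("dynamics must be expanding/stable/contracting",
              "ldr_error_bad_spec")
  if (is.null(volume_ratio))
    volume_ratio <- c(expanding = 1.08, stable = 1, contracting = 0.92)[dynamics]
  volume_ratio <- unname(rep_len(as.numeric(volume_ratio), n_lesions))
  if (any(volume_ratio <= 0)) ldr_abort("volume ratios must be positive",
                                        "ldr_error_bad_spec")
  if (is.null(ventricle$centre_mm) && identical(ventricle$type, "sphere"))
    ventricle$centre_mm <- grid * voxel_mm / 2
  if (lattice_pitch_mm <= 2 * deformation$r_out)
    ldr_abort("lattice pitch must exceed twice the deformation support radius",
              "ldr_error_bad_spec")
  structure(list(
    patient_id = patient_id, n_lesions = n_lesions, categories = categories,
    dynamics = dynamics, volume_ratio = volume_ratio, delta_mtr = delta_mtr,
    arm = arm, grid = as.integer(grid), voxel_mm = as.numeric(voxel_mm),
    ventricle = ventricle, tract_default_axis = unit(tract_default_axis),
    minor_axis_mm = minor_axis_mm, axis_ratio = axis_ratio,
    vein_radius_mm = vein_radius_mm, vein_length_mm = vein_length_mm,
    margin_deg = margin_deg, lattice_pitch_mm = lattice_pitch_mm,
    mtr_wm_pu = mtr_wm_pu, mtr_lesion_pu = mtr_lesion_pu,
    deformation = deformation, noise_sd = noise_sd,
    threshold_deg = threshold_deg, seed = as.integer(seed)),
    class = "phantom_spec")
}

# rejection-sample a uniform axis whose axial angle to `ref` is
# <= 45 - margin (inside = TRUE) or >= 45 + margin (inside = FALSE)
sample_axis_constrained <- function(ref, inside, margin, threshold = 45,
                                    max_tries = 10000L) {
  for (i in seq_len(max_tries)) {
    x <- canonical_axis(sample_sphere(1)[1, ])
    a <- angle_between_axes(x, ref)
    if (inside && a <= threshold - margin) return(x)
    if (!inside && a >= threshold + margin) return(x)
  }
  ldr_abort("could not sample an axis satisfying the angular constraint",
            "ldr_error_unrealizable_category")
}

# world coordinates of all voxel centres of a diagonal-affine grid,
# returned as three vectors (per axis)
grid_world_axes <- function(grid, voxel_mm) {
  lapply(1:3, function(k) (seq_len(grid[k]) - 1) * voxel_mm[k])
}

#' Build a phantom from its specification
#'
#' Realizes a [phantom_spec()]: places lesions on a jittered lattice
#' outside the ventricle, samples each lesion's true major axis by
#' rejection so that every true feature angle respects the spec's angular
#' margin from the 45-degree boundary, digitizes lesions by
#' centre-of-voxel inclusion against the analytic ellipsoid, rasterizes
#' one vein tube per non-excluded lesion, assembles the tract axis field,
#' builds the analytic deformation field (exact Jacobian `s` on every
#' lesion voxel) and the MT image pairs (which satisfy the MTR identity
#' exactly before noise), and records the full ground truth.
#'
#' @param spec a [phantom_spec()].
#' @return A `lesion_phantom` list: `labels`, `ventricles`, `veins`
#'   ([label_volume()]s), `tract` (axis [vector_volume()]),
#'   `displacement` (displacement [vector_volume()]),
#'   `mt_off_baseline`, `mt_on_baseline`, `mt_off_followup`,
#'   `mt_on_followup` ([image_volume()]s), `truth` (tibble: intended
#'   category/class/ratio/MTR change, true axes and angles,
#'   `min_margin_deg`), and `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, build_phantom_impl(spec))
}

build_phantom_impl <- function(spec) {
  g <- spec$grid; vx <- spec$voxel_mm
  affine <- diag(c(vx, 1))
  extent <- g * vx
  ax <- grid_world_axes(g, vx)
  labels <- array(0L, dim = g)
  veins <- array(0L, dim = g)
  vent <- array(0L, dim = g)

  # ventricle
  if (identical(spec$ventricle$type, "sphere")) {
    vc <- spec$ventricle$centre_mm; vr <- spec$ventricle$radius_mm
    dx2 <- (ax[[1]] - vc[1])^2
    dy2 <- (ax[[2]] - vc[2])^2
    dz2 <- (ax[[3]] - vc[3])^2
    vent[] <- as.integer(outer(outer(dx2, dy2, `+`), dz2, `+`) <= vr^2)
    gdir <- function(p) unit(p - vc)
    vent_clear <- function(p) vnorm(p - vc) >= vr + 9
  } else if (identical(spec$ventricle$type, "slab")) {
    zk <- spec$ventricle$z_mm
    vent[, , ax[[3]] <= zk] <- 1L
    gdir <- function(p) c(0, 0, 1)
    vent_clear <- function(p) p[3] >= zk + 9
  } else ldr_abort("unknown ventricle type", "ldr_error_bad_spec")

  # candidate lesion centres on a lattice, shuffled
  marg <- spec$deformation$r_out + 1
  cand1 <- lapply(1:3, function(k)
    seq(marg, extent[k] - marg, by = spec$lattice_pitch_mm))
  cand <- as.matrix(expand.grid(cand1[[1]], cand1[[2]], cand1[[3]]))
  ok <- apply(cand, 1, vent_clear)
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) < spec$n_lesions)
    ldr_abort(sprintf("grid holds only %d lesion sites, %d requested",
                      nrow(cand), spec$n_lesions), "ldr_error_bad_spec")
  cand <- cand[sample.int(nrow(cand), spec$n_lesions), , drop = FALSE]

  tract <- array(0, dim = c(g, 3L))
  for (k in 1:3) tract[, , , k] <- spec$tract_default_axis[k]
  disp <- array(0, dim = c(g, 3L))
  mtr_base <- array(spec$mtr_wm_pu, dim = g)
  mtr_fu <- array(spec$mtr_wm_pu, dim = g)

  box_idx <- function(centre, half) {
    lapply(1:3, function(k) {
      which(ax[[k]] >= centre[k] - half & ax[[k]] <= centre[k] + half)
    })
  }

  truth <- vector("list", spec$n_lesions)
  for (i in seq_len(spec$n_lesions)) {
    cat_i <- spec$categories[i]
    excluded <- cat_i == "EXCLUDED"
    feats <- if (excluded) character(0) else
      regmatches(cat_i, gregexpr("G|W|V90|V", cat_i))[[1]]
    centre <- cand[i, ]
    g0 <- gdir(centre)

    b <- stats::runif(1, spec$minor_axis_mm[1], spec$minor_axis_mm[2])
    cc <- stats::runif(1, spec$minor_axis_mm[1], spec$minor_axis_mm[2])
    a <- stats::runif(1, spec$axis_ratio[1], spec$axis_ratio[2]) * max(b, cc)

    e1 <- if (excluded)
      canonical_axis(sample_sphere(1)[1, ])
    else
      sample_axis_constrained(g0, "G" %in% feats, spec$margin_deg,
                              spec$threshold_deg)
    w0 <- if (excluded)
      canonical_axis(sample_sphere(1)[1, ])
    else
      sample_axis_constrained(e1, "W" %in% feats, spec$margin_deg,
                              spec$threshold_deg)
    v0 <- if (excluded) {
      c(NA_real_, NA_real_, NA_real_)
    } else if ("V90" %in% feats) {
      # vein perpendicular to the lesion major axis
      r <- sample_sphere(1)[1, ]
      canonical_axis(unit(r - sum(r * e1) * e1))
    } else {
      e1 # vein along the lesion major axis
    }

    # digitize the ellipsoid (centre-of-voxel inclusion)
    roll <- stats::runif(1, 0, 2 * pi)
    R <- complete_basis(e1) %*% rotation_about(c(1, 0, 0), deg(roll))
    bi <- box_idx(centre, a + 1)
    sub <- as.matrix(expand.grid(ax[[1]][bi[[1]]], ax[[2]][bi[[2]]],
                                 ax[[3]][bi[[3]]]))
    loc <- sweep(sub, 2, centre) %*% R # rows: coordinates in lesion frame
    inside <- (loc[, 1] / a)^2 + (loc[, 2] / b)^2 + (loc[, 3] / cc)^2 <= 1
    idx <- as.matrix(expand.grid(bi[[1]], bi[[2]], bi[[3]]))[inside, ,
                                                             drop = FALSE]
    labels[idx] <- i

    # vein tube
    if (!excluded) {
      half_len <- spec$vein_length_mm / 2
      bv <- box_idx(centre, half_len + spec$vein_radius_mm + 1)
      subv <- as.matrix(expand.grid(ax[[1]][bv[[1]]], ax[[2]][bv[[2]]],
                                    ax[[3]][bv[[3]]]))
      rel <- sweep(subv, 2, centre)
      t_par <- rel %*% v0
      t_cl <- pmin(pmax(t_par, -half_len), half_len)
      perp2 <- rowSums((rel - t_cl %*% t(v0))^2)
      inv <- perp2 <= spec$vein_radius_mm^2
      idxv <- as.matrix(expand.grid(bv[[1]], bv[[2]], bv[[3]]))[inv, ,
                                                                drop = FALSE]
      veins[idxv] <- 1L
    }

    # tract axis in the lesion neighbourhood
    bt <- box_idx(centre, a + 3)
    for (k in 1:3) tract[bt[[1]], bt[[2]], bt[[3]], k] <- w0[k]

    # deformation bump: exact uniform stretch s along e1 within r_in
    s <- spec$volume_ratio[i]
    if (s != 1) {
      r_in <- spec$deformation$r_in; r_out <- spec$deformation$r_out
      bd <- box_idx(centre, r_out)
      subd <- as.matrix(expand.grid(ax[[1]][bd[[1]]], ax[[2]][bd[[2]]],
                                    ax[[3]][bd[[3]]]))
      reld <- sweep(subd, 2, centre)
      r <- sqrt(rowSums(reld^2))
      wnd <- ifelse(r <= r_in, 1,
                    ifelse(r >= r_out, 0,
                           0.5 * (1 + cos(pi * (r - r_in) / (r_out - r_in)))))
      amp <- wnd * (s - 1) * (reld %*% e1)[, 1]
      idxd <- as.matrix(expand.grid(bd[[1]], bd[[2]], bd[[3]]))
      for (k in 1:3) {
        lin <- idxd[, 1] + g[1] * (idxd[, 2] - 1L + g[2] * (idxd[, 3] - 1L)) +
          (k - 1L) * prod(g)
        disp[lin] <- disp[lin] + amp * e1[k]
      }
    }

    mtr_base[idx] <- spec$mtr_lesion_pu
    mtr_fu[idx] <- spec$mtr_lesion_pu + spec$delta_mtr[i]

    ang_g <- if (excluded) NA_real_ else angle_between_axes(e1, g0)
    ang_w <- if (excluded) NA_real_ else angle_between_axes(e1, w0)
    ang_v <- if (excluded) NA_real_ else angle_between_axes(e1, v0)
    truth[[i]] <- tibble(
      lesion_id = i, patient_id = spec$patient_id,
      category = cat_i, dynamics = spec$dynamics[i],
      volume_ratio = s, delta_mtr = spec$delta_mtr[i], arm = spec$arm,
      centre_x_mm = centre[1], centre_y_mm = centre[2], centre_z_mm = centre[3],
      semi_a_mm = a, semi_b_mm = b, semi_c_mm = cc,
      e1_x = e1[1], e1_y = e1[2], e1_z = e1[3],
      g_x = g0[1], g_y = g0[2], g_z = g0[3],
      w_x = w0[1], w_y = w0[2], w_z = w0[3],
      v_x = v0[1], v_y = v0[2], v_z = v0[3],
      angle_g_deg = ang_g, angle_w_deg = ang_w, angle_v_deg = ang_v,
      min_margin_deg = if (excluded) NA_real_ else
        min(abs(c(ang_g, ang_w, ang_v) - spec$threshold_deg))
    )
  }

  # global rigid translation
  tr <- spec$deformation$translation
  if (any(tr != 0)) for (k in 1:3) disp[, , , k] <- disp[, , , k] + tr[k]

  off_b <- array(100, dim = g); off_f <- array(100, dim = g)
  on_b <- off_b * (1 - mtr_base / 100)
  on_f <- off_f * (1 - mtr_fu / 100)
  if (spec$noise_sd > 0) {
    off_b <- off_b + array(stats::rnorm(prod(g), 0, spec$noise_sd), dim = g)
    on_b <- on_b + array(stats::rnorm(prod(g), 0, spec$noise_sd), dim = g)
    off_f <- off_f + array(stats::rnorm(prod(g), 0, spec$noise_sd), dim = g)
    on_f <- on_f + array(stats::rnorm(prod(g), 0, spec$noise_sd), dim = g)
  }

  structure(list(
    labels = label_volume(labels, affine),
    ventricles = label_volume(vent, affine),
    veins = label_volume(veins, affine),
    tract = vector_volume(tract, affine, semantics = "axis"),
    displacement = vector_volume(disp, affine, semantics = "displacement"),
    mt_off_baseline = image_volume(off_b, affine, units = "au"),
    mt_on_baseline = image_volume(on_b, affine, units = "au"),
    mt_off_followup = image_volume(off_f, affine, units = "au"),
    mt_on_followup = image_volume(on_f, affine, units = "au"),
    truth = dplyr::bind_rows(truth), spec = spec),
    class = "lesion_phantom")
}

#' @export
print.lesion_phantom <- function(x, ...) {
  cat(sprintf("<lesion_phantom> %s: %d lesions on a %s grid (%s mm voxels)\n",
              x$spec$patient_id, x$spec$n_lesions,
              paste(x$spec$grid, collapse = "x"),
              paste(x$spec$voxel_mm, collapse = "x")))
  invisible(x)
}

#' Sample a synthetic cohort of phantom specs
#'
#' Draws per-patient lesion categories from a category mixture (plus an
#' independent probability of a vein-undefined, hence excluded, lesion),
#' dynamics classes from an expansion/contraction mixture, and per-lesion
#' MTR changes, then packages each patient as a [phantom_spec()].
#' Defaults mirror the structure of the motivating 6-month cohort at desk
#' scale: 20 patients x 16 lesions, a category mixture proportional to
#' the observed per-patient means (V 33, WV 31, GV 13, GWV 11, V90 4,
#' WV90 3, GV90 1, GWV90 1, renormalized), 20% vein-undefined lesions,
#' 13% expanding / 7% contracting with volume ratios 1.08 / 0.92, and
#' alternating placebo/active arms.
#'
#' @param n_patients number of patients.
#' @param n_lesions lesions per patient (scalar or length `n_patients`).
#' @param mixture named probabilities over (a subset of) the realizable
#'   categories; must sum to 1.
#' @param p_excluded probability that a lesion has no measurable vein.
#' @param dynamics_mix named probabilities over
#'   expanding/stable/contracting; must sum to 1.
#' @param expand_ratio,contract_ratio injected volume ratios.
#' @param delta_mtr_mean,delta_mtr_sd Gaussian parameters of the
#'   per-lesion MTR change (pu).
#' @param arm_effect optional `list(arm =, category =, delta =)`: adds
#'   `delta` pu to the MTR change of lesions of that intended category in
#'   that arm (a localized treatment effect with known ground truth).
#' @param arms arm labels, assigned alternately.
#' @param seed master seed; per-patient seeds are derived from it.
#' @param ... further arguments passed to every [phantom_spec()].
#' @return List of `phantom_spec` (possibly empty).
#' @export
sample_cohort <- function(n_patients = 20,
                          n_lesions = 16,
                          mixture = c(V = 0.33, WV = 0.31, GV = 0.13,
                                      GWV = 0.11, V90 = 0.04, WV90 = 0.03,
                                      GV90 = 0.01, GWV90 = 0.01) / 0.97,
                          p_excluded = 0.2,
                          dynamics_mix = c(expanding = 0.13, stable = 0.80,
                                           contracting = 0.07),
                          expand_ratio = 1.08, contract_ratio = 0.92,
                          delta_mtr_mean = 0, delta_mtr_sd = 0.3,
                          arm_effect = NULL,
                          arms = c("placebo", "active"),
                          seed = 1L, ...) {
  if (n_patients == 0) return(list())
  if (any(mixture < 0) || abs(sum(mixture) - 1) > 1e-6)
    ldr_abort("category mixture must be non-negative and sum to 1",
              "ldr_error_degenerate_mixture")
  if (abs(sum(dynamics_mix) - 1) > 1e-6 || any(dynamics_mix < 0))
    ldr_abort("dynamics mixture must be non-negative and sum to 1",
              "ldr_error_degenerate_mixture")
  bad <- setdiff(names(mixture), setdiff(realizable_categories(), "EXCLUDED"))
  if (length(bad) > 0)
    ldr_abort(sprintf("mixture names outside realizable categories: %s",
                      paste(bad, collapse = ", ")),
              "ldr_error_unrealizable_category")
  n_lesions <- rep_len(n_lesions, n_patients)
  withr::with_seed(as.integer(seed), {
    pseeds <- sample.int(.Machine$integer.max - 1L, n_patients)
    lapply(seq_len(n_patients), function(p) {
      n <- n_lesions[p]
      arm <- arms[(p - 1L) %% length(arms) + 1L]
      cats <- ifelse(stats::runif(n) < p_excluded, "EXCLUDED",
                     sample(names(mixture), n, replace = TRUE, prob = mixture))
      dyn <- sample(names(dynamics_mix), n, replace = TRUE,
                    prob = dynamics_mix)
      vr <- c(expanding = expand_ratio, stable = 1,
              contracting = contract_ratio)[dyn]
      dm <- stats::rnorm(n, delta_mtr_mean, delta_mtr_sd)
      if (!is.null(arm_effect) && identical(arm, arm_effect$arm))
        dm <- dm + ifelse(cats == arm_effect$category, arm_effect$delta, 0)
      phantom_spec(patient_id = sprintf("P%02d", p), n_lesions = n,
                   categories = cats, dynamics = dyn, volume_ratio = unname(vr),
                   delta_mtr = dm, arm = arm, seed = pseeds[p], ...)
    })
  })
}
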