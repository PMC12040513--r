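#' The 11 directional categories plus NONE
#'
#' Canonical category names are the concatenation of the aligned feature
#' letters in the fixed order G (surface-in gradient), W (tract), then V
#' (vein) or V90 (orthogonal-to-vein); a lesion aligned with nothing is
#' `NONE`. V and V90 are mutually exclusive by construction (their axes
#' are perpendicular, and no axis can be strictly within 45 degrees of
#' both), giving 11 possible non-empty combinations.
#'
#' @return Character vector of the 12 category names.
#' @export
orientation_categories <- function() {
  c("G", "W", "V", "V90", "GW", "GV", "WV", "GWV",
    "GV90", "WV90", "GWV90", "NONE")
}

category_name <- function(G, W, V, V90) {
  nm <- paste0(ifelse(G, "G", ""), ifelse(W, "W", ""),
               ifelse(V, "V", ""), ifelse(V90, "V90", ""))
  ifelse(nm == "", "NONE", nm)
}

#' Angle between two axes
#'
#' The acute angle between sign-free axes: `acos(|a . b| / (|a| |b|))` in
#' degrees, always in `[0, 90]`. Flipping the sign of either argument
#' leaves the result unchanged (axial convention).
#'
#' @param a,b numeric length-3 vectors (need not be unit norm).
#' @return Angle in degrees.
#' @examples
#' angle_between_axes(c(1, 1, 0), c(1, 0, 0)) # 45
#' @export
angle_between_axes <- function(a, b) {
  na <- vnorm(a); nb <- vnorm(b)
  if (na < 1e-300 || nb < 1e-300)
    ldr_abort("cannot measure an angle to a zero vector", "ldr_error_zero_vector")
  deg(acos(pmin(1, abs(sum(a * b)) / (na * nb))))
}

#' Classify one axis against the feature axes
#'
#' Applies the strict `< threshold` rule: a feature is in the aligned set
#' iff its axis is defined and the axial angle from `axis` to it is
#' strictly below the threshold (an angle exactly at the threshold does
#' not align). Lesions whose vein axis is undefined are not classified
#' (`excluded = TRUE`): without a vein there is no V/V90 comparison and
#' such lesions are tallied separately rather than forced into the
#' remaining categories.
#'
#' `v90_mode` selects how orthogonal-to-vein alignment is assessed:
#' `"projection"` (default) measures the angle to the supplied `v90` axis
#' (the in-plane direction nearest the lesion major axis);
#' `"plane"` calls an axis V90-aligned when it is within `threshold` of
#' the whole plane orthogonal to the vein, i.e. when its angle to the
#' vein exceeds `90 - threshold` (the reported `angle_v90` is then
#' `90 - angle_v`).
#'
#' @param axis unit axis to classify (lesion major axis, or expansion
#'   axis).
#' @param g,w,v,v90 feature axes (length-3, or `NULL`/`NA` = undefined).
#' @param threshold alignment threshold in degrees, in (0, 90).
#' @param v90_mode `"projection"` or `"plane"`.
#' @return A list: `aligned` (character subset of G/W/V/V90), `category`,
#'   `exclusive` (exactly one feature aligned), `excluded` (vein
#'   undefined), `angles` (named, degrees, `NA` where undefined).
#' @export
classify_lesion <- function(axis, g = NULL, w = NULL, v = NULL, v90 = NULL,
                            threshold = 45,
                            v90_mode = c("projection", "plane")) {
  v90_mode <- match.arg(v90_mode)
  if (is.null(axis) || any(!is.finite(axis)))
    ldr_abort("cannot classify an undefined axis", "ldr_error_undefined_axis")
  if (!(threshold > 0 && threshold < 90))
    ldr_abort("threshold must be in (0, 90) degrees", "ldr_error_threshold")
  defined <- function(x) !is.null(x) && all(is.finite(x))
  ang <- function(x) if (defined(x)) angle_between_axes(axis, x) else NA_real_
  angles <- c(g = ang(g), w = ang(w), v = ang(v))
  angles["v90"] <- if (v90_mode == "plane") {
    if (defined(v)) 90 - angles[["v"]] else NA_real_
  } else ang(v90)
  if (!defined(v)) {
    return(list(aligned = character(0), category = NA_character_,
                exclusive = NA, excluded = TRUE, angles = angles))
  }
  al <- !is.na(angles) & angles < threshold
  aligned <- c("G", "W", "V", "V90")[unname(al[c("g", "w", "v", "v90")])]
  list(aligned = aligned,
       category = category_name(al[["g"]], al[["w"]], al[["v"]], al[["v90"]]),
       exclusive = length(aligned) == 1L, excluded = FALSE, angles = angles)
}

#' Classify every lesion's baseline orientation
#'
#' Joins the shape and feature-axis tables and applies [classify_lesion()]
#' to each lesion's major axis.
#'
#' @param shapes [lesion_shapes()] output.
#' @param axes [feature_axes()] output.
#' @inheritParams classify_lesion
#' @return A tibble with one row per lesion: `lesion_id`, `patient_id`,
#'   `angle_{g,w,v,v90}_deg`, `aligned_{g,w,v,v90}`, `category`
#'   (factor over [orientation_categories()]), `exclusive`, `excluded`.
#' @export
classify_orientation <- function(shapes, axes, threshold = 45,
                                 v90_mode = c("projection", "plane")) {
  v90_mode <- match.arg(v90_mode)
  df <- dplyr::inner_join(shapes, axes, by = "lesion_id")
  rows <- purrr::pmap(
    list(df$lesion_id, df$patient_id,
         df$e1_x, df$e1_y, df$e1_z,
         df$g_x, df$g_y, df$g_z, df$g_defined,
         df$w_x, df$w_y, df$w_z, df$w_defined,
         df$v_x, df$v_y, df$v_z, df$v_defined,
         df$v90_x, df$v90_y, df$v90_z, df$v90_defined),
    function(id, pid, ex, ey, ez, gx, gy, gz, gd, wx, wy, wz, wd,
             vx, vy, vz, vd, px, py, pz, pd) {
      cl <- classify_lesion(c(ex, ey, ez),
                            g = if (gd) c(gx, gy, gz),
                            w = if (wd) c(wx, wy, wz),
                            v = if (vd) c(vx, vy, vz),
                            v90 = if (pd) c(px, py, pz),
                            threshold = threshold, v90_mode = v90_mode)
      tibble(lesion_id = id, patient_id = pid,
             angle_g_deg = cl$angles[["g"]], angle_w_deg = cl$angles[["w"]],
             angle_v_deg = cl$angles[["v"]], angle_v90_deg = cl$angles[["v90"]],
             aligned_g = "G" %in% cl$aligned, aligned_w = "W" %in% cl$aligned,
             aligned_v = "V" %in% cl$aligned, aligned_v90 = "V90" %in% cl$aligned,
             category = cl$category, exclusive = cl$exclusive,
             excluded = cl$excluded)
    })
  out <- dplyr::bind_rows(rows)
  out$category <- factor(out$category, levels = orientation_categories())
  out
}

#' Chance probability of aligning with one fixed axis
#'
#' For a lesion axis uniformly distributed on the sphere, the probability
#' of falling strictly within `threshold` degrees of one fixed axis
#' (axial convention, i.e. either hemisphere counts) is the fractional
#' area of the two antipodal spherical caps: `1 - cos(threshold)`.
#' At the 45-degree rule this is `1 - cos(45) = 0.2929`, conventionally
#' reported as 29%.
#'
#' @param threshold degrees, in (0, 90].
#' @return Probability in (0, 1].
#' @examples
#' chance_single(45) # 0.2928932
#' @export
chance_single <- function(threshold) {
  if (!(threshold > 0 && threshold <= 90))
    ldr_abort("threshold must be in (0, 90] degrees", "ldr_error_threshold")
  1 - cos(threshold * pi / 180)
}

#' Monte-Carlo chance probabilities of each category
#'
#' Given one lesion's actual feature-axis geometry, estimates the
#' probability that a uniformly random axis would land in each of the 12
#' mutually exclusive categories. The inter-axis angles of the real
#' features (e.g. a vein nearly parallel to the local tracts) determine
#' how much the single-axis 29% caps overlap, so the joint probabilities
#' are lesion-specific; sampling the random-orientation null directly
#' against the lesion's axes captures that with no atlas required.
#'
#' @param g,w,v,v90 feature axes (length-3 or `NULL` = undefined). At
#'   least one must be defined.
#' @inheritParams classify_lesion
#' @param n_samples Monte-Carlo sample count (default 1e5: standard error
#'   of a probability near 0.3 is about 0.0014).
#' @param seed optional integer; when given, sampling is reproducible and
#'   the caller's RNG state is untouched.
#' @return A tibble `category`, `probability` (rows over
#'   [orientation_categories()]; probabilities sum to 1), with attributes
#'   `n_samples` and `mc_se` (per-category standard errors).
#' @export
chance_joint <- function(g = NULL, w = NULL, v = NULL, v90 = NULL,
                         threshold = 45, n_samples = 1e5, seed = NULL,
                         v90_mode = c("projection", "plane")) {
  v90_mode <- match.arg(v90_mode)
  defined <- function(x) !is.null(x) && all(is.finite(x))
  if (!defined(g) && !defined(w) && !defined(v))
    ldr_abort("no defined feature axes", "ldr_error_undefined_axis")
  X <- with_seed_if(seed, sample_sphere(n_samples))
  angcol <- function(ax) {
    if (!defined(ax)) return(rep(NA_real_, n_samples))
    deg(acos(pmin(1, abs(X %*% unit(ax))[, 1])))
  }
  a_g <- angcol(g); a_w <- angcol(w); a_v <- angcol(v)
  a_v90 <- if (v90_mode == "plane") {
    if (defined(v)) 90 - a_v else rep(NA_real_, n_samples)
  } else angcol(v90)
  al <- function(a) !is.na(a) & a < threshold
  cat <- category_name(al(a_g), al(a_w), al(a_v), al(a_v90))
  counts <- table(factor(cat, levels = orientation_categories()))
  p <- as.numeric(counts) / n_samples
  out <- tibble(category = orientation_categories(), probability = p)
  attr(out, "n_samples") <- n_samples
  attr(out, "mc_se") <- sqrt(p * (1 - p) / n_samples)
  out
}
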