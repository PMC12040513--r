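#' Analyze one phantom (or subject) end to end
#'
#' Runs the baseline stages — shape fitting, feature axes, orientation
#' classification — and the longitudinal stages — Jacobian, expansion
#' axis, direction of change, MTR change — for a single subject, and
#' returns one wide per-lesion tibble. Expansion/contraction classes are
#' cohort-level and are added by [analyze_cohort()].
#'
#' @param phantom a `lesion_phantom` from [build_phantom()], or any list
#'   with the same named volumes (`labels` required; `ventricles`,
#'   `tract`, `veins`, `displacement`, `mt_off_baseline`, `mt_on_baseline`,
#'   `mt_off_followup`, `mt_on_followup` optional).
#' @param patient_id defaults to the phantom spec's id.
#' @inheritParams classify_lesion
#' @param min_volume minimum lesion volume, mm^3.
#' @param min_vein_voxels passed to [lesion_vein_axis()].
#' @return A tibble joining [lesion_shapes()], [feature_axes()],
#'   [classify_orientation()] and [lesion_dynamics()] by `lesion_id`.
#' @export
analyze_phantom <- function(phantom, patient_id = NULL, threshold = 45,
                            min_volume = 3, min_vein_voxels = 3L,
                            v90_mode = c("projection", "plane")) {
  v90_mode <- match.arg(v90_mode)
  if (is.null(patient_id))
    patient_id <- if (!is.null(phantom$spec)) phantom$spec$patient_id else "P01"
  shapes <- lesion_shapes(phantom$labels, min_volume = min_volume,
                          patient_id = patient_id)
  axes <- feature_axes(phantom$labels, shapes,
                       ventricles = phantom$ventricles,
                       tract_field = phantom$tract,
                       veins = phantom$veins,
                       min_volume = min_volume,
                       min_vein_voxels = min_vein_voxels)
  orient <- classify_orientation(shapes, axes, threshold = threshold,
                                 v90_mode = v90_mode)
  out <- shapes |>
    dplyr::inner_join(axes, by = "lesion_id") |>
    dplyr::inner_join(dplyr::select(orient, -"patient_id"), by = "lesion_id")
  if (!is.null(phantom$displacement)) {
    mtr_b <- mtr_f <- NULL
    if (!is.null(phantom$mt_off_baseline) && !is.null(phantom$mt_on_baseline))
      mtr_b <- compute_mtr(phantom$mt_off_baseline, phantom$mt_on_baseline)
    if (!is.null(phantom$mt_off_followup) && !is.null(phantom$mt_on_followup))
      mtr_f <- compute_mtr(phantom$mt_off_followup, phantom$mt_on_followup)
    dyn <- lesion_dynamics(phantom$labels, phantom$displacement, axes,
                           mtr_baseline = mtr_b, mtr_followup = mtr_f,
                           threshold = threshold, min_volume = min_volume,
                           v90_mode = v90_mode)
    out <- dplyr::inner_join(out, dyn, by = "lesion_id")
  }
  out
}

#' Cohort-level analysis
#'
#' Builds (if given specs) and analyzes every phantom, pools the
#' per-lesion tables, applies the cohort ±`k` SD Jacobian rule
#' ([classify_dynamics()]), restricts direction-of-change attribution to
#' non-stable lesions, and aggregates per-patient orientation
#' proportions.
#'
#' @param phantoms list of `phantom_spec` or `lesion_phantom` objects.
#' @inheritParams analyze_phantom
#' @param k SD multiplier of the expansion/contraction cut.
#' @return A `lesion_cohort` list: `lesions` (wide per-lesion tibble with
#'   `dynamics_class`), `truth` (pooled ground truth, when phantoms carry
#'   it), `patient_proportions`, `cohort_proportions`, `cuts`
#'   (`mu`, `sigma`, `low`, `high`), and `params`.
#' @export
analyze_cohort <- function(phantoms, threshold = 45, min_volume = 3,
                           min_vein_voxels = 3L, k = 1,
                           v90_mode = c("projection", "plane")) {
  v90_mode <- match.arg(v90_mode)
  lesions <- vector("list", length(phantoms))
  truths <- vector("list", length(phantoms))
  for (i in seq_along(phantoms)) {
    ph <- phantoms[[i]]
    if (inherits(ph, "phantom_spec")) ph <- build_phantom(ph)
    t0 <- proc.time()[["elapsed"]]
    lesions[[i]] <- analyze_phantom(ph, threshold = threshold,
                                    min_volume = min_volume,
                                    min_vein_voxels = min_vein_voxels,
                                    v90_mode = v90_mode)
    truths[[i]] <- ph$truth
    message(sprintf("[analyze_cohort] %s: %d lesions in %.1fs",
                    lesions[[i]]$patient_id[1], nrow(lesions[[i]]),
                    proc.time()[["elapsed"]] - t0))
  }
  lesions <- dplyr::bind_rows(lesions)
  truth <- dplyr::bind_rows(truths)
  cuts <- NULL
  if ("mean_jacobian" %in% names(lesions)) {
    cls <- classify_dynamics(lesions$mean_jacobian, k = k)
    lesions$dynamics_class <- as.character(cls)
    cuts <- list(mu = attr(cls, "mu"), sigma = attr(cls, "sigma"),
                 low = attr(cls, "cut_low"), high = attr(cls, "cut_high"))
    stable <- lesions$dynamics_class == "stable"
    lesions$direction_category[stable] <- NA_character_
    lesions$exp_x[stable] <- NA_real_
    lesions$exp_y[stable] <- NA_real_
    lesions$exp_z[stable] <- NA_real_
    lesions$exp_defined[stable] <- FALSE
  }
  pp <- per_patient_proportions(lesions)
  structure(list(lesions = lesions, truth = truth,
                 patient_proportions = pp,
                 cohort_proportions = cohort_proportions(pp),
                 cuts = cuts,
                 params = list(threshold = threshold, min_volume = min_volume,
                               k = k, v90_mode = v90_mode)),
            class = "lesion_cohort")
}

#' @export
print.lesion_cohort <- function(x, ...) {
  cat(sprintf("<lesion_cohort> %d lesions, %d patients\n",
              nrow(x$lesions), dplyr::n_distinct(x$lesions$patient_id)))
  if (!is.null(x$cuts))
    cat(sprintf("  Jacobian cuts: %.4f / %.4f (mu %.4f, sigma %.4f)\n",
                x$cuts$low, x$cuts$high, x$cuts$mu, x$cuts$sigma))
  top <- x$cohort_proportions |>
    dplyr::filter(.data$percent > 0) |>
    dplyr::arrange(dplyr::desc(.data$percent))
  cat("  per-patient mean orientation percentages:\n")
  for (i in seq_len(min(6, nrow(top))))
    cat(sprintf("    %-6s %5.1f%%\n", top$category[i], top$percent[i]))
  invisible(x)
}

#' Generator/analyzer recovery summary
#'
#' Joins a cohort analysis to its phantom ground truth and reports how
#' well the pipeline recovered what the generator injected: the angular
#' error of the lesion major axis, the intended-category recovery rate
#' among lesions with a comfortable angular margin from the decision
#' boundary, the intended dynamics-class recovery rate among lesions
#' whose injected volume change exceeds the cohort cut, and the MTR
#' change error.
#'
#' @param cohort a `lesion_cohort` with a non-empty `truth` table.
#' @param margin_deg angular margin (degrees) defining the
#'   "comfortably classifiable" subset (default 10).
#' @return A list: `lesions` (joined tibble with `e1_error_deg`,
#'   `category_match`, `dynamics_match`, `delta_mtr_error`), and scalars
#'   `median_e1_error_deg`, `max_e1_error_deg`,
#'   `category_recovery` (on the margin subset), `n_margin_subset`,
#'   `dynamics_recovery` (on the beyond-cut subset), `n_beyond_cut`,
#'   `max_delta_mtr_error`, `excluded_agreement` (lesions the generator
#'   made vein-free that the pipeline also excluded, and vice versa).
#' @export
recovery_summary <- function(cohort, margin_deg = 10) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  tr <- cohort$truth |>
    dplyr::select("patient_id", "lesion_id",
                  true_category = "category", true_dynamics = "dynamics",
                  true_e1_x = "e1_x", true_e1_y = "e1_y", true_e1_z = "e1_z",
                  true_volume_ratio = "volume_ratio",
                  true_delta_mtr = "delta_mtr", "min_margin_deg")
  j <- dplyr::inner_join(cohort$lesions, tr, by = c("patient_id", "lesion_id"))
  j$e1_error_deg <- purrr::pmap_dbl(
    list(j$e1_x, j$e1_y, j$e1_z, j$true_e1_x, j$true_e1_y, j$true_e1_z),
    function(a, b, c, d, e, f) angle_between_axes(c(a, b, c), c(d, e, f)))
  j$category_match <- !j$excluded & !is.na(j$category) &
    as.character(j$category) == j$true_category
  excl_match <- (j$true_category == "EXCLUDED") == j$excluded
  j$delta_mtr_error <- j$delta_mtr - j$true_delta_mtr
  msub <- j |>
    dplyr::filter(.data$true_category != "EXCLUDED",
                  .data$min_margin_deg >= margin_deg)
  beyond <- if (!is.null(cohort$cuts)) {
    j |> dplyr::filter(.data$true_volume_ratio >= cohort$cuts$high |
                         .data$true_volume_ratio <= cohort$cuts$low)
  } else j[0, ]
  j$dynamics_match <- !is.na(j$dynamics_class) &
    j$dynamics_class == j$true_dynamics
  beyond <- dplyr::semi_join(j, beyond, by = c("patient_id", "lesion_id"))
  list(lesions = j,
       median_e1_error_deg = stats::median(j$e1_error_deg),
       max_e1_error_deg = max(j$e1_error_deg),
       category_recovery = mean(msub$category_match),
       n_margin_subset = nrow(msub),
       dynamics_recovery = if (nrow(beyond) > 0)
         mean(beyond$dynamics_match) else NA_real_,
       n_beyond_cut = nrow(beyond),
       max_delta_mtr_error = max(abs(j$delta_mtr_error)),
       excluded_agreement = mean(excl_match))
}

#' Run the pipeline from a configuration file
#'
#' Reads a structured (YAML) configuration declaring input NIfTI paths,
#' thresholds and a seed, runs every stage whose inputs are present, and
#' writes the tabular outputs as headered CSV files. Progress and
#' per-stage timing go to stderr.
#'
#' Config layout (all inputs except `labels` optional):
#' \preformatted{
#' patient_id: P01
#' inputs:
#'   labels: lesions.nii.gz          # labelled baseline lesion mask
#'   ventricles: vent.nii.gz
#'   tract: tract_e1.nii.gz          # 4D (X,Y,Z,3) axis field
#'   veins: veins.nii.gz
#'   displacement: disp.nii.gz       # 4D (X,Y,Z,3) world-mm
#'   mt_off_baseline: ...            # with mt_on_* at both timepoints
#' params:
#'   threshold_deg: 45
#'   min_volume_mm3: 3
#'   sd_multiplier: 1
#'   min_vein_voxels: 3
#'   v90_mode: projection
#'   seed: 1
#' output_dir: out/
#' }
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return Invisibly, the list of output tibbles (`lesion_shape`,
#'   `feature_axes`, `orientation`, `dynamics`); CSVs of the same names
#'   are written under `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  p <- config$params %||% list()
  threshold <- p$threshold_deg %||% 45
  min_volume <- p$min_volume_mm3 %||% 3
  k <- p$sd_multiplier %||% 1
  minvv <- p$min_vein_voxels %||% 3
  v90_mode <- p$v90_mode %||% "projection"
  if (!is.null(p$seed)) set.seed(as.integer(p$seed))
  outdir <- config$output_dir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- code
    message(sprintf("[%s] done in %.2fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  inp <- config$inputs
  rd <- function(key, sem) if (!is.null(inp[[key]]))
    stage(paste("read", key), read_volume(inp[[key]], sem))
  labels <- rd("labels", "label")
  if (is.null(labels)) ldr_abort("config must declare inputs: labels",
                                 "ldr_error_missing_file")
  bundle <- list(labels = labels,
                 ventricles = rd("ventricles", "label"),
                 tract = rd("tract", "axis"),
                 veins = rd("veins", "label"),
                 displacement = rd("displacement", "displacement"),
                 mt_off_baseline = rd("mt_off_baseline", "image"),
                 mt_on_baseline = rd("mt_on_baseline", "image"),
                 mt_off_followup = rd("mt_off_followup", "image"),
                 mt_on_followup = rd("mt_on_followup", "image"))
  pid <- config$patient_id %||% "P01"
  shapes <- stage("lesion_shape",
                  lesion_shapes(labels, min_volume = min_volume,
                                patient_id = pid))
  axes <- stage("feature_axes",
                feature_axes(labels, shapes, ventricles = bundle$ventricles,
                             tract_field = bundle$tract, veins = bundle$veins,
                             min_volume = min_volume,
                             min_vein_voxels = minvv))
  orient <- stage("orientation",
                  classify_orientation(shapes, axes, threshold = threshold,
                                       v90_mode = v90_mode))
  out <- list(lesion_shape = shapes, feature_axes = axes, orientation = orient)
  if (!is.null(bundle$displacement)) {
    mtr_b <- mtr_f <- NULL
    if (!is.null(bundle$mt_off_baseline) && !is.null(bundle$mt_on_baseline))
      mtr_b <- compute_mtr(bundle$mt_off_baseline, bundle$mt_on_baseline)
    if (!is.null(bundle$mt_off_followup) && !is.null(bundle$mt_on_followup))
      mtr_f <- compute_mtr(bundle$mt_off_followup, bundle$mt_on_followup)
    dyn <- stage("dynamics",
                 lesion_dynamics(labels, bundle$displacement, axes,
                                 mtr_baseline = mtr_b, mtr_followup = mtr_f,
                                 threshold = threshold,
                                 min_volume = min_volume,
                                 v90_mode = v90_mode))
    if (nrow(dyn) >= 2) {
      cls <- classify_dynamics(dyn$mean_jacobian, k = k)
      dyn$dynamics_class <- as.character(cls)
    }
    out$dynamics <- dyn
  }
  for (nm in names(out))
    utils::write.csv(out[[nm]], file.path(outdir, paste0(nm, ".csv")),
                     row.names = FALSE)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
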