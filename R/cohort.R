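#' Per-patient category proportions
#'
#' Computes, within each patient, the proportion of included lesions in
#' each mutually exclusive category. Working per patient first — and
#' averaging patients with equal weight afterwards — stops
#' high-lesion-count patients from dominating cohort percentages.
#' Patients with zero included lesions are dropped with a warning.
#'
#' @param df data frame with one row per lesion.
#' @param category_col,patient_col column names (character).
#' @param exclude_col optional logical column marking lesions excluded
#'   from classification (e.g. vein undefined); excluded and
#'   `NA`-category lesions are not counted in proportions but are
#'   tallied in `n_excluded`.
#' @return A long tibble: `patient_id`, `category`, `n`, `proportion`
#'   (complete over the category levels; proportions sum to 1 per
#'   patient), with attribute `patients` (per-patient
#'   `n_included` / `n_excluded` table).
#' @export
per_patient_proportions <- function(df, category_col = "category",
                                    patient_col = "patient_id",
                                    exclude_col = "excluded") {
  cat_v <- df[[category_col]]
  lv <- if (is.factor(cat_v)) levels(cat_v) else sort(unique(stats::na.omit(cat_v)))
  excl <- if (exclude_col %in% names(df)) df[[exclude_col]] %in% TRUE else
    rep(FALSE, nrow(df))
  excl <- excl | is.na(cat_v)
  d <- tibble(patient_id = df[[patient_col]],
              category = factor(as.character(cat_v), levels = lv),
              excluded = excl)
  patients <- d |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_included = sum(!.data$excluded),
                     n_excluded = sum(.data$excluded), .groups = "drop")
  empty <- patients$patient_id[patients$n_included == 0]
  if (length(empty) > 0)
    warn(sprintf("dropping %d patient(s) with zero included lesions: %s",
                 length(empty), paste(empty, collapse = ", ")))
  out <- d |>
    dplyr::filter(!.data$excluded, !(.data$patient_id %in% empty)) |>
    dplyr::count(.data$patient_id, .data$category, .drop = FALSE, name = "n") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  attr(out, "patients") <- patients
  out
}

#' Cohort mean of per-patient proportions
#'
#' Unweighted mean (and SD) across patients of the per-patient category
#' proportions — the cohort summary convention in which every patient
#' counts once regardless of lesion count.
#'
#' @param pp output of [per_patient_proportions()].
#' @return A tibble: `category`, `mean_proportion`, `sd_proportion`,
#'   `percent` (mean x 100), `n_patients`.
#' @export
cohort_proportions <- function(pp) {
  pp |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(mean_proportion = mean(.data$proportion),
                     sd_proportion = stats::sd(.data$proportion),
                     percent = 100 * mean(.data$proportion),
                     n_patients = dplyr::n(), .groups = "drop")
}

#' Observed vs chance alignment test
#'
#' Compares the observed frequency of a category against its theoretical
#' chance probability with an exact binomial test on the pooled lesion
#' counts, and (optionally) summarizes the per-patient proportions with a
#' one-sample sign test against the same expected value. The binomial
#' against a fixed analytic probability is the minimal faithful null for
#' "is this orientation more common than chance"; no multiplicity
#' adjustment is applied here (see [stats::p.adjust()] if you test many
#' categories).
#'
#' @param successes pooled count of lesions in the category.
#' @param n pooled count of classified lesions.
#' @param expected chance probability, in (0, 1).
#' @param per_patient optional numeric vector of per-patient proportions
#'   for the sign summary.
#' @param category optional label stored in the result.
#' @return An object of class `vs_chance` with [tidy()]/[glance()]
#'   methods: a list with `successes`, `n`, `estimate`, `expected`,
#'   `p.value`, `direction` (`"more"`, `"less"` or `"none"` when the
#'   observed proportion equals the expected exactly), `conf.int`, and a
#'   `per_patient` sub-list (`n_above`, `n_below`, `n_tied`,
#'   `sign_p.value`) when provided.
#' @export
observed_vs_chance <- function(successes, n, expected, per_patient = NULL,
                               category = NA_character_) {
  if (!(expected > 0 && expected < 1))
    ldr_abort("expected probability must be in (0, 1)", "ldr_error_probability")
  if (n < 1) ldr_abort("no observations", "ldr_error_no_observations")
  bt <- stats::binom.test(successes, n, p = expected)
  est <- successes / n
  direction <- if (est > expected) "more" else if (est < expected) "less" else "none"
  pp <- NULL
  if (!is.null(per_patient)) {
    above <- sum(per_patient > expected)
    below <- sum(per_patient < expected)
    sp <- if (above + below > 0)
      stats::binom.test(above, above + below, p = 0.5)$p.value else NA_real_
    pp <- list(n_above = above, n_below = below,
               n_tied = length(per_patient) - above - below,
               sign_p.value = sp)
  }
  structure(list(category = category, successes = successes, n = n,
                 estimate = est, expected = expected,
                 p.value = bt$p.value, conf.int = as.numeric(bt$conf.int),
                 direction = direction, per_patient = pp,
                 method = "exact binomial test vs fixed chance probability"),
            class = "vs_chance")
}

#' @export
print.vs_chance <- function(x, ...) {
  cat(sprintf("Observed vs chance%s: %d/%d = %.3f vs %.3f (%s), p = %.3g\n",
              if (is.na(x$category)) "" else paste0(" [", x$category, "]"),
              x$successes, x$n, x$estimate, x$expected, x$direction,
              x$p.value))
  if (!is.null(x$per_patient))
    cat(sprintf("  per patient: %d above / %d below expected, sign p = %.3g\n",
                x$per_patient$n_above, x$per_patient$n_below,
                x$per_patient$sign_p.value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an observed-vs-chance test
#'
#' @param x a `vs_chance` object.
#' @param ... unused.
#' @return One-row tibble: `category`, `estimate`, `expected`,
#'   `successes`, `n`, `direction`, `p.value`, `conf.low`, `conf.high`,
#'   `method`.
#' @export
tidy.vs_chance <- function(x, ...) {
  tibble(category = x$category, estimate = x$estimate, expected = x$expected,
         successes = x$successes, n = x$n, direction = x$direction,
         p.value = x$p.value, conf.low = x$conf.int[1],
         conf.high = x$conf.int[2], method = x$method)
}

#' @rdname tidy.vs_chance
#' @export
glance.vs_chance <- function(x, ...) {
  tibble(n = x$n, estimate = x$estimate, expected = x$expected,
         p.value = x$p.value, direction = x$direction,
         sign_p.value = if (is.null(x$per_patient)) NA_real_ else
           x$per_patient$sign_p.value)
}

#' Unadjusted group MTR-change table
#'
#' Per category and treatment arm: lesion count, mean and SD of the
#' lesionwise MTR change, plus the raw between-arm difference of means
#' per category (covariate-adjusted modelling is out of scope here — the
#' per-lesion table this package emits is the input such models consume).
#' Cells with fewer than `min_n` lesions are flagged rather than
#' suppressed.
#'
#' @param df data frame with one row per lesion.
#' @param category_col,arm_col,delta_col column names.
#' @param min_n minimum cell count below which `flagged` is `TRUE`.
#' @return A tibble with one row per category x arm: `category`, `arm`,
#'   `n`, `mean_delta_mtr`, `sd_delta_mtr`, `flagged`, and
#'   `arm_difference` (second arm level minus first, repeated within the
#'   category; `NA` when either cell is empty).
#' @export
group_mtr_table <- function(df, category_col = "category", arm_col = "arm",
                            delta_col = "delta_mtr", min_n = 3) {
  cat_v <- df[[category_col]]
  lv <- if (is.factor(cat_v)) levels(cat_v) else sort(unique(stats::na.omit(cat_v)))
  arms <- sort(unique(as.character(df[[arm_col]])))
  d <- tibble(category = factor(as.character(cat_v), levels = lv),
              arm = factor(as.character(df[[arm_col]]), levels = arms),
              delta_mtr = df[[delta_col]]) |>
    dplyr::filter(!is.na(.data$category), is.finite(.data$delta_mtr))
  cells <- d |>
    dplyr::group_by(.data$category, .data$arm, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(), mean_delta_mtr = mean(.data$delta_mtr),
                     sd_delta_mtr = stats::sd(.data$delta_mtr),
                     .groups = "drop") |>
    dplyr::mutate(mean_delta_mtr = ifelse(.data$n == 0, NA_real_,
                                          .data$mean_delta_mtr),
                  flagged = .data$n < min_n)
  if (length(arms) == 2) {
    diffs <- cells |>
      dplyr::select("category", "arm", "mean_delta_mtr") |>
      tidyr::pivot_wider(names_from = "arm", values_from = "mean_delta_mtr") |>
      dplyr::mutate(arm_difference = .data[[arms[2]]] - .data[[arms[1]]]) |>
      dplyr::select("category", "arm_difference")
    cells <- dplyr::left_join(cells, diffs, by = "category")
  } else {
    cells$arm_difference <- NA_real_
  }
  cells
}
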