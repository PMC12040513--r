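#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_col geom_histogram
#'   geom_vline labs scale_fill_viridis_c coord_fixed theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a slice of an image volume
#'
#' Mid-slice (or chosen slice) heatmap in world millimetres.
#'
#' @param object an [image_volume()] or [label_volume()].
#' @param slice 1-based slice index along `axis` (default: middle).
#' @param axis slicing axis, 1-3 (default 3, axial).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.image_volume <- function(object, slice = NULL, axis = 3, ...) {
  d <- dim(object$data)
  if (is.null(slice)) slice <- ceiling(d[axis] / 2)
  sl <- switch(axis, object$data[slice, , ], object$data[, slice, ],
               object$data[, , slice])
  keep <- setdiff(1:3, axis)
  sp <- voxel_spacing(object$affine)
  df <- expand.grid(i = seq_len(dim(sl)[1]), j = seq_len(dim(sl)[2]))
  df$value <- as.vector(sl)
  df$x <- (df$i - 1) * sp[keep[1]]
  df$y <- (df$j - 1) * sp[keep[2]]
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "grey80") +
    coord_fixed() +
    labs(x = sprintf("axis %d (mm)", keep[1]),
         y = sprintf("axis %d (mm)", keep[2]),
         fill = object$units %||% "value",
         title = sprintf("slice %d / axis %d", slice, axis)) +
    theme_minimal()
}

#' @export
autoplot.label_volume <- function(object, slice = NULL, axis = 3, ...) {
  obj <- image_volume(object$data, object$affine, units = "label")
  autoplot.image_volume(obj, slice = slice, axis = axis, ...)
}

#' Bar chart of cohort orientation percentages
#'
#' Mean per-patient percentage of lesions in each directional category —
#' the standard cohort summary figure for this analysis.
#'
#' @param x a `lesion_cohort` or a [cohort_proportions()] tibble.
#' @param drop_empty drop categories with zero mean (default `TRUE`).
#' @return A ggplot.
#' @export
plot_orientation_distribution <- function(x, drop_empty = TRUE) {
  cp <- if (inherits(x, "lesion_cohort")) x$cohort_proportions else x
  if (drop_empty) cp <- dplyr::filter(cp, .data$percent > 0)
  ggplot(cp, aes(x = stats::reorder(.data$category, -.data$percent),
                 y = .data$percent)) +
    geom_col(fill = "steelblue") +
    labs(x = "orientation category",
         y = "mean % of lesions per patient") +
    theme_minimal()
}

#' Histogram of lesion-mean Jacobian determinants
#'
#' Shows the cohort distribution with the ±k SD expansion/contraction
#' cuts marked.
#'
#' @param cohort a `lesion_cohort` from [analyze_cohort()].
#' @param bins histogram bins.
#' @return A ggplot.
#' @export
plot_jacobian_distribution <- function(cohort, bins = 40) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  p <- ggplot(cohort$lesions, aes(x = .data$mean_jacobian)) +
    geom_histogram(bins = bins, fill = "grey60", colour = "white") +
    labs(x = "lesion-mean Jacobian determinant", y = "lesions") +
    theme_minimal()
  if (!is.null(cohort$cuts))
    p <- p + geom_vline(xintercept = c(cohort$cuts$low, cohort$cuts$high),
                        linetype = "dashed", colour = "firebrick")
  p
}
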