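#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_point
#'   geom_col geom_violin labs scale_fill_gradient2 facet_wrap theme_minimal
NULL

#' Heatmap of CAP Z-maps
#'
#' States by ROIs, diverging colour scale centred at zero so co-activation
#' and co-deactivation read symmetrically.
#'
#' @param object A `cap_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cap_set <- function(object, ...) {
  d <- tidy(object)
  d$roi_index <- match(d$roi, unique(d$roi))
  ggplot(d, aes(x = .data$roi_index, y = factor(.data$state),
                fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B") +
    labs(x = "ROI", y = "state", fill = "Z",
         title = "CAP state Z-maps") +
    theme_minimal()
}

#' Silhouette curve plot
#'
#' @param curve Tibble from [silhouette_curve()].
#' @return A ggplot of mean silhouette width against the state count.
#' @export
plot_silhouette_curve <- function(curve) {
  ggplot(curve, aes(x = .data$k, y = .data$mean_silhouette)) +
    geom_line() + geom_point() +
    labs(x = "number of states K", y = "mean silhouette width") +
    theme_minimal()
}

#' State-dynamics summary plot
#'
#' Group means with standard-error bars for one dynamics metric per state,
#' optionally faceted by band.
#'
#' @param summary Tibble from [summarize_dynamics()].
#' @param metric Which metric to show (default `"persistence_s"`).
#' @return A ggplot.
#' @export
plot_dynamics <- function(summary, metric = "persistence_s") {
  d <- summary[summary$metric == metric, ]
  has_group <- "group" %in% names(d)
  p <- ggplot(d, aes(x = factor(.data$state), y = .data$mean,
                     fill = if (has_group) .data$group else NULL)) +
    geom_col(position = "dodge") +
    ggplot2::geom_errorbar(aes(ymin = .data$mean - .data$se,
                               ymax = .data$mean + .data$se),
                           position = ggplot2::position_dodge(0.9),
                           width = 0.25) +
    labs(x = "state", y = metric, fill = "group") +
    theme_minimal()
  if (length(unique(d$band)) > 1) p <- p + facet_wrap(~band)
  p
}

#' Hold-out accuracy distribution plot
#'
#' Violin of per-repetition classification accuracy from
#' [holdout_experiment()].
#'
#' @param reports The `reports` tibble of a hold-out run (or several bound
#'   together with a `model` column).
#' @return A ggplot.
#' @export
plot_holdout_accuracy <- function(reports) {
  if (!"model" %in% names(reports)) reports$model <- "model"
  ggplot(reports, aes(x = .data$model, y = .data$acc)) +
    geom_violin(fill = "grey85") +
    geom_point(position = ggplot2::position_jitter(width = 0.05),
               alpha = 0.5) +
    labs(x = NULL, y = "hold-out accuracy") +
    theme_minimal()
}
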