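#' Plot a raster surface
#'
#' @param object A [noise_raster].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.noise_raster <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = object$units, na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)") +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a fitted LUR model
#'
#' Point estimates with +/- 2 standard-error bars, intercept omitted.
#'
#' @param object A [fit_ols()] result.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.lur_model <- function(object, ...) {
  df <- dplyr::filter(object$coefficients, .data$term != "(Intercept)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 2 * .data$std_error,
      xmax = .data$estimate + 2 * .data$std_error)) +
    ggplot2::labs(x = "estimate (dB(A) per unit)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Accuracy distributions across campaigns
#'
#' Mean accuracy (solid) with a +/- 1 sd ribbon per scheme over sample
#' size, one facet per metric.
#'
#' @param object An [aggregate_results()] summary.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.campaign_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object, cols = tidyr::matches("^(r2|rmse|mae)_(mean|sd)$"),
    names_to = c("metric", "stat"), names_sep = "_", values_to = "value")
  wide <- tidyr::pivot_wider(long, names_from = "stat", values_from = "value")
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$N_requested, y = .data$mean,
                                     colour = .data$scheme,
                                     fill = .data$scheme)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "sample size N", y = NULL) +
    ggplot2::theme_minimal()
}
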