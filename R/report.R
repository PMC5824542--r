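#' Plot per-subject metric distributions by model and scenario
#'
#' Dot-and-interval display of per-subject error values (log x-axis) per
#' model, faceted by metric and scenario, with the median and IQR
#' overlaid — the usual way these comparisons are browsed. Requires
#' ggplot2.
#'
#' @param metrics Per-subject metric tibble from [run_scenario()] or
#'   [run_comparison()] (`$metrics`).
#' @param holdout_fraction Which hold-out fraction to display. Default 0.2.
#' @return A ggplot object.
#' @export
plot_metric_distributions <- function(metrics, holdout_fraction = 0.2) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("plot_metric_distributions requires the ggplot2 package")
  }
  d <- metrics[metrics$holdout_fraction == holdout_fraction &
                 metrics$stratum == "all" & metrics$value > 0, ]
  s <- summarize_metrics(d)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, y = .data$model)) +
    ggplot2::geom_jitter(height = 0.15, size = 0.4, alpha = 0.3) +
    ggplot2::geom_pointrange(
      data = s, shape = 18, colour = "red",
      ggplot2::aes(x = .data$median, xmin = .data$q25, xmax = .data$q75)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(scenario ~ metric, scales = "free_x") +
    ggplot2::labs(x = "per-subject prediction error", y = NULL)
}
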