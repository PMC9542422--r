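#' @importFrom ggplot2 autoplot ggplot aes geom_boxplot geom_point
#'   geom_abline geom_col labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Boxplot of site-normalized concentrations by flow condition
#'
#' @param object A `flow_effect_test` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot flow_effect_test
#' @export
autoplot.flow_effect_test <- function(object, ...) {
  ggplot(object$data, aes(x = .data$flow_class, y = .data$normalized)) +
    geom_boxplot() +
    labs(
      x = "Flow condition",
      y = "Site-normalized summed concentration",
      subtitle = sprintf("Welch t = %.2f, p = %.3g; medians differ by %+.0f%%",
                         object$statistic, object$p_value,
                         object$percent_difference)
    ) +
    theme_minimal()
}

#' Scatter plot of site medians against WWTP effluent fraction
#'
#' @param object A `wwtp_correlation` object.
#' @param ... Unused.
#' @return A ggplot with the least-squares line.
#' @method autoplot wwtp_correlation
#' @export
autoplot.wwtp_correlation <- function(object, ...) {
  ggplot(object$data, aes(x = .data$wwtp_fraction, y = .data$median_sum_ng_l)) +
    geom_point() +
    geom_abline(slope = object$slope, intercept = object$intercept,
                linetype = "dashed") +
    labs(
      x = "WWTP effluent fraction of streamflow",
      y = "Site median summed concentration (ng/L)",
      subtitle = sprintf("Pearson r = %.2f, p = %.3g (n = %d sites)",
                         object$r, object$p_value, object$n_sites)
    ) +
    theme_minimal()
}

#' Stacked site exceedance-tier bars
#'
#' Visual analogue of the per-site hazard summary: for each site, the
#' number of pharmaceuticals whose site maximum falls in each incremental
#' band above the EAR and TQ thresholds.
#'
#' @param report Output of [site_report()].
#' @return A ggplot, faceted by metric.
#' @export
plot_site_exceedances <- function(report) {
  long <- report |>
    select("site_id", dplyr::matches("^(ear|tq)_band")) |>
    tidyr::pivot_longer(-"site_id", names_to = c("metric", "band"),
                        names_sep = "_", values_to = "n") |>
    mutate(
      metric = dplyr::recode(.data$metric, ear = "EAR", tq = "TQ"),
      band = dplyr::recode(.data$band, band1 = "×1–×10",
                           band2 = "×10–×100",
                           band3 = ">×100")
    )
  ggplot(long, aes(x = .data$site_id, y = .data$n, fill = .data$band)) +
    geom_col() +
    facet_wrap(~metric) +
    labs(x = NULL, y = "Pharmaceuticals above threshold",
         fill = "Exceedance band") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}
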