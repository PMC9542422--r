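#' Tidy a flow-condition comparison
#'
#' @param x A `flow_effect_test` object.
#' @param ... Unused.
#' @return One-row tibble with the statistic, degrees of freedom, p-value,
#'   group medians and the percent difference of medians.
#' @method tidy flow_effect_test
#' @export
tidy.flow_effect_test <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    df = x$df,
    p_value = x$p_value,
    median_low = x$median_low,
    median_increased = x$median_increased,
    percent_difference = x$percent_difference
  )
}

#' @rdname tidy.flow_effect_test
#' @method glance flow_effect_test
#' @export
glance.flow_effect_test <- function(x, ...) {
  tibble(
    n_low = x$n_low,
    n_increased = x$n_increased,
    statistic = x$statistic,
    p_value = x$p_value,
    method = "Welch two-sample t test"
  )
}

#' Tidy a WWTP effluent correlation
#'
#' @param x A `wwtp_correlation` object.
#' @param ... Unused.
#' @return One-row tibble with the Pearson r, p-value and linear-fit
#'   coefficients.
#' @method tidy wwtp_correlation
#' @export
tidy.wwtp_correlation <- function(x, ...) {
  tibble(
    r = x$r,
    p_value = x$p_value,
    slope = x$slope,
    intercept = x$intercept
  )
}

#' @rdname tidy.wwtp_correlation
#' @method glance wwtp_correlation
#' @export
glance.wwtp_correlation <- function(x, ...) {
  tibble(
    n_sites = x$n_sites,
    r = x$r,
    r_squared = x$r^2,
    p_value = x$p_value,
    method = "Pearson correlation"
  )
}
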