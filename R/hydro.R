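#' Classify samples into low- and increased-flow conditions
#'
#' Within each site, regular samples are split at the site's median mean
#' daily discharge: at or below the median is `low`, above is `increased`
#' (for two-sample sites this is simply lowest vs highest). Sites without
#' discharge data or with fewer than two regular samples are excluded, with
#' a message naming them.
#'
#' @param samples Sample metadata (`sample_id`, `site_id`, `discharge`,
#'   `qc_type`).
#' @return The eligible regular samples with a `flow_class` column
#'   (`"low"` / `"increased"`). Excluded site ids are attached as the
#'   `excluded_sites` attribute.
#' @export
classify_flow <- function(samples) {
  reg <- regular_samples(samples)
  eligible <- reg |>
    group_by(.data$site_id) |>
    filter(dplyr::n() >= 2L, !anyNA(.data$discharge)) |>
    ungroup()
  dropped <- setdiff(unique(reg$site_id), unique(eligible$site_id))
  if (length(dropped) > 0L) {
    inform(sprintf(
      "classify_flow: excluding %d site(s) without streamflow data and/or a minimum of two samples: %s",
      length(dropped), paste(head(dropped, 5L), collapse = ", ")))
  }
  out <- eligible |>
    group_by(.data$site_id) |>
    mutate(flow_class = if_else(.data$discharge <= median(.data$discharge),
                                "low", "increased")) |>
    ungroup()
  attr(out, "excluded_sites") <- dropped
  out
}

#' Normalize per-sample concentration sums by the site mean
#'
#' Each sample's summed concentration is divided by the mean summed
#' concentration at its site, so every site contributes values centered on
#' 1 and between-site magnitude differences drop out. Sites whose sums are
#' all zero are excluded and flagged.
#'
#' @param sums Per-sample sums (`sample_id`, `site_id`, `sum_ng_l`), e.g.
#'   from [sum_panel_concentrations()].
#' @return The input with a `normalized` column; all-zero site ids in the
#'   `excluded_sites` attribute.
#' @export
normalize_by_site_mean <- function(sums) {
  check_columns(sums, c("sample_id", "site_id", "sum_ng_l"), "sums")
  means <- sums |>
    group_by(.data$site_id) |>
    summarise(site_mean = mean(.data$sum_ng_l), .groups = "drop")
  zero_sites <- means$site_id[means$site_mean == 0]
  if (length(zero_sites) > 0L) {
    inform(sprintf("normalize_by_site_mean: excluding all-zero site(s): %s",
                   paste(zero_sites, collapse = ", ")))
  }
  out <- sums |>
    inner_join(filter(means, .data$site_mean > 0), by = "site_id") |>
    mutate(normalized = .data$sum_ng_l / .data$site_mean) |>
    select(-"site_mean")
  attr(out, "excluded_sites") <- zero_sites
  out
}

#' Compare normalized concentrations between flow conditions
#'
#' Welch's unequal-variance two-sample t test between the site-normalized
#' summed concentrations of low-flow and increased-flow samples, together
#' with the percent difference of the two group medians,
#' \eqn{(median_{low} - median_{incr}) / median_{incr} \times 100}.
#'
#' Note that site-mean normalization couples the groups: a site's
#' normalized values sum to a constant, so its low- and increased-flow
#' values are negatively dependent. The test treats the groups as
#' independent, which makes it anti-conservative; interpret the p-value as
#' a descriptive screen rather than an exact error rate (see the package
#' vignette).
#'
#' @param normalized Output of [normalize_by_site_mean()] joined with a
#'   `flow_class` column (see [classify_flow()]), or any data frame with
#'   `normalized` and `flow_class`.
#' @return A `flow_effect_test` object with the Welch statistic, degrees of
#'   freedom, p-value, group medians and sizes, and the percent difference
#'   of medians. Supports [tidy()], [glance()] and `print()`.
#' @export
flow_effect_test <- function(normalized) {
  check_columns(normalized, c("normalized", "flow_class"), "normalized")
  low <- normalized$normalized[normalized$flow_class == "low"]
  high <- normalized$normalized[normalized$flow_class == "increased"]
  if (length(low) < 2L || length(high) < 2L) {
    abort("each flow group needs at least two samples")
  }
  degenerate <- stats::sd(low) == 0 && stats::sd(high) == 0
  if (degenerate) {
    # both groups constant: the Welch statistic is 0/0 or +/-Inf/0
    d <- mean(low) - mean(high)
    if (d != 0) warn("zero-variance groups; Welch test is degenerate")
    ht <- list(
      statistic = c(t = if (d == 0) 0 else sign(d) * Inf),
      parameter = c(df = NA_real_),
      p.value = if (d == 0) 1 else NA_real_
    )
  } else {
    ht <- t.test(low, high, var.equal = FALSE)
  }
  structure(
    list(
      statistic = unname(ht$statistic),
      df = unname(ht$parameter),
      p_value = ht$p.value,
      median_low = median(low),
      median_increased = median(high),
      percent_difference =
        (median(low) - median(high)) / median(high) * 100,
      n_low = length(low),
      n_increased = length(high),
      data = as_tibble(normalized[c("site_id", "sample_id", "flow_class",
                                    "normalized")[
        c("site_id", "sample_id", "flow_class", "normalized") %in%
          names(normalized)]])
    ),
    class = "flow_effect_test"
  )
}

#' @export
print.flow_effect_test <- function(x, ...) {
  cat("Welch two-sample comparison of site-normalized concentrations\n")
  cat(sprintf("  low flow:       n = %d, median = %.3f\n", x$n_low, x$median_low))
  cat(sprintf("  increased flow: n = %d, median = %.3f\n",
              x$n_increased, x$median_increased))
  cat(sprintf("  median difference: %+.1f%%\n", x$percent_difference))
  cat(sprintf("  t = %.3f, df = %.1f, p = %.4g\n", x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Correlate site concentration levels with wastewater effluent fraction
#'
#' Pearson correlation (with two-sided test) and ordinary least-squares fit
#' of per-site median summed concentrations against the fraction of
#' streamflow attributable to treated wastewater effluent.
#'
#' @param site_sums Per-sample sums (`site_id`, `sum_ng_l`) from
#'   [sum_panel_concentrations()]; medians are taken per site.
#' @param sites Site metadata with `site_id`, `wwtp_fraction`.
#' @return A `wwtp_correlation` object with `r`, `p_value`, `slope`,
#'   `intercept`, `n_sites`, and the per-site data. Supports [tidy()],
#'   [glance()], `print()` and [ggplot2::autoplot()].
#' @export
wwtp_correlation <- function(site_sums, sites) {
  check_columns(site_sums, c("site_id", "sum_ng_l"), "site_sums")
  check_columns(sites, c("site_id", "wwtp_fraction"), "sites")
  med <- site_sums |>
    group_by(.data$site_id) |>
    summarise(median_sum_ng_l = median(.data$sum_ng_l), .groups = "drop") |>
    inner_join(select(sites, "site_id", "wwtp_fraction"), by = "site_id")
  if (nrow(med) < 3L) abort("need at least 3 sites for a correlation")
  if (stats::sd(med$wwtp_fraction) == 0 || stats::sd(med$median_sum_ng_l) == 0) {
    abort("zero variance in concentrations or WWTP fractions; correlation undefined",
          class = "tribscreen_degenerate_error")
  }
  ct <- cor.test(med$wwtp_fraction, med$median_sum_ng_l, method = "pearson")
  fit <- lm(median_sum_ng_l ~ wwtp_fraction, data = med)
  structure(
    list(
      r = unname(ct$estimate),
      p_value = ct$p.value,
      slope = unname(coef(fit)[2L]),
      intercept = unname(coef(fit)[1L]),
      n_sites = nrow(med),
      data = med
    ),
    class = "wwtp_correlation"
  )
}

#' @export
print.wwtp_correlation <- function(x, ...) {
  cat("Pearson correlation: site median concentration vs WWTP effluent fraction\n")
  cat(sprintf("  n = %d sites, r = %.3f, p = %.4g\n", x$n_sites, x$r, x$p_value))
  cat(sprintf("  fit: median_sum = %.1f + %.1f * wwtp_fraction (ng/L)\n",
              x$intercept, x$slope))
  invisible(x)
}
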