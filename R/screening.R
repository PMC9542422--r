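#' Toxicity quotients against the minimum chemical benchmark
#'
#' TQ = measured concentration (ug/L) / screening benchmark (ug/L), using
#' each chemical's minimum subset benchmark so the quotient is the maximum
#' over subsets. Chemicals without a benchmark yield no row (unavailable is
#' not zero); nondetects yield TQ 0; interference rows are skipped.
#'
#' @param measurements Curated measurements (`sample_id`, `cas`,
#'   `curated_value` in ng/L, `qualifier`).
#' @param benchmarks Per-chemical benchmarks (`cas`, `benchmark_ug_l`),
#'   e.g. from [chemical_benchmarks()].
#' @return A tibble: `sample_id`, `cas`, `tq`.
#' @export
compute_tq <- function(measurements, benchmarks) {
  check_columns(measurements, c("sample_id", "cas", "curated_value",
                                "qualifier"), "measurements")
  check_columns(benchmarks, c("cas", "benchmark_ug_l"), "benchmarks")
  if (any(benchmarks$benchmark_ug_l <= 0)) {
    abort("benchmarks must be > 0", class = "tribscreen_validation_error")
  }
  measurements |>
    filter(.data$qualifier != "interference") |>
    inner_join(select(benchmarks, "cas", "benchmark_ug_l"), by = "cas") |>
    mutate(tq = (.data$curated_value / 1000) / .data$benchmark_ug_l) |>
    select("sample_id", "cas", "tq")
}

#' Site-level hazard flags per chemical
#'
#' Collapses per-sample hazard quotients to the site level (maximum across
#' a site's regular samples) and tests each against its prioritization
#' threshold with a strict inequality. A chemical with no EAR (or TQ) data
#' carries `NA` for that metric — unavailable, never a false negative.
#'
#' @param ear_chem Per-sample summed EARs from [sum_ear_chem()] (or `NULL`).
#' @param tq Per-sample toxicity quotients from [compute_tq()] (or `NULL`).
#' @param samples Sample metadata (`sample_id`, `site_id`, `qc_type`).
#' @param ear_threshold EAR_Chem prioritization threshold (default 1e-3).
#' @param tq_threshold TQ prioritization threshold (default 0.1).
#' @return A tibble per site x chemical: `site_id`, `cas`, `max_ear_chem`,
#'   `max_tq`, `exceeds_ear`, `exceeds_tq` (logical, `NA` = unavailable).
#' @export
site_flags <- function(ear_chem, tq, samples,
                       ear_threshold = 1e-3, tq_threshold = 0.1) {
  check_scalar_number(ear_threshold, "ear_threshold")
  check_scalar_number(tq_threshold, "tq_threshold")
  reg <- select(regular_samples(samples), "sample_id", "site_id")

  site_max <- function(df, value_col, out_col) {
    if (is.null(df) || nrow(df) == 0L) {
      return(tibble(site_id = character(), cas = character(),
                    !!out_col := numeric()))
    }
    df |>
      inner_join(reg, by = "sample_id") |>
      group_by(.data$site_id, .data$cas) |>
      summarise(!!out_col := max(.data[[value_col]]), .groups = "drop")
  }

  ear_site <- site_max(ear_chem, "ear_chem", "max_ear_chem")
  tq_site <- site_max(tq, "tq", "max_tq")

  dplyr::full_join(ear_site, tq_site, by = c("site_id", "cas")) |>
    mutate(
      exceeds_ear = .data$max_ear_chem > ear_threshold,
      exceeds_tq = .data$max_tq > tq_threshold
    ) |>
    arrange(.data$site_id, .data$cas)
}

#' Prioritize chemicals by threshold exceedance across sites
#'
#' A chemical is flagged high priority when it exceeds the EAR_Chem or TQ
#' prioritization threshold at a minimum fraction (default 10%) of the
#' sites monitored for its presence. Denominators are chemical-specific:
#' a chemical on a panel run at only 37 sites is judged against 37, not the
#' full site count. A metric with no data anywhere is reported as `NA`
#' ("–") and treated as failing, so a chemical lacking both screening
#' values can never be prioritized.
#'
#' @param flags Site-level flags from [site_flags()].
#' @param samples,chemicals Used to derive each chemical's monitored-site
#'   count from panel coverage.
#' @param min_fraction Minimum exceedance fraction for priority
#'   (default 0.10; compared with `>=`).
#' @return A tibble per chemical: `cas`, `name`, `class`,
#'   `ear_exceed_sites`, `tq_exceed_sites`, `sites_monitored`,
#'   `ear_exceed_pct`, `tq_exceed_pct`, `priority`.
#' @export
prioritize <- function(flags, samples, chemicals, min_fraction = 0.10) {
  if (min_fraction <= 0 || min_fraction > 1) {
    abort("`min_fraction` must be in (0, 1]")
  }
  mon <- monitored_sites(samples, chemicals) |>
    count(.data$cas, name = "sites_monitored")

  exceed <- flags |>
    group_by(.data$cas) |>
    summarise(
      ear_exceed_sites = if (all(is.na(.data$exceeds_ear))) NA_integer_ else
        sum(.data$exceeds_ear, na.rm = TRUE),
      tq_exceed_sites = if (all(is.na(.data$exceeds_tq))) NA_integer_ else
        sum(.data$exceeds_tq, na.rm = TRUE),
      .groups = "drop"
    )

  chemicals |>
    select("cas", "name", "class") |>
    inner_join(mon, by = "cas") |>
    left_join(exceed, by = "cas") |>
    mutate(
      ear_exceed_pct = exceedance_percent(.data$ear_exceed_sites,
                                          .data$sites_monitored),
      tq_exceed_pct = exceedance_percent(.data$tq_exceed_sites,
                                         .data$sites_monitored),
      priority =
        dplyr::coalesce(.data$ear_exceed_sites / .data$sites_monitored >=
                          min_fraction, FALSE) |
        dplyr::coalesce(.data$tq_exceed_sites / .data$sites_monitored >=
                          min_fraction, FALSE)
    ) |>
    arrange(desc(.data$priority),
            desc(pmax(.data$ear_exceed_pct, .data$tq_exceed_pct, na.rm = TRUE)))
}

#' Exceedance (or detection) frequency as a whole percent
#'
#' @param exceed_sites Number of sites exceeding (or detecting).
#' @param sites_monitored Number of sites monitored (>= 1).
#' @return `round(100 * exceed_sites / sites_monitored)` to the nearest
#'   integer (vectorized; `NA` passes through).
#' @examples
#' exceedance_percent(c(38, 31), 44)
#' @export
exceedance_percent <- function(exceed_sites, sites_monitored) {
  if (any(sites_monitored < 1, na.rm = TRUE)) {
    abort("`sites_monitored` must be >= 1")
  }
  round(100 * exceed_sites / sites_monitored)
}
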