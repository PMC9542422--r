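#' Per-site pharmaceutical detection summary
#'
#' Counts, for every site, the number of pharmaceuticals monitored (from the
#' panels its regular samples ran) and the number detected at least once.
#' The nonpharmaceutical "contextual" analytes are tallied separately so
#' they never inflate the pharmaceutical story.
#'
#' @param measurements Curated measurements.
#' @param samples Sample metadata.
#' @param chemicals Chemical catalog with `is_pharmaceutical`.
#' @param sites Site table (defines row order; optional).
#' @return A tibble per site: `site_id`, `n_monitored`, `n_detected`,
#'   `n_monitored_context`, `n_detected_context`.
#' @export
site_detection_summary <- function(measurements, samples, chemicals,
                                   sites = NULL) {
  mon <- monitored_sites(samples, chemicals) |>
    left_join(select(chemicals, "cas", "is_pharmaceutical"), by = "cas")
  reg <- select(regular_samples(samples), "sample_id", "site_id")
  det <- measurements |>
    filter(.data$qualifier %in% c("detect", "estimate")) |>
    inner_join(reg, by = "sample_id") |>
    distinct(.data$site_id, .data$cas) |>
    left_join(select(chemicals, "cas", "is_pharmaceutical"), by = "cas")

  mon_counts <- mon |>
    group_by(.data$site_id) |>
    summarise(
      n_monitored = sum(.data$is_pharmaceutical),
      n_monitored_context = sum(!.data$is_pharmaceutical),
      .groups = "drop"
    )
  det_counts <- det |>
    group_by(.data$site_id) |>
    summarise(
      n_detected = sum(.data$is_pharmaceutical),
      n_detected_context = sum(!.data$is_pharmaceutical),
      .groups = "drop"
    )
  base <- if (!is.null(sites)) select(sites, "site_id") else
    distinct(mon_counts, .data$site_id)
  base |>
    left_join(mon_counts, by = "site_id") |>
    left_join(det_counts, by = "site_id") |>
    mutate(across(dplyr::starts_with("n_"),
                  ~ dplyr::coalesce(.x, 0L) + 0L)) |>
    select("site_id", "n_monitored", "n_detected",
           "n_monitored_context", "n_detected_context")
}

#' Band site maxima into incremental threshold tiers
#'
#' Assigns each exceeding value to exactly one order-of-magnitude band above
#' the base threshold t: (t, 10t], (10t, 100t], (100t, Inf). Values at or
#' below t fall in no band, so the band counts always sum to the number of
#' exceedances.
#'
#' @param values Site-level maximum quotients (one per chemical).
#' @param base_threshold Base prioritization threshold t (> 0).
#' @return A tibble with one row: `band1`, `band2`, `band3`.
#' @examples
#' tier_counts(c(0.05, 0.5, 20), base_threshold = 0.1)
#' @export
tier_counts <- function(values, base_threshold) {
  check_scalar_number(base_threshold, "base_threshold")
  v <- values[!is.na(values)]
  t <- base_threshold
  tibble(
    band1 = sum(v > t & v <= 10 * t),
    band2 = sum(v > 10 * t & v <= 100 * t),
    band3 = sum(v > 100 * t)
  )
}

#' Sum of maximum EARs across a site's samples
#'
#' For each chemical-assay pair, takes the maximum EAR across the site's
#' regular samples, then sums over all pairs — the site-level "sum of
#' maximum EAR values for all assays". Duplicating a sample leaves the
#' result unchanged; adding a sample can only increase it.
#'
#' @param ear Per-sample EAR table from [compute_ear()].
#' @param samples Sample metadata.
#' @param per_chemical If `TRUE`, take maxima of the per-chemical summed
#'   EAR_Chem instead of per-assay maxima (an alternative summary).
#' @return A tibble per site: `site_id`, `sum_max_ear`, `n_pairs`, and
#'   `no_toxcast` flagging sites with no EAR rows at all.
#' @export
sum_max_ear <- function(ear, samples, per_chemical = FALSE) {
  reg <- select(regular_samples(samples), "sample_id", "site_id")
  keyed <- if (per_chemical) {
    sum_ear_chem(ear) |>
      rename(ear = "ear_chem") |>
      mutate(assay_id = "all") |>
      select("sample_id", "cas", "assay_id", "ear")
  } else {
    ear
  }
  out <- keyed |>
    inner_join(reg, by = "sample_id") |>
    group_by(.data$site_id, .data$cas, .data$assay_id) |>
    summarise(max_ear = max(.data$ear), .groups = "drop") |>
    group_by(.data$site_id) |>
    summarise(
      sum_max_ear = sum(.data$max_ear),
      n_pairs = dplyr::n(),
      .groups = "drop"
    )
  distinct(reg, .data$site_id) |>
    left_join(out, by = "site_id") |>
    mutate(
      no_toxcast = is.na(.data$sum_max_ear),
      sum_max_ear = dplyr::coalesce(.data$sum_max_ear, 0),
      n_pairs = dplyr::coalesce(.data$n_pairs, 0L)
    )
}

#' Assemble the per-site report
#'
#' One row per site with detection counts, incremental EAR and TQ
#' threshold-exceedance tiers (x1/x10/x100 of the base thresholds), and the
#' sum of maximum EARs — the tabular analogue of the study's site figures.
#'
#' @param flags Site-level flags from [site_flags()].
#' @param ear Per-sample EAR table from [compute_ear()].
#' @param measurements,samples,chemicals,sites Study tables.
#' @param ear_threshold,tq_threshold Base thresholds for the tier bands.
#' @return A tibble per site: detection counts, `ear_band1..3`,
#'   `tq_band1..3`, `sum_max_ear`.
#' @export
site_report <- function(flags, ear, measurements, samples, chemicals,
                        sites = NULL, ear_threshold = 1e-3,
                        tq_threshold = 0.1) {
  detect <- site_detection_summary(measurements, samples, chemicals, sites)
  pharma <- chemicals$cas[chemicals$is_pharmaceutical]
  tiers <- flags |>
    filter(.data$cas %in% pharma) |>
    group_by(.data$site_id) |>
    summarise(
      ear_bands = list(tier_counts(.data$max_ear_chem, ear_threshold)),
      tq_bands = list(tier_counts(.data$max_tq, tq_threshold)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("ear_bands", names_sep = "_") |>
    tidyr::unnest_wider("tq_bands", names_sep = "_") |>
    rename(
      ear_band1 = "ear_bands_band1", ear_band2 = "ear_bands_band2",
      ear_band3 = "ear_bands_band3", tq_band1 = "tq_bands_band1",
      tq_band2 = "tq_bands_band2", tq_band3 = "tq_bands_band3"
    )
  sums <- sum_max_ear(filter(ear, .data$cas %in% pharma), samples)
  detect |>
    left_join(tiers, by = "site_id") |>
    left_join(select(sums, "site_id", "sum_max_ear"), by = "site_id") |>
    mutate(across(dplyr::matches("band|sum_max"),
                  ~ tidyr::replace_na(.x, 0)))
}
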