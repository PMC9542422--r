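#' Apply censoring and interference rules to raw concentration values
#'
#' Concentration values below the method detection limit (MDL) are treated as
#' zero nondetects; values at or above the MDL but below the method reporting
#' limit (MRL) are retained but flagged as estimates; values at or above the
#' MRL are detections. Severe analytical interference suppresses the value
#' entirely; minor interference downgrades a detection to an estimate.
#'
#' @param value Raw concentration (ng/L); `NA` for values not reported.
#' @param mdl Method detection limit (ng/L), > 0.
#' @param mrl Method reporting limit (ng/L), > 0.
#' @param interference One of `"none"`, `"minor"`, `"severe"` (recycled).
#' @return A tibble with columns `qualifier` (detect / estimate / nondetect /
#'   interference) and `curated_value` (ng/L; 0 for nondetects, `NA` for
#'   interference-suppressed rows).
#' @examples
#' curate_measurement(c(5, 20, 100), mdl = 13, mrl = 30)
#' @export
curate_measurement <- function(value, mdl, mrl,
                               interference = "none") {
  n <- max(length(value), length(mdl), length(mrl), length(interference))
  value <- rep_len(value, n)
  mdl <- rep_len(mdl, n)
  mrl <- rep_len(mrl, n)
  interference <- rep_len(interference, n)

  if (any(mdl <= 0 | mrl <= 0, na.rm = TRUE)) {
    abort("`mdl` and `mrl` must be > 0")
  }
  if (any(value < 0, na.rm = TRUE)) {
    abort("negative concentration value", class = "tribscreen_validation_error")
  }
  bad_int <- setdiff(unique(interference), c("none", "minor", "severe"))
  if (length(bad_int) > 0L) {
    abort(sprintf("unknown interference level: %s", paste(bad_int, collapse = ", ")))
  }

  qualifier <- rep("nondetect", n)
  curated <- rep(0, n)

  observed <- !is.na(value) & value >= mdl
  qualifier[observed & value < mrl] <- "estimate"
  qualifier[observed & value >= mrl] <- "detect"
  curated[observed] <- value[observed]

  # minor interference permits quantitation but only as an estimate
  qualifier[interference == "minor" & qualifier == "detect"] <- "estimate"
  qualifier[interference == "severe"] <- "interference"
  curated[interference == "severe"] <- NA_real_

  tibble(qualifier = qualifier, curated_value = curated)
}

#' Curate a measurement table against the chemical catalog
#'
#' Joins per-chemical MDL/MRL from the catalog and applies
#' [curate_measurement()] row-wise, producing `qualifier` and
#' `curated_value` columns. Rows already qualified as `interference` keep
#' that status (a suppressed value cannot be re-derived). The operation is
#' idempotent: curating an already-curated table leaves it unchanged.
#'
#' @param measurements Tibble with `sample_id`, `cas`, `value_ng_l` and
#'   optionally `qualifier` and `interference`.
#' @param chemicals Chemical catalog with `cas`, `mdl_ng_l`, `mrl_ng_l`.
#' @return The measurement tibble with `qualifier` and `curated_value`.
#' @export
curate_measurements <- function(measurements, chemicals) {
  check_columns(measurements, c("sample_id", "cas", "value_ng_l"),
                "measurements")
  check_columns(chemicals, c("cas", "mdl_ng_l", "mrl_ng_l"), "chemicals")
  interference <- if ("interference" %in% names(measurements)) {
    measurements$interference
  } else if ("qualifier" %in% names(measurements)) {
    if_else(measurements$qualifier == "interference", "severe", "none")
  } else {
    "none"
  }
  limits <- measurements |>
    left_join(select(chemicals, "cas", "mdl_ng_l", "mrl_ng_l"), by = "cas")
  if (anyNA(limits$mdl_ng_l)) {
    bad <- limits$cas[which(is.na(limits$mdl_ng_l))[1L]]
    abort(sprintf("integrity error: measurement references unknown cas `%s`", bad))
  }
  cur <- curate_measurement(limits$value_ng_l, limits$mdl_ng_l,
                            limits$mrl_ng_l, interference)
  measurements$qualifier <- cur$qualifier
  measurements$curated_value <- cur$curated_value
  measurements
}

#' Per-chemical detection frequency as a percentage of sites monitored
#'
#' Because not all sites are monitored for all method panels, detection
#' frequencies are expressed against the number of sites at which a chemical
#' was actually monitored, not the total site count. A site counts as a
#' detection when any regular sample there carries a `detect` or `estimate`
#' qualifier for the chemical.
#'
#' @param measurements Curated measurement tibble (see
#'   [curate_measurements()]).
#' @param samples Sample metadata with `sample_id`, `site_id`, `qc_type`,
#'   `panels`.
#' @param chemicals Chemical catalog with `cas` and `panel`.
#' @return A tibble with one row per chemical: `cas`, `sites_monitored`,
#'   `sites_detected`, `det_freq` (exact percent) and `det_freq_pct`
#'   (nearest integer). Chemicals monitored at zero sites get `NA`
#'   frequencies and `undefined = TRUE` rather than 0.
#' @export
detection_frequency <- function(measurements, samples, chemicals) {
  mon <- monitored_sites(samples, chemicals) |>
    count(.data$cas, name = "sites_monitored")
  reg_ids <- regular_samples(samples)$sample_id
  det <- measurements |>
    filter(.data$sample_id %in% reg_ids,
           .data$qualifier %in% c("detect", "estimate")) |>
    left_join(select(samples, "sample_id", "site_id"), by = "sample_id") |>
    distinct(.data$cas, .data$site_id) |>
    count(.data$cas, name = "sites_detected")

  chemicals |>
    select("cas") |>
    left_join(mon, by = "cas") |>
    left_join(det, by = "cas") |>
    mutate(
      sites_monitored = dplyr::coalesce(.data$sites_monitored, 0L),
      sites_detected = dplyr::coalesce(.data$sites_detected, 0L),
      undefined = .data$sites_monitored == 0L,
      det_freq = if_else(.data$undefined, NA_real_,
                         100 * .data$sites_detected / .data$sites_monitored),
      det_freq_pct = round(.data$det_freq)
    )
}

#' Relative percent difference between paired measurements
#'
#' RPD = |a - b| / mean(a, b) x 100, the standard QC comparison between a
#' regular sample and its field duplicate. Symmetric in its arguments.
#'
#' @param a,b Non-negative concentrations (same units), not both zero.
#' @return RPD in percent (vectorized); `NA` with a warning where both
#'   values are zero.
#' @examples
#' relative_percent_difference(100, 81)
#' @export
relative_percent_difference <- function(a, b) {
  if (any(a < 0 | b < 0, na.rm = TRUE)) {
    abort("`a` and `b` must be >= 0")
  }
  both_zero <- a == 0 & b == 0
  if (any(both_zero, na.rm = TRUE)) {
    warn("RPD undefined where both values are zero; returning NA")
  }
  out <- abs(a - b) / ((a + b) / 2) * 100
  out[both_zero] <- NA_real_
  out
}

#' Screen blank samples for contamination
#'
#' Reports every chemical detected in any blank sample, with the number of
#' blank detections, the maximum blank concentration, and whether that
#' maximum stayed below the chemical's MRL. Regular-sample data are never
#' adjusted.
#'
#' @inheritParams detection_frequency
#' @return A tibble: `cas`, `n_blank_detections`, `max_blank_value`,
#'   `below_mrl`. Empty when no blank detections occurred.
#' @export
blank_screen <- function(measurements, samples, chemicals) {
  blank_ids <- samples$sample_id[samples$qc_type == "blank"]
  hits <- filter(measurements, .data$sample_id %in% blank_ids,
                 .data$qualifier %in% c("detect", "estimate"))
  if (nrow(hits) == 0L) {
    return(tibble(cas = character(), n_blank_detections = integer(),
                  max_blank_value = numeric(), below_mrl = logical()))
  }
  hits |>
    group_by(.data$cas) |>
    summarise(
      n_blank_detections = dplyr::n(),
      max_blank_value = max(.data$curated_value),
      .groups = "drop"
    ) |>
    left_join(select(chemicals, "cas", "mrl_ng_l"), by = "cas") |>
    mutate(below_mrl = .data$max_blank_value < .data$mrl_ng_l) |>
    select(-"mrl_ng_l")
}

#' Sum curated concentrations over one method panel per sample
#'
#' Totals the curated values of all chemicals in the requested analytical
#' panel, sample by sample. Nondetects contribute zero; interference rows
#' are skipped. It is an error to request a panel a sample did not run —
#' the total is genuinely unknown there, not zero.
#'
#' @inheritParams detection_frequency
#' @param panel A method panel code (`"M1"`, `"M2neg"`, `"M2pos"`).
#' @return A tibble: `sample_id`, `site_id`, `panel`, `sum_ng_l`.
#' @export
sum_panel_concentrations <- function(measurements, samples, chemicals,
                                     panel = "M1") {
  stopifnot(panel %in% method_panels)
  ran <- vapply(samples$panels, function(p) panel %in% p, TRUE)
  if (!all(ran)) {
    abort(sprintf("panel `%s` was not run for sample(s) %s", panel,
                  paste(head(samples$sample_id[!ran], 3L), collapse = ", ")),
          class = "tribscreen_panel_error")
  }
  panel_cas <- chemicals$cas[chemicals$panel == panel]
  sums <- measurements |>
    filter(.data$sample_id %in% samples$sample_id,
           .data$cas %in% panel_cas,
           .data$qualifier != "interference") |>
    group_by(.data$sample_id) |>
    summarise(sum_ng_l = sum(.data$curated_value), .groups = "drop")
  samples |>
    select("sample_id", "site_id") |>
    left_join(sums, by = "sample_id") |>
    mutate(
      panel = panel,
      sum_ng_l = dplyr::coalesce(.data$sum_ng_l, 0)
    )
}
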