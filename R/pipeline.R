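#' Chemicals detected but lacking any screening value
#'
#' The set difference between the detected chemicals and those represented
#' by at least one alternative benchmark (an included ACC record or a
#' derivable ecotoxicity benchmark), sorted by detection frequency so the
#' most widespread knowledge gaps lead the report.
#'
#' @param detection Detection-frequency table from [detection_frequency()]
#'   (needs `cas`, `sites_detected`, `det_freq`).
#' @param acc ACC table (`cas`, `included`), or `NULL` for none.
#' @param benchmarks Per-chemical benchmarks (`cas`), e.g. from
#'   [chemical_benchmarks()], or `NULL` for none.
#' @return The detected rows of `detection` without either screening value,
#'   sorted by `det_freq` descending.
#' @export
gap_report <- function(detection, acc = NULL, benchmarks = NULL) {
  check_columns(detection, c("cas", "sites_detected"), "detection")
  with_acc <- if (is.null(acc)) character() else
    unique(acc$cas[acc$included %||% TRUE])
  with_bench <- if (is.null(benchmarks)) character() else unique(benchmarks$cas)
  detection |>
    filter(.data$sites_detected > 0L,
           !(.data$cas %in% c(with_acc, with_bench))) |>
    arrange(desc(.data$det_freq))
}

#' Run the full screening pipeline on a study bundle
#'
#' Orchestrates every stage in order: measurement curation, detection
#' frequencies, benchmark derivation from endpoint records, EAR and TQ
#' computation, site-level flags, prioritization, the per-site report, the
#' gap report of detected chemicals lacking both screening values, the
#' hydrologic flow comparison and the WWTP effluent correlation. When
#' `out_dir` is given, each report is written as CSV alongside a JSON run
#' manifest with row counts and the configuration used.
#'
#' @param bundle A `study_bundle` (see [read_study_tables()],
#'   [study_bundle()], [generate_bundle()]).
#' @param out_dir Optional output directory for `priority.csv`,
#'   `site_report.csv`, `gap_report.csv`, `flow_report.csv`,
#'   `wwtp_report.csv`, `benchmarks.csv`, `detection.csv` and
#'   `manifest.json`.
#' @param ear_threshold,tq_threshold,min_site_fraction Screening thresholds
#'   (defaults 1e-3, 0.1 and 0.10).
#' @param missing_af Persistence application factor for chemicals without a
#'   half-life (default 5).
#' @return A `screening_results` list: `detection`, `benchmarks`,
#'   `chem_benchmarks`, `ear`, `ear_chem`, `tq`, `flags`, `priority`,
#'   `site_report`, `gap_report`, `blanks`, `flow_test` (or `NULL` when
#'   hydrology is not computable), `wwtp` (likewise), and `manifest`.
#' @examples
#' sim <- generate_bundle(sim_config(seed = 3, n_sites = 6, n_chemicals = 15))
#' res <- run_pipeline(sim$bundle)
#' res$priority
#' @export
run_pipeline <- function(bundle, out_dir = NULL,
                         ear_threshold = 1e-3, tq_threshold = 0.1,
                         min_site_fraction = 0.10, missing_af = 5) {
  stopifnot(inherits(bundle, "study_bundle"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)),
            class = "tribscreen_stage_error", parent = e)
    })
  }

  meas <- stage("curation",
                curate_measurements(bundle$measurements, bundle$chemicals))
  detection <- stage("detection_frequency",
                     detection_frequency(meas, bundle$samples,
                                         bundle$chemicals))
  blanks <- stage("blank_screen",
                  blank_screen(meas, bundle$samples, bundle$chemicals))

  benchmarks <- if (!is.null(bundle$endpoints)) {
    stage("benchmarks",
          derive_benchmarks(bundle$endpoints, bundle$chemicals,
                            missing_af = missing_af))
  } else {
    derive_benchmarks(tibble(cas = character(), endpoint_code = character(),
                             effect_level = numeric(), conc_ug_l = numeric(),
                             species = character(), species_group = character(),
                             excluded = logical()))
  }
  chem_bench <- chemical_benchmarks(benchmarks)

  ear <- if (!is.null(bundle$acc)) {
    stage("ear", compute_ear(meas, bundle$chemicals, bundle$acc))
  } else {
    tibble(sample_id = character(), cas = character(),
           assay_id = character(), ear = numeric())
  }
  ear_chem <- sum_ear_chem(ear)
  tq <- stage("tq", compute_tq(meas, chem_bench))

  flags <- stage("site_flags",
                 site_flags(ear_chem, tq, bundle$samples,
                            ear_threshold = ear_threshold,
                            tq_threshold = tq_threshold))
  priority <- stage("prioritize",
                    prioritize(flags, bundle$samples, bundle$chemicals,
                               min_fraction = min_site_fraction))
  sites_tab <- stage("site_report",
                     site_report(flags, ear, meas, bundle$samples,
                                 bundle$chemicals, bundle$sites,
                                 ear_threshold = ear_threshold,
                                 tq_threshold = tq_threshold))
  gaps <- stage("gap_report", gap_report(detection, bundle$acc, chem_bench))

  # hydrology: M1 sums on regular samples from sites with discharge data
  flow_test <- NULL
  wwtp <- NULL
  hydro <- tryCatch({
    flow <- classify_flow(bundle$samples)
    flow <- flow[vapply(flow$panels, function(p) "M1" %in% p, TRUE), ]
    sums <- sum_panel_concentrations(meas, flow, bundle$chemicals, "M1")
    normed <- normalize_by_site_mean(sums) |>
      left_join(select(flow, "sample_id", "flow_class"), by = "sample_id")
    list(
      test = flow_effect_test(normed),
      wwtp = wwtp_correlation(sums, bundle$sites)
    )
  }, error = function(e) {
    inform(sprintf("hydrology stage skipped: %s", conditionMessage(e)))
    NULL
  })
  if (!is.null(hydro)) {
    flow_test <- hydro$test
    wwtp <- hydro$wwtp
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tribscreen")),
    thresholds = list(ear = ear_threshold, tq = tq_threshold,
                      min_site_fraction = min_site_fraction,
                      missing_af = missing_af),
    config_hash = rlang::hash(list(ear_threshold, tq_threshold,
                                   min_site_fraction, missing_af)),
    rows = list(
      chemicals = nrow(bundle$chemicals), sites = nrow(bundle$sites),
      samples = nrow(bundle$samples), measurements = nrow(bundle$measurements),
      acc = if (is.null(bundle$acc)) 0L else nrow(bundle$acc),
      endpoints = if (is.null(bundle$endpoints)) 0L else nrow(bundle$endpoints),
      priority = nrow(priority), gap = nrow(gaps)
    )
  )

  res <- structure(
    list(
      detection = detection, benchmarks = benchmarks,
      chem_benchmarks = chem_bench, ear = ear, ear_chem = ear_chem,
      tq = tq, flags = flags, priority = priority, site_report = sites_tab,
      gap_report = gaps, blanks = blanks, flow_test = flow_test,
      wwtp = wwtp, manifest = manifest
    ),
    class = "screening_results"
  )
  if (!is.null(out_dir)) write_reports(res, out_dir)
  res
}

#' @export
print.screening_results <- function(x, ...) {
  cat("<screening_results>\n")
  cat(sprintf("  chemicals detected: %d\n",
              sum(x$detection$sites_detected > 0)))
  cat(sprintf("  with >=1 screening value: %d\n",
              sum(x$detection$sites_detected > 0) - nrow(x$gap_report)))
  cat(sprintf("  lacking screening values: %d\n", nrow(x$gap_report)))
  cat(sprintf("  high-priority chemicals: %d\n", sum(x$priority$priority)))
  if (!is.null(x$flow_test)) {
    cat(sprintf("  flow effect: %+.0f%% (p = %.3g)\n",
                x$flow_test$percent_difference, x$flow_test$p_value))
  }
  if (!is.null(x$wwtp)) {
    cat(sprintf("  WWTP correlation: r = %.2f (p = %.3g)\n",
                x$wwtp$r, x$wwtp$p_value))
  }
  invisible(x)
}

#' Write screening reports to disk
#'
#' @param results A `screening_results` object from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_reports <- function(results, out_dir) {
  stopifnot(inherits(results, "screening_results"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(df, name) {
    readr::write_csv(df, file.path(out_dir, name), progress = FALSE, na = "-")
  }
  w(results$priority, "priority.csv")
  w(results$site_report, "site_report.csv")
  w(results$gap_report, "gap_report.csv")
  w(results$detection, "detection.csv")
  w(results$benchmarks, "benchmarks.csv")
  w(results$blanks, "blank_report.csv")
  if (!is.null(results$flow_test)) {
    w(tidy(results$flow_test), "flow_report.csv")
  }
  if (!is.null(results$wwtp)) {
    w(tidy(results$wwtp), "wwtp_stats.csv")
    w(results$wwtp$data, "wwtp_report.csv")
  }
  jsonlite::write_json(results$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
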