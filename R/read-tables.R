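#' Read and validate a study bundle from CSV tables
#'
#' A study bundle collects the tabular inputs of a tributary screening study:
#' a chemical catalog, site metadata, sample metadata, per-sample
#' concentration measurements, and (optionally) an in vitro activity
#' concentration (ACC) table and in vivo ecotoxicity endpoint records.
#' All cross-references (sample to site, measurement to sample and chemical,
#' ACC and endpoint records to chemicals) are checked on read.
#'
#' Expected files and columns (all UTF-8 CSV with a header row; concentration
#' units are fixed per table: ng/L in measurements, ug/L in endpoint records,
#' uM in ACC records):
#' \describe{
#'   \item{chemicals.csv}{cas, name, class, is_pharmaceutical, panel,
#'     mw_g_mol, mrl_ng_l, mdl_ng_l, half_life_weeks}
#'   \item{sites.csv}{site_id, watershed, lake, tier, wwtp_fraction,
#'     drainage_km2, pop_density}
#'   \item{samples.csv}{sample_id, site_id, date, discharge, qc_type, panels
#'     (semicolon-separated panel codes)}
#'   \item{measurements.csv}{sample_id, cas, value_ng_l, qualifier}
#'   \item{acc.csv}{cas, assay_id, acc_um, included}
#'   \item{endpoints.csv}{cas, endpoint_code, effect_level, conc_ug_l,
#'     species, species_group, excluded, exclusion_reason}
#' }
#'
#' @param dir Directory containing the CSV tables named as above, or a named
#'   list/character vector mapping table roles (`chemicals`, `sites`,
#'   `samples`, `measurements`, `acc`, `endpoints`) to file paths.
#' @return A `study_bundle`: a named list of tibbles with components
#'   `chemicals`, `sites`, `samples`, `measurements` and, when present,
#'   `acc` and `endpoints`.
#' @examples
#' cfg <- sim_config(seed = 1, n_sites = 4, n_chemicals = 6)
#' sim <- generate_bundle(cfg)
#' dir <- tempfile(); dir.create(dir)
#' write_study_tables(sim$bundle, dir)
#' bundle <- read_study_tables(dir)
#' nrow(bundle$sites)
#' @export
read_study_tables <- function(dir) {
  roles <- c("chemicals", "sites", "samples", "measurements", "acc", "endpoints")
  if (is.character(dir) && length(dir) == 1L && is.null(names(dir))) {
    paths <- file.path(dir, paste0(roles, ".csv"))
    names(paths) <- roles
    paths <- paths[file.exists(paths)]
  } else {
    paths <- unlist(dir)
    bad <- setdiff(names(paths), roles)
    if (length(bad) > 0L) {
      abort(sprintf("unknown table role(s): %s", paste(bad, collapse = ", ")))
    }
  }
  required <- c("chemicals", "sites", "samples", "measurements")
  missing <- setdiff(required, names(paths))
  if (length(missing) > 0L) {
    abort(sprintf("missing required table(s): %s", paste(missing, collapse = ", ")))
  }
  absent <- paths[!file.exists(paths)]
  if (length(absent) > 0L) {
    abort(sprintf("file not found: %s", paste(absent, collapse = ", ")))
  }

  read_csv_quiet <- function(path) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  tabs <- lapply(paths, read_csv_quiet)

  bundle <- list(
    chemicals = parse_chemicals(tabs$chemicals),
    sites = parse_sites(tabs$sites),
    samples = parse_samples(tabs$samples),
    measurements = parse_measurements(tabs$measurements)
  )
  if (!is.null(tabs$acc)) bundle$acc <- parse_acc(tabs$acc)
  if (!is.null(tabs$endpoints)) bundle$endpoints <- parse_endpoints(tabs$endpoints)
  as_study_bundle(bundle)
}

#' Assemble a study bundle from in-memory tables
#'
#' Validates schemas and referential integrity the same way as
#' [read_study_tables()], for tables built in code (e.g. by the synthetic
#' generator).
#'
#' @param chemicals,sites,samples,measurements Data frames following the
#'   schemas documented in [read_study_tables()].
#' @param acc,endpoints Optional ACC and ecotoxicity endpoint tables.
#' @return A validated `study_bundle`.
#' @export
study_bundle <- function(chemicals, sites, samples, measurements,
                         acc = NULL, endpoints = NULL) {
  bundle <- list(
    chemicals = parse_chemicals(chemicals),
    sites = parse_sites(sites),
    samples = parse_samples(samples),
    measurements = parse_measurements(measurements)
  )
  if (!is.null(acc)) bundle$acc <- parse_acc(acc)
  if (!is.null(endpoints)) bundle$endpoints <- parse_endpoints(endpoints)
  as_study_bundle(bundle)
}

parse_chemicals <- function(df) {
  check_columns(df, c("cas", "name", "class", "is_pharmaceutical", "panel",
                      "mw_g_mol", "mrl_ng_l", "mdl_ng_l"), "chemicals")
  df <- as_tibble(df)
  if (!"half_life_weeks" %in% names(df)) df$half_life_weeks <- NA_real_
  df$half_life_weeks <- as.numeric(df$half_life_weeks)
  if (anyDuplicated(df$cas)) {
    abort(sprintf("integrity error in `chemicals`: duplicated cas %s",
                  paste(unique(df$cas[duplicated(df$cas)]), collapse = ", ")))
  }
  bad_panel <- setdiff(unique(df$panel), method_panels)
  if (length(bad_panel) > 0L) {
    abort(sprintf("schema error in `chemicals`: unknown panel %s",
                  paste(bad_panel, collapse = ", ")))
  }
  stopifnot_positive(df$mw_g_mol, "chemicals$mw_g_mol")
  stopifnot_positive(df$mrl_ng_l, "chemicals$mrl_ng_l")
  stopifnot_positive(df$mdl_ng_l, "chemicals$mdl_ng_l")
  df$is_pharmaceutical <- as.logical(df$is_pharmaceutical)
  df
}

parse_sites <- function(df) {
  check_columns(df, c("site_id", "watershed", "lake", "tier", "wwtp_fraction",
                      "drainage_km2", "pop_density"), "sites")
  df <- as_tibble(df)
  if (anyDuplicated(df$site_id)) {
    abort("integrity error in `sites`: duplicated site_id")
  }
  if (any(df$wwtp_fraction < 0, na.rm = TRUE)) {
    abort("schema error in `sites`: wwtp_fraction must be >= 0")
  }
  stopifnot_positive(df$drainage_km2, "sites$drainage_km2")
  df
}

parse_samples <- function(df) {
  check_columns(df, c("sample_id", "site_id", "date", "discharge",
                      "qc_type", "panels"), "samples")
  df <- as_tibble(df)
  if (anyDuplicated(df$sample_id)) {
    abort("integrity error in `samples`: duplicated sample_id")
  }
  bad_qc <- setdiff(unique(df$qc_type), qc_types)
  if (length(bad_qc) > 0L) {
    abort(sprintf("schema error in `samples`: unknown qc_type %s",
                  paste(bad_qc, collapse = ", ")))
  }
  if (is.character(df$panels)) df$panels <- split_panels(df$panels)
  df$panels <- unclass(df$panels)  # plain list column, drop any AsIs
  if (any(lengths(df$panels) == 0L)) {
    abort("schema error in `samples`: panels must be non-empty")
  }
  df
}

parse_measurements <- function(df) {
  check_columns(df, c("sample_id", "cas", "value_ng_l", "qualifier"),
                "measurements")
  df <- as_tibble(df)
  bad_q <- setdiff(unique(df$qualifier), measurement_qualifiers)
  if (length(bad_q) > 0L) {
    abort(sprintf("schema error in `measurements`: unknown qualifier %s",
                  paste(bad_q, collapse = ", ")))
  }
  df
}

parse_acc <- function(df) {
  check_columns(df, c("cas", "assay_id", "acc_um", "included"), "acc")
  df <- as_tibble(df)
  stopifnot_positive(df$acc_um, "acc$acc_um")
  if (anyDuplicated(df[c("cas", "assay_id")])) {
    abort("integrity error in `acc`: duplicated (cas, assay_id)")
  }
  df$included <- as.logical(df$included)
  df
}

parse_endpoints <- function(df) {
  check_columns(df, c("cas", "endpoint_code", "effect_level", "conc_ug_l",
                      "species", "species_group", "excluded"), "endpoints")
  df <- as_tibble(df)
  if (!"exclusion_reason" %in% names(df)) df$exclusion_reason <- NA_character_
  stopifnot_positive(df$conc_ug_l, "endpoints$conc_ug_l")
  bad_g <- setdiff(unique(df$species_group), species_groups)
  if (length(bad_g) > 0L) {
    abort(sprintf("schema error in `endpoints`: unknown species_group %s",
                  paste(bad_g, collapse = ", ")))
  }
  df$excluded <- as.logical(df$excluded)
  df
}

stopifnot_positive <- function(x, name) {
  if (any(x <= 0, na.rm = TRUE)) {
    abort(sprintf("schema error: `%s` must be > 0 (row %d)",
                  name, which(x <= 0)[1L]))
  }
  invisible(x)
}

as_study_bundle <- function(bundle) {
  # referential integrity: every foreign key must resolve
  dangling <- function(child, key, parent_keys, what) {
    bad <- which(!(child[[key]] %in% parent_keys))
    if (length(bad) > 0L) {
      abort(
        sprintf("integrity error: %s row %d references unknown %s `%s`",
                what, bad[1L], key, child[[key]][bad[1L]]),
        class = "tribscreen_integrity_error"
      )
    }
  }
  dangling(bundle$samples, "site_id", bundle$sites$site_id, "samples")
  dangling(bundle$measurements, "sample_id", bundle$samples$sample_id,
           "measurements")
  dangling(bundle$measurements, "cas", bundle$chemicals$cas, "measurements")
  if (!is.null(bundle$acc)) {
    dangling(bundle$acc, "cas", bundle$chemicals$cas, "acc")
  }
  if (!is.null(bundle$endpoints)) {
    dangling(bundle$endpoints, "cas", bundle$chemicals$cas, "endpoints")
  }
  structure(bundle, class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("<study_bundle>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-13s %6d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Write a study bundle to a directory of CSV tables
#'
#' The inverse of [read_study_tables()]: one CSV per table, using the
#' documented schemas. The list-column of method panels in `samples` is
#' serialized as a semicolon-separated string.
#'
#' @param bundle A `study_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_tables <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  flat <- bundle
  flat$samples$panels <- vapply(flat$samples$panels, paste, "", collapse = ";")
  for (nm in names(flat)) {
    readr::write_csv(flat[[nm]], file.path(dir, paste0(nm, ".csv")),
                     progress = FALSE)
  }
  invisible(dir)
}
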