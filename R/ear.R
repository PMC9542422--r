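#' Convert mass concentrations to molar concentrations
#'
#' Exposure-activity ratios compare a water concentration with an in vitro
#' activity concentration at cutoff (ACC), both in micromolar. Measured
#' concentrations arrive in ng/L, so
#' \eqn{\mu M = (ng/L) / (1000 \times MW)} with MW in g/mol.
#'
#' @param ng_l Concentration in ng/L (>= 0).
#' @param mw_g_mol Molecular weight in g/mol (> 0).
#' @return Concentration in micromolar.
#' @examples
#' ngl_to_um(100000, 100)   # 1 uM
#' @export
ngl_to_um <- function(ng_l, mw_g_mol) {
  if (any(mw_g_mol <= 0, na.rm = TRUE)) {
    abort("molecular weight must be > 0", class = "tribscreen_validation_error")
  }
  if (any(ng_l < 0, na.rm = TRUE)) abort("concentration must be >= 0")
  ng_l / (1000 * mw_g_mol)
}

#' @rdname ngl_to_um
#' @param um Concentration in micromolar.
#' @export
um_to_ngl <- function(um, mw_g_mol) {
  if (any(mw_g_mol <= 0, na.rm = TRUE)) {
    abort("molecular weight must be > 0", class = "tribscreen_validation_error")
  }
  um * 1000 * mw_g_mol
}

#' Exposure-activity ratios per sample, chemical and assay
#'
#' EAR = measured concentration (uM) / ACC (uM) for each chemical-assay
#' pair with a curated, included ACC value. Nondetects yield EAR 0;
#' interference-suppressed measurements yield no row; assays flagged as not
#' included by the upstream ACC curation are dropped (with a message, never
#' silently used).
#'
#' @param measurements Curated measurements (`sample_id`, `cas`,
#'   `curated_value`, `qualifier`).
#' @param chemicals Chemical catalog with `cas`, `mw_g_mol`.
#' @param acc ACC table (`cas`, `assay_id`, `acc_um`, `included`).
#' @return A tibble: `sample_id`, `cas`, `assay_id`, `ear`.
#' @export
compute_ear <- function(measurements, chemicals, acc) {
  check_columns(measurements, c("sample_id", "cas", "curated_value",
                                "qualifier"), "measurements")
  check_columns(acc, c("cas", "assay_id", "acc_um", "included"), "acc")
  n_excluded <- sum(!acc$included)
  if (n_excluded > 0L) {
    inform(sprintf("compute_ear: dropping %d ACC record(s) not on the curated assay list",
                   n_excluded))
  }
  acc_in <- filter(acc, .data$included)
  measurements |>
    filter(.data$qualifier != "interference") |>
    left_join(select(chemicals, "cas", "mw_g_mol"), by = "cas") |>
    inner_join(select(acc_in, "cas", "assay_id", "acc_um"), by = "cas",
               relationship = "many-to-many") |>
    mutate(ear = ngl_to_um(.data$curated_value, .data$mw_g_mol) / .data$acc_um) |>
    select("sample_id", "cas", "assay_id", "ear")
}

#' Sum EARs over a chemical's assays
#'
#' \eqn{EAR_{Chem} = \sum_i EAR_i} over the assays relevant to each
#' chemical, per sample. Chemicals with no ACC representation produce no
#' row — absence of evidence is reported as absence, never as zero hazard.
#'
#' @param ear EAR table from [compute_ear()].
#' @return A tibble: `sample_id`, `cas`, `ear_chem`, `n_assays`.
#' @export
sum_ear_chem <- function(ear) {
  check_columns(ear, c("sample_id", "cas", "ear"), "ear")
  ear |>
    group_by(.data$sample_id, .data$cas) |>
    summarise(
      ear_chem = sum(.data$ear),
      n_assays = dplyr::n(),
      .groups = "drop"
    )
}

#' Minimum ACC per chemical
#'
#' Convenience summary of the most sensitive included assay per chemical.
#'
#' @param acc ACC table (`cas`, `assay_id`, `acc_um`, `included`).
#' @return A tibble: `cas`, `min_acc_um`, `assay_id`, `n_assays`.
#' @export
min_acc_summary <- function(acc) {
  acc |>
    filter(.data$included) |>
    group_by(.data$cas) |>
    arrange(.data$acc_um, .by_group = TRUE) |>
    summarise(
      min_acc_um = first(.data$acc_um),
      assay_id = first(.data$assay_id),
      n_assays = dplyr::n(),
      .groups = "drop"
    )
}
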