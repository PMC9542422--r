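#' Classify an ecotoxicity endpoint into a benchmark subset
#'
#' Endpoints are separated into three subsets that determine the endpoint
#' application factor: \emph{No Effect} (NOEC/NOEL, or EC/LC with effect
#' level x <= 10), \emph{Low Effect} (LOEC/LOEL, or EC/LC with 10 < x < 50)
#' and \emph{Acute Effect} (EC/LC with x = 50). EC/LC endpoints with
#' x > 50 and unrecognized endpoint codes are excluded (`NA`): a
#' greater-than-half effect level has no place in a minimum-based screening
#' benchmark.
#'
#' @param endpoint_code Character: `"NOEC"`, `"NOEL"`, `"LOEC"`, `"LOEL"`,
#'   `"EC"` or `"LC"` (aliases `"ECx"`/`"LCx"` accepted).
#' @param effect_level Percent effect level x for EC/LC endpoints
#'   (0 < x <= 100); must be absent (`NA`) otherwise.
#' @return Character vector over `"NoEffect"`, `"LowEffect"`,
#'   `"AcuteEffect"`, with `NA` for excluded endpoints.
#' @examples
#' classify_endpoint(c("NOEC", "EC", "LC", "EC"), c(NA, 25, 50, 90))
#' @export
classify_endpoint <- function(endpoint_code, effect_level = NA_real_) {
  n <- max(length(endpoint_code), length(effect_level))
  code <- toupper(rep_len(endpoint_code, n))
  code[code %in% c("ECX", "LCX")] <- substr(code[code %in% c("ECX", "LCX")], 1, 2)
  x <- rep_len(as.numeric(effect_level), n)

  is_xy <- code %in% c("EC", "LC")
  if (any(is_xy & is.na(x))) {
    abort("EC/LC endpoints require an effect level")
  }
  if (any(!is_xy & !is.na(x))) {
    abort("effect level only applies to EC/LC endpoints")
  }
  if (any(is_xy & (x <= 0 | x > 100))) {
    abort("effect level must satisfy 0 < x <= 100",
          class = "tribscreen_validation_error")
  }

  out <- rep(NA_character_, n)
  out[code %in% c("NOEC", "NOEL")] <- "NoEffect"
  out[code %in% c("LOEC", "LOEL")] <- "LowEffect"
  out[is_xy & x <= 10] <- "NoEffect"
  out[is_xy & x > 10 & x < 50] <- "LowEffect"
  out[is_xy & x == 50] <- "AcuteEffect"
  out
}

#' Species application factor for an endpoint subset
#'
#' A subset is considered well characterized by test species when it covers
#' at least three distinct fish species, three distinct invertebrate
#' species, and one plant species (AF_Species = 1); otherwise AF_Species = 2.
#'
#' @param endpoints Tibble with `species` and `species_group` columns for
#'   one chemical x subset.
#' @return 1 or 2.
#' @export
species_af <- function(endpoints) {
  counts <- endpoints |>
    distinct(.data$species, .data$species_group) |>
    count(.data$species_group)
  n_of <- function(g) {
    v <- counts$n[counts$species_group == g]
    if (length(v) == 0L) 0L else v
  }
  if (n_of("fish") >= 3L && n_of("invertebrate") >= 3L && n_of("plant") >= 1L) 1 else 2
}

#' Persistence application factor
#'
#' Chemicals with an aquatic biodegradation half-life of at least 8 weeks
#' are considered persistent (AF_Persistence = 5); shorter-lived chemicals
#' get 1. The factor is never applied to the Acute Effect subset, under the
#' assumption that even a non-persistent chemical can act in the short
#' term. A missing half-life defaults conservatively to the persistent
#' factor (configurable).
#'
#' @param half_life_weeks Biodegradation half-life (weeks), or `NA`.
#' @param subset Endpoint subset label.
#' @param missing_af Factor to use when `half_life_weeks` is `NA` for a
#'   non-acute subset (default 5, conservative).
#' @return 1 or 5 (vectorized).
#' @export
persistence_af <- function(half_life_weeks, subset, missing_af = 5) {
  n <- max(length(half_life_weeks), length(subset))
  hl <- rep_len(half_life_weeks, n)
  sub <- rep_len(subset, n)
  if (any(hl <= 0, na.rm = TRUE)) abort("half_life_weeks must be > 0")
  stopifnot(missing_af %in% c(1, 5))
  out <- if_else(is.na(hl), missing_af, if_else(hl >= 8, 5, 1))
  out[sub == "AcuteEffect"] <- 1
  out
}

#' Derive screening-level benchmarks by endpoint subset
#'
#' For each chemical and non-empty endpoint subset, the benchmark is the
#' minimum endpoint concentration divided by the overall application factor:
#'
#' \deqn{benchmark = \frac{\min conc\ (\mu g/L)}{AF_{Endpoint} \times
#'   AF_{Species} \times AF_{Persistence}}}
#'
#' AF_Endpoint is 10 for the No Effect and Low Effect subsets and 100 for
#' Acute Effect. Endpoints flagged `excluded` and those that fail subset
#' classification are dropped first. Chemicals with no qualifying endpoints
#' yield no rows (not a zero, not an infinity).
#'
#' @param endpoints Endpoint records (`cas`, `endpoint_code`,
#'   `effect_level`, `conc_ug_l`, `species`, `species_group`, `excluded`).
#' @param chemicals Chemical catalog providing `half_life_weeks` per `cas`
#'   (optional column; missing values fall back to `missing_af`).
#' @param missing_af Persistence factor for chemicals without a half-life.
#' @return A tibble with one row per chemical x subset: `cas`, `subset`,
#'   `n_endpoints`, `min_conc_ug_l`, `af_endpoint`, `af_species`,
#'   `af_persistence`, `overall_af`, `benchmark_ug_l`.
#' @seealso [chemical_benchmarks()] for the per-chemical minimum used by
#'   toxicity quotients.
#' @export
derive_benchmarks <- function(endpoints, chemicals = NULL, missing_af = 5) {
  check_columns(endpoints, c("cas", "endpoint_code", "effect_level",
                             "conc_ug_l", "species", "species_group",
                             "excluded"), "endpoints")
  half_life <- if (!is.null(chemicals) && "half_life_weeks" %in% names(chemicals)) {
    select(chemicals, "cas", "half_life_weeks")
  } else {
    tibble(cas = character(), half_life_weeks = numeric())
  }

  ep <- endpoints |>
    filter(!.data$excluded) |>
    mutate(subset = classify_endpoint(.data$endpoint_code, .data$effect_level)) |>
    filter(!is.na(.data$subset))
  if (nrow(ep) == 0L) {
    return(tibble(
      cas = character(), subset = character(), n_endpoints = integer(),
      min_conc_ug_l = numeric(), af_endpoint = numeric(),
      af_species = numeric(), af_persistence = numeric(),
      overall_af = numeric(), benchmark_ug_l = numeric()
    ))
  }

  ep |>
    group_by(.data$cas, .data$subset) |>
    summarise(
      n_endpoints = dplyr::n(),
      min_conc_ug_l = min(.data$conc_ug_l),
      af_species = species_af(dplyr::pick("species", "species_group")),
      .groups = "drop"
    ) |>
    left_join(half_life, by = "cas") |>
    mutate(
      af_endpoint = if_else(.data$subset == "AcuteEffect", 100, 10),
      af_persistence = persistence_af(.data$half_life_weeks, .data$subset,
                                      missing_af = missing_af),
      overall_af = .data$af_endpoint * .data$af_species * .data$af_persistence,
      benchmark_ug_l = .data$min_conc_ug_l / .data$overall_af
    ) |>
    select("cas", "subset", "n_endpoints", "min_conc_ug_l", "af_endpoint",
           "af_species", "af_persistence", "overall_af", "benchmark_ug_l") |>
    arrange(.data$cas, .data$subset)
}

#' Per-chemical minimum benchmark
#'
#' Collapses subset-level benchmarks to the minimum per chemical — the value
#' used for toxicity quotients, chosen so that the resulting TQ is the
#' maximum over subsets.
#'
#' @param benchmarks Output of [derive_benchmarks()].
#' @return A tibble: `cas`, `benchmark_ug_l`, `subset` (the subset that
#'   supplied the minimum).
#' @export
chemical_benchmarks <- function(benchmarks) {
  benchmarks |>
    group_by(.data$cas) |>
    arrange(.data$benchmark_ug_l, .by_group = TRUE) |>
    summarise(
      benchmark_ug_l = first(.data$benchmark_ug_l),
      subset = first(.data$subset),
      .groups = "drop"
    )
}

#' Enumerate all admissible application-factor combinations
#'
#' Walks every combination of endpoint subset, species characterization and
#' persistence status allowed by the assignment rules (the persistence
#' factor never applies to the Acute Effect subset) and returns the overall
#' AF for each. The admissible overall values are
#' \{10, 20, 50, 100, 200\}.
#'
#' @return A tibble: `subset`, `af_endpoint`, `af_species`,
#'   `af_persistence`, `overall_af`, one row per admissible combination.
#' @examples
#' range(af_combinations()$overall_af)
#' @export
af_combinations <- function() {
  grid <- tidyr::expand_grid(
    subset = endpoint_subsets,
    af_species = c(1, 2),
    af_persistence = c(1, 5)
  ) |>
    mutate(af_endpoint = if_else(.data$subset == "AcuteEffect", 100, 10)) |>
    filter(!(.data$subset == "AcuteEffect" & .data$af_persistence != 1)) |>
    mutate(overall_af = .data$af_endpoint * .data$af_species * .data$af_persistence)
  select(grid, "subset", "af_endpoint", "af_species", "af_persistence",
         "overall_af")
}
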