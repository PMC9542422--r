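#' Configuration for the synthetic study generator
#'
#' Describes the shape of a synthetic tributary monitoring study: a network
#' of sites with varying wastewater influence, two to four samples per
#' site, a chemical catalog split across analytical method panels with
#' unequal site coverage, lognormal concentrations that rise with the WWTP
#' effluent fraction and during low-flow conditions, left-censoring at the
#' method detection limit, and sparse in vitro (ACC) and in vivo (endpoint)
#' benchmark coverage. A subset of chemicals can be planted with forced
#' exceedance geometry so that the prioritization stage has a known answer.
#'
#' @param seed Integer seed; every table draws from a substream derived
#'   from it, so regenerating with the same seed is bit-identical.
#' @param n_sites Number of monitoring sites (default 44).
#' @param n_tier1 Number of tier-1 sites sampled four times; the rest are
#'   tier-2 sites sampled twice (default: 20% of sites, i.e. 9 of 44).
#' @param n_chemicals Number of pharmaceutical analytes (default 257).
#' @param n_context Number of nonpharmaceutical contextual analytes
#'   (default 9).
#' @param wwtp_range Range of the WWTP effluent fraction of streamflow
#'   across sites (default `c(0, 0.45)`).
#' @param log_conc_base Median chemical-level concentration scale in ng/L
#'   (default 0.8; most chemicals sit below detection, as in a broad
#'   monitoring panel where fewer than half the analytes are ever seen).
#' @param chem_sd_log Between-chemical SD of log concentration scale
#'   (natural log; default 2.3).
#' @param sample_sd_log Within-chemical, between-sample SD of log
#'   concentration (default 0.7).
#' @param wwtp_slope Log-scale concentration increase per unit WWTP
#'   fraction (default 3: a fully effluent-dominated stream would carry
#'   about e^3 ~ 20x the concentration of an effluent-free one).
#' @param low_flow_multiplier Multiplicative concentration elevation for
#'   low-flow samples (default 1.5).
#' @param censor_at_mdl Censor values below the MDL to zero nondetects
#'   (default `TRUE`).
#' @param acc_coverage Fraction of chemicals with ToxCast-style ACC records
#'   (default 0.45).
#' @param endpoint_coverage Fraction of chemicals with ecotoxicity endpoint
#'   records (default 0.25).
#' @param planted_priority Integer indices (into the pharmaceutical
#'   catalog) of chemicals planted with forced exceedance geometry
#'   (default `1:3`; they are placed on the universally monitored M1
#'   panel).
#' @param planted_site_fraction Fraction of sites at which each planted
#'   chemical exceeds both thresholds (default 0.25).
#' @param planted_margin Multiple of each threshold achieved at planted
#'   sites (default 3; >= 2 guarantees exact recovery).
#' @param ear_threshold,tq_threshold Thresholds the planted geometry is
#'   built against (defaults 1e-3 and 0.1).
#' @param n_blanks,n_duplicates Number of field blank and duplicate QC
#'   samples (defaults 2 and 3).
#' @param m2neg_site_fraction,m2pos_site_fraction Fractions of sites whose
#'   samples also ran the M2 negative- and positive-mode panels (nested;
#'   defaults 0.6 and 0.4).
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1,
                       n_sites = 44,
                       n_tier1 = NULL,
                       n_chemicals = 257,
                       n_context = 9,
                       wwtp_range = c(0, 0.45),
                       log_conc_base = 0.8,
                       chem_sd_log = 2.3,
                       sample_sd_log = 0.7,
                       wwtp_slope = 3,
                       low_flow_multiplier = 1.5,
                       censor_at_mdl = TRUE,
                       acc_coverage = 0.45,
                       endpoint_coverage = 0.25,
                       planted_priority = 1:3,
                       planted_site_fraction = 0.25,
                       planted_margin = 3,
                       ear_threshold = 1e-3,
                       tq_threshold = 0.1,
                       n_blanks = 2,
                       n_duplicates = 3,
                       m2neg_site_fraction = 0.6,
                       m2pos_site_fraction = 0.4) {
  if (is.null(n_tier1)) n_tier1 <- max(0L, round(0.2 * n_sites))
  cfg <- as.list(environment())
  stopifnot(
    length(seed) == 1L, is.finite(seed),
    n_sites >= 2L, n_tier1 >= 0L, n_tier1 <= n_sites,
    n_chemicals >= 1L, n_context >= 0L,
    all(wwtp_range >= 0), all(wwtp_range <= 1), diff(wwtp_range) >= 0,
    log_conc_base > 0, chem_sd_log >= 0, sample_sd_log >= 0,
    low_flow_multiplier > 0,
    acc_coverage >= 0, acc_coverage <= 1,
    endpoint_coverage >= 0, endpoint_coverage <= 1,
    planted_site_fraction >= 0, planted_site_fraction <= 1,
    planted_margin > 0, ear_threshold > 0, tq_threshold > 0,
    m2neg_site_fraction >= 0, m2neg_site_fraction <= 1,
    m2pos_site_fraction >= 0, m2pos_site_fraction <= m2neg_site_fraction
  )
  planted_priority <- as.integer(planted_priority)
  if (any(planted_priority < 1L | planted_priority > n_chemicals)) {
    abort("planted_priority indices must address the pharmaceutical catalog",
          class = "tribscreen_config_error")
  }
  if (length(planted_priority) > 0L &&
      acc_coverage == 0 && endpoint_coverage == 0) {
    abort(paste("impossible planted geometry: priority chemicals need ACC",
                "and/or endpoint coverage"),
          class = "tribscreen_config_error")
  }
  cfg$planted_priority <- planted_priority
  structure(cfg, class = "sim_config")
}

# Run `expr` under a derived substream seed, restoring the caller's RNG
# state afterwards so table order never perturbs other draws.
with_substream <- function(seed, k, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((abs(seed) * 131L + k) %% 2147483647L)
  force(expr)
}

#' Generate a synthetic study bundle with ground truth
#'
#' Draws a complete study bundle (sites, samples, chemical catalog,
#' censored measurements, ACC table, endpoint records) from a
#' [sim_config()], together with the ground truth needed to verify every
#' downstream stage: the planted priority set and its exceedance sites, the
#' target minimum benchmark and minimum ACC per covered chemical, the true
#' per-site detection sets, and the planted flow and WWTP effects.
#'
#' @param config A [sim_config()].
#' @return A list with elements `bundle` (a `study_bundle`) and `truth`.
#' @examples
#' sim <- generate_bundle(sim_config(seed = 7, n_sites = 6, n_chemicals = 12))
#' sim$bundle
#' sim$truth$priority_cas
#' @export
generate_bundle <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config

  chemicals <- with_substream(cfg$seed, 1L, sim_chemicals(cfg))
  sites <- with_substream(cfg$seed, 2L, sim_sites(cfg))
  samples <- with_substream(cfg$seed, 3L, sim_samples(cfg, sites))
  meas <- with_substream(cfg$seed, 4L, sim_measurements(cfg, chemicals, sites, samples))
  measurements <- meas$measurements

  # benchmark / ACC targets are planted from the realized concentrations so
  # that non-priority chemicals can never cross a threshold
  targets <- with_substream(cfg$seed, 5L,
                            sim_targets(cfg, chemicals, sites, samples,
                                        measurements, meas$planted))
  acc <- with_substream(cfg$seed, 6L, sim_acc(cfg, targets))
  endpoints <- with_substream(cfg$seed, 7L, sim_endpoints(cfg, chemicals, targets))

  bundle <- study_bundle(
    chemicals = select(chemicals, -"log_scale"),
    sites = select(sites, -"runs_m2neg", -"runs_m2pos"),
    samples = select(samples, -"is_low_flow"),
    measurements = measurements,
    acc = if (nrow(acc) > 0L) acc else NULL,
    endpoints = if (nrow(endpoints) > 0L) endpoints else NULL
  )

  reg_ids <- samples$sample_id[samples$qc_type == "regular"]
  detections <- measurements |>
    filter(.data$sample_id %in% reg_ids,
           .data$qualifier %in% c("detect", "estimate")) |>
    left_join(select(samples, "sample_id", "site_id"), by = "sample_id") |>
    distinct(.data$site_id, .data$cas)

  truth <- list(
    priority_cas = meas$planted$cas,
    planted_sites = meas$planted$sites,
    benchmarks = targets |>
      filter(.data$has_endpoints) |>
      select("cas", benchmark_ug_l = "target_benchmark"),
    min_acc = targets |>
      filter(.data$has_acc) |>
      select("cas", min_acc_um = "target_min_acc"),
    detections = detections,
    low_flow_multiplier = cfg$low_flow_multiplier,
    wwtp_slope = cfg$wwtp_slope
  )
  list(bundle = bundle, truth = truth)
}

sim_chemicals <- function(cfg) {
  n_ph <- cfg$n_chemicals
  n_cx <- cfg$n_context
  n <- n_ph + n_cx
  use_classes <- c("Analgesic", "Antibiotic", "Antidepressant",
                   "Anticonvulsant", "Cardiovascular care", "Stimulant",
                   "Antihistamine", "Antidiabetic")
  cx_classes <- c("Pesticide", "Corrosion inhibitor", "Plasticizer",
                  "Antioxidant")

  # M1 covers ~41% of pharmaceuticals (monitored everywhere); the remainder
  # split between the two M2 ionization-mode panels with partial coverage
  n_m1 <- max(1L, round(106 / 257 * n_ph))
  n_m2neg <- round(50 / 257 * n_ph)
  panel_ph <- c(rep("M1", n_m1), rep("M2neg", n_m2neg),
                rep("M2pos", n_ph - n_m1 - n_m2neg))
  panel_cx <- rep(c("M1", "M2neg", "M2pos"), length.out = n_cx)

  mrl <- rlnorm(n, log(30), 0.5)
  tibble(
    cas = sprintf("SIM-%04d-%d", seq_len(n), (seq_len(n) * 7L) %% 10L),
    name = c(sprintf("pharma_%03d", seq_len(n_ph)),
             if (n_cx > 0L) sprintf("context_%02d", seq_len(n_cx))),
    class = c(sample(use_classes, n_ph, replace = TRUE),
              sample(cx_classes, n_cx, replace = TRUE)),
    is_pharmaceutical = rep(c(TRUE, FALSE), c(n_ph, n_cx)),
    panel = c(panel_ph, panel_cx),
    mw_g_mol = runif(n, 100, 500),
    mrl_ng_l = mrl,
    mdl_ng_l = mrl * runif(n, 0.4, 0.8),
    half_life_weeks = if_else(runif(n) < 0.05, NA_real_,
                              rlnorm(n, log(4), 0.8)),
    log_scale = log(cfg$log_conc_base) + rnorm(n, 0, cfg$chem_sd_log)
  )
}

sim_sites <- function(cfg) {
  n <- cfg$n_sites
  lakes <- sample(c("Superior", "Michigan", "Huron", "Erie", "Ontario"),
                  n, replace = TRUE, prob = c(2, 20, 1, 17, 4))
  m2neg_n <- round(cfg$m2neg_site_fraction * n)
  m2pos_n <- round(cfg$m2pos_site_fraction * n)
  m2neg_sites <- sample.int(n, m2neg_n)
  m2pos_sites <- if (m2pos_n > 0L) sample(m2neg_sites, m2pos_n) else integer()
  tibble(
    site_id = sprintf("S%02d", seq_len(n)),
    watershed = sprintf("W%02d", ((seq_len(n) - 1L) %% 16L) + 1L),
    lake = lakes,
    tier = rep(c(1L, 2L), c(cfg$n_tier1, n - cfg$n_tier1)),
    wwtp_fraction = runif(n, cfg$wwtp_range[1L], cfg$wwtp_range[2L]),
    drainage_km2 = rlnorm(n, log(500), 1.2),
    pop_density = rlnorm(n, log(100), 1.5),
    runs_m2neg = seq_len(n) %in% m2neg_sites,
    runs_m2pos = seq_len(n) %in% m2pos_sites
  )
}

sim_samples <- function(cfg, sites) {
  n_per <- if_else(sites$tier == 1L, 4L, 2L)
  idx <- rep(seq_len(nrow(sites)), n_per)
  within <- unlist(lapply(n_per, seq_len))
  panels <- lapply(idx, function(i) {
    c("M1",
      if (sites$runs_m2neg[i]) "M2neg",
      if (sites$runs_m2pos[i]) "M2pos")
  })
  base_q <- sites$drainage_km2[idx] * 0.01
  reg <- tibble(
    sample_id = sprintf("%s-R%d", sites$site_id[idx], within),
    site_id = sites$site_id[idx],
    date = as.Date("2017-10-01") + sample.int(360L, length(idx), replace = TRUE),
    discharge = base_q * exp(rnorm(length(idx), 0, 0.6)),
    qc_type = "regular",
    panels = I(panels)
  ) |>
    group_by(.data$site_id) |>
    mutate(is_low_flow = .data$discharge <= median(.data$discharge)) |>
    ungroup()

  qc <- list()
  if (cfg$n_blanks > 0L) {
    host <- sample(sites$site_id, cfg$n_blanks, replace = TRUE)
    qc$blank <- tibble(
      sample_id = sprintf("BLK-%02d", seq_len(cfg$n_blanks)),
      site_id = host,
      date = as.Date("2018-03-01") + seq_len(cfg$n_blanks),
      discharge = NA_real_,
      qc_type = "blank",
      panels = I(rep(list("M1"), cfg$n_blanks)),
      is_low_flow = FALSE
    )
  }
  if (cfg$n_duplicates > 0L) {
    dup_of <- sample(reg$sample_id, min(cfg$n_duplicates, nrow(reg)))
    src <- reg[match(dup_of, reg$sample_id), ]
    qc$dup <- src |>
      mutate(
        sample_id = sprintf("DUP-%02d", row_number()),
        qc_type = "duplicate",
        discharge = NA_real_
      )
    qc$dup$duplicate_of <- dup_of
  }
  reg$duplicate_of <- NA_character_
  if (!is.null(qc$blank)) qc$blank$duplicate_of <- NA_character_
  bind_rows(reg, qc$blank, qc$dup)
}

sim_measurements <- function(cfg, chemicals, sites, samples) {
  reg <- samples[samples$qc_type == "regular", ]
  frac <- sites$wwtp_fraction[match(reg$site_id, sites$site_id)]

  # long grid restricted to the panels each sample ran
  panel_of <- setNames(chemicals$panel, chemicals$cas)
  grid <- tidyr::expand_grid(
    sample_id = reg$sample_id,
    cas = chemicals$cas
  )
  grid$panel <- panel_of[grid$cas]
  ran <- unlist(Map(function(p, id) rep(id, length(p)), reg$panels, reg$sample_id))
  ran_panel <- unlist(reg$panels)
  grid <- semi_join(grid,
                    tibble(sample_id = ran, panel = ran_panel),
                    by = c("sample_id", "panel"))

  i_s <- match(grid$sample_id, reg$sample_id)
  i_c <- match(grid$cas, chemicals$cas)
  log_val <- chemicals$log_scale[i_c] +
    cfg$wwtp_slope * frac[i_s] +
    log(cfg$low_flow_multiplier) * reg$is_low_flow[i_s] +
    rnorm(nrow(grid), 0, cfg$sample_sd_log)
  grid$value_ng_l <- exp(log_val)

  # planted priority chemicals: zero everywhere except one detect sample at
  # each planted site, at a concentration set later to clear both
  # thresholds by the configured margin
  planted_idx <- cfg$planted_priority
  planted_cas <- chemicals$cas[chemicals$is_pharmaceutical][planted_idx]
  planted_sites <- list()
  if (length(planted_cas) > 0L) {
    samp_site <- reg$site_id[match(grid$sample_id, reg$sample_id)]
    for (p in planted_cas) {
      # exceedances land on sites actually monitored for this chemical's
      # panel, so the chemical-specific denominator sees the full fraction
      sel <- grid$cas == p
      mon_sites <- unique(samp_site[sel])
      k <- max(1L, ceiling(cfg$planted_site_fraction * length(mon_sites)))
      chosen <- sort(sample(mon_sites, k))
      planted_sites[[p]] <- chosen
      hit_samples <- vapply(chosen, function(s) {
        grid$sample_id[sel & samp_site == s][1L]
      }, "")
      grid$value_ng_l[sel] <- 0
      exceed_value <- planted_exceed_value(cfg, chemicals, p)
      grid$value_ng_l[sel & grid$sample_id %in% hit_samples] <- exceed_value
    }
  }

  # censor against the chemical's MDL/MRL
  mdl <- chemicals$mdl_ng_l[i_c]
  mrl <- chemicals$mrl_ng_l[i_c]
  if (cfg$censor_at_mdl) {
    qualifier <- dplyr::case_when(
      grid$value_ng_l < mdl ~ "nondetect",
      grid$value_ng_l < mrl ~ "estimate",
      TRUE ~ "detect"
    )
    value <- if_else(qualifier == "nondetect", 0, grid$value_ng_l)
  } else {
    qualifier <- if_else(grid$value_ng_l > 0, "detect", "nondetect")
    value <- grid$value_ng_l
  }
  measurements <- tibble(
    sample_id = grid$sample_id,
    cas = grid$cas,
    value_ng_l = value,
    qualifier = qualifier
  )

  # field duplicates: the paired regular values with analytical jitter
  dups <- samples[samples$qc_type == "duplicate", ]
  if (nrow(dups) > 0L) {
    dm <- measurements |>
      filter(.data$sample_id %in% dups$duplicate_of) |>
      rename(duplicate_of = "sample_id") |>
      left_join(select(dups, "sample_id", "duplicate_of"), by = "duplicate_of")
    jit <- exp(rnorm(nrow(dm), 0, 0.33))
    dm$value_ng_l <- dm$value_ng_l * jit
    mdl_d <- chemicals$mdl_ng_l[match(dm$cas, chemicals$cas)]
    mrl_d <- chemicals$mrl_ng_l[match(dm$cas, chemicals$cas)]
    dm$qualifier <- dplyr::case_when(
      dm$value_ng_l < mdl_d ~ "nondetect",
      dm$value_ng_l < mrl_d ~ "estimate",
      TRUE ~ "detect"
    )
    dm$value_ng_l[dm$qualifier == "nondetect"] <- 0
    measurements <- bind_rows(measurements,
                              select(dm, "sample_id", "cas", "value_ng_l",
                                     "qualifier"))
  }

  # blanks: clean except a planted sub-MRL detection of one M1 chemical
  blanks <- samples[samples$qc_type == "blank", ]
  if (nrow(blanks) > 0L) {
    m1_cas <- chemicals$cas[chemicals$panel == "M1"]
    bg <- tidyr::expand_grid(sample_id = blanks$sample_id, cas = m1_cas)
    bg$value_ng_l <- 0
    bg$qualifier <- "nondetect"
    hot <- setdiff(m1_cas, planted_cas)[1L]
    if (!is.na(hot)) {
      i_hot <- which(bg$cas == hot & bg$sample_id == blanks$sample_id[1L])
      bg$value_ng_l[i_hot] <- chemicals$mdl_ng_l[chemicals$cas == hot] * 1.2
      bg$qualifier[i_hot] <- "estimate"
    }
    measurements <- bind_rows(measurements, bg)
  }

  list(
    measurements = measurements,
    planted = list(cas = planted_cas, sites = planted_sites)
  )
}

# Concentration a planted chemical takes at its exceedance sites: clear of
# the MRL so it is an unambiguous detect.
planted_exceed_value <- function(cfg, chemicals, cas) {
  max(2 * chemicals$mrl_ng_l[chemicals$cas == cas], 1000)
}

# Decide per-chemical ACC / endpoint coverage and the target values that
# make the screening outcome exactly the planted one.
sim_targets <- function(cfg, chemicals, sites, samples, measurements, planted) {
  reg_ids <- samples$sample_id[samples$qc_type == "regular"]
  max_conc <- measurements |>
    filter(.data$sample_id %in% reg_ids, .data$qualifier != "interference") |>
    group_by(.data$cas) |>
    summarise(max_ng_l = max(.data$value_ng_l), .groups = "drop")

  out <- chemicals |>
    select("cas", "mw_g_mol", "mrl_ng_l") |>
    left_join(max_conc, by = "cas") |>
    mutate(max_ng_l = dplyr::coalesce(.data$max_ng_l, 0))

  n <- nrow(out)
  is_planted <- out$cas %in% planted$cas
  out$has_acc <- (runif(n) < cfg$acc_coverage & cfg$acc_coverage > 0) |
    (is_planted & cfg$acc_coverage > 0)
  out$has_endpoints <- (runif(n) < cfg$endpoint_coverage &
                          cfg$endpoint_coverage > 0) |
    (is_planted & cfg$endpoint_coverage > 0)

  safety <- 0.2  # non-planted chemicals top out at 20% of each threshold
  exceed_ngl <- vapply(out$cas, function(p) {
    if (p %in% planted$cas) planted_exceed_value(cfg, chemicals, p) else NA_real_
  }, 0, USE.NAMES = FALSE)

  out$target_min_acc <- dplyr::case_when(
    is_planted ~ ngl_to_um(exceed_ngl, out$mw_g_mol) /
      (cfg$planted_margin * cfg$ear_threshold),
    out$max_ng_l > 0 ~ ngl_to_um(out$max_ng_l, out$mw_g_mol) /
      (safety * cfg$ear_threshold),
    TRUE ~ 10
  )
  out$target_benchmark <- dplyr::case_when(
    is_planted ~ (exceed_ngl / 1000) / (cfg$planted_margin * cfg$tq_threshold),
    out$max_ng_l > 0 ~ (out$max_ng_l / 1000) / (safety * cfg$tq_threshold),
    TRUE ~ 100
  )
  out
}

sim_acc <- function(cfg, targets) {
  covered <- targets[targets$has_acc, ]
  if (nrow(covered) == 0L) {
    return(tibble(cas = character(), assay_id = character(),
                  acc_um = numeric(), included = logical()))
  }
  n_assays <- 1L + stats::rpois(nrow(covered), 4)
  purrr::map2_dfr(seq_len(nrow(covered)), n_assays, function(i, k) {
    generate_acc(covered$cas[i], covered$target_min_acc[i], k,
                 include_excluded = i %% 5L == 0L)
  })
}

sim_endpoints <- function(cfg, chemicals, targets) {
  covered <- targets[targets$has_endpoints, ]
  if (nrow(covered) == 0L) {
    return(tibble(cas = character(), endpoint_code = character(),
                  effect_level = numeric(), conc_ug_l = numeric(),
                  species = character(), species_group = character(),
                  excluded = logical(), exclusion_reason = character()))
  }
  hl <- chemicals$half_life_weeks[match(covered$cas, chemicals$cas)]
  subsets <- sample(endpoint_subsets, nrow(covered), replace = TRUE)
  rich <- runif(nrow(covered)) < 0.4
  purrr::pmap_dfr(
    list(covered$cas, covered$target_benchmark, subsets, rich, hl),
    function(cas, target, subset, is_rich, half_life) {
      generate_endpoints(cas, target, subset = subset,
                         species_rich = is_rich,
                         half_life_weeks = half_life)
    }
  )
}

#' Generate endpoint records whose derived benchmark equals a target
#'
#' Inverse of the benchmark formula: picks the application factors implied
#' by the requested subset, species richness and half-life, then emits a
#' minimum endpoint at `target * overall_af` ug/L plus higher-concentration
#' supporting records, so that [derive_benchmarks()] on the output recovers
#' `target` exactly.
#'
#' @param cas Chemical identifier.
#' @param target_benchmark Desired chemical benchmark (ug/L, > 0).
#' @param subset Endpoint subset to emit (`"NoEffect"`, `"LowEffect"` or
#'   `"AcuteEffect"`).
#' @param species_rich If `TRUE`, emit three fish, three invertebrate and
#'   one plant species (AF_Species 1); otherwise one fish and one
#'   invertebrate (AF_Species 2).
#' @param half_life_weeks Chemical half-life used for the persistence
#'   factor (`NA` falls back to `missing_af`).
#' @param n_extra Number of supporting endpoints above the minimum.
#' @param missing_af Persistence factor assumed when the half-life is
#'   missing (must match the value used at derivation time).
#' @return An endpoint tibble (schema of `endpoints.csv`).
#' @export
generate_endpoints <- function(cas, target_benchmark, subset = "NoEffect",
                               species_rich = TRUE, half_life_weeks = NA,
                               n_extra = 3L, missing_af = 5) {
  check_scalar_number(target_benchmark, "target_benchmark")
  stopifnot(subset %in% endpoint_subsets)
  af_endpoint <- if (subset == "AcuteEffect") 100 else 10
  af_species <- if (species_rich) 1 else 2
  af_persistence <- persistence_af(half_life_weeks, subset, missing_af)
  overall <- af_endpoint * af_species * af_persistence
  min_conc <- target_benchmark * overall

  pool <- if (species_rich) {
    tibble(
      species = c(sprintf("fish_sp_%d", 1:3), sprintf("invert_sp_%d", 1:3),
                  "plant_sp_1"),
      species_group = c(rep("fish", 3), rep("invertebrate", 3), "plant")
    )
  } else {
    tibble(species = c("fish_sp_1", "invert_sp_1"),
           species_group = c("fish", "invertebrate"))
  }
  n <- max(nrow(pool), 1L + n_extra)
  rows <- pool[rep_len(seq_len(nrow(pool)), n), ]
  code <- switch(subset, NoEffect = "NOEC", LowEffect = "LOEC",
                 AcuteEffect = "LC")
  tibble(
    cas = cas,
    endpoint_code = code,
    effect_level = if (subset == "AcuteEffect") 50 else NA_real_,
    conc_ug_l = c(min_conc, min_conc * runif(n - 1L, 1.5, 20)),
    species = rows$species,
    species_group = rows$species_group,
    excluded = FALSE,
    exclusion_reason = NA_character_
  )
}

#' Generate ACC records with a known minimum
#'
#' Emits `n_assays` included ACC records for one chemical whose minimum is
#' exactly `target_min_acc`; the remaining assays sit well above it so the
#' chemical's summed EAR stays dominated by the most sensitive assay.
#' Optionally adds a below-target record flagged as excluded by assay
#' curation, which downstream computation must ignore.
#'
#' @param cas Chemical identifier.
#' @param target_min_acc Minimum included ACC (uM, > 0).
#' @param n_assays Number of included assays (>= 1).
#' @param include_excluded Add one excluded decoy record below the target.
#' @return An ACC tibble (schema of `acc.csv`).
#' @export
generate_acc <- function(cas, target_min_acc, n_assays,
                         include_excluded = FALSE) {
  check_scalar_number(target_min_acc, "target_min_acc")
  stopifnot(n_assays >= 1L)
  acc <- c(target_min_acc, target_min_acc * runif(n_assays - 1L, 50, 500))
  out <- tibble(
    cas = cas,
    assay_id = sprintf("%s_A%02d", cas, seq_len(n_assays)),
    acc_um = acc,
    included = TRUE
  )
  if (include_excluded) {
    out <- bind_rows(out, tibble(
      cas = cas,
      assay_id = sprintf("%s_X01", cas),
      acc_um = target_min_acc / 10,
      included = FALSE
    ))
  }
  out
}
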