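# Small in-code fixtures and brute-force reference implementations used as
# independent oracles across the suite.

chem_row <- function(cas, panel = "M1", mw = 100, mrl = 30, mdl = 13,
                     pharma = TRUE, half_life = NA_real_) {
  tibble::tibble(
    cas = cas, name = paste0("chem_", cas), class = "Test",
    is_pharmaceutical = pharma, panel = panel, mw_g_mol = mw,
    mrl_ng_l = mrl, mdl_ng_l = mdl, half_life_weeks = half_life
  )
}

site_row <- function(site_id, wwtp = 0.1) {
  tibble::tibble(
    site_id = site_id, watershed = "W01", lake = "Erie", tier = 2L,
    wwtp_fraction = wwtp, drainage_km2 = 100, pop_density = 50
  )
}

sample_row <- function(sample_id, site_id, discharge = 10,
                       qc_type = "regular", panels = list("M1")) {
  tibble::tibble(
    sample_id = sample_id, site_id = site_id, date = as.Date("2018-01-01"),
    discharge = discharge, qc_type = qc_type, panels = I(panels)
  )
}

# one site, one sample, one chemical; measurement value configurable
tiny_bundle <- function(value = 100, qualifier = "detect") {
  study_bundle(
    chemicals = chem_row("C1"),
    sites = site_row("S1"),
    samples = sample_row("A1", "S1"),
    measurements = tibble::tibble(
      sample_id = "A1", cas = "C1", value_ng_l = value, qualifier = qualifier
    )
  )
}

# random multi-site fixture for brute-force comparisons (<= 10 x 10)
random_fixture <- function(seed, n_sites = 6, n_chem = 8, n_samp_per = 2) {
  withr::with_seed(seed, {
    chems <- dplyr::bind_rows(lapply(seq_len(n_chem), function(i) {
      chem_row(sprintf("C%02d", i),
               panel = sample(c("M1", "M2neg"), 1),
               mw = runif(1, 100, 400),
               mrl = runif(1, 20, 60), mdl = runif(1, 5, 19),
               half_life = sample(c(NA, runif(1, 1, 16)), 1))
    }))
    sites <- dplyr::bind_rows(lapply(seq_len(n_sites), function(i) {
      site_row(sprintf("S%02d", i), wwtp = runif(1, 0, 0.4))
    }))
    samples <- dplyr::bind_rows(lapply(seq_len(n_sites), function(i) {
      panels <- if (runif(1) < 0.5) list(c("M1", "M2neg")) else list("M1")
      dplyr::bind_rows(lapply(seq_len(n_samp_per), function(j) {
        sample_row(sprintf("S%02d-%d", i, j), sprintf("S%02d", i),
                   discharge = runif(1, 1, 100), panels = panels)
      }))
    }))
    grid <- tidyr::expand_grid(sample_id = samples$sample_id,
                               cas = chems$cas)
    grid$panel <- chems$panel[match(grid$cas, chems$cas)]
    keep <- mapply(function(sid, p) {
      p %in% samples$panels[[match(sid, samples$sample_id)]]
    }, grid$sample_id, grid$panel)
    grid <- grid[keep, ]
    grid$value_ng_l <- rlnorm(nrow(grid), log(20), 1.5)
    mdl <- chems$mdl_ng_l[match(grid$cas, chems$cas)]
    mrl <- chems$mrl_ng_l[match(grid$cas, chems$cas)]
    grid$qualifier <- ifelse(grid$value_ng_l < mdl, "nondetect",
                             ifelse(grid$value_ng_l < mrl, "estimate",
                                    "detect"))
    grid$value_ng_l[grid$qualifier == "nondetect"] <- 0
    study_bundle(chems, sites, samples,
                 grid[c("sample_id", "cas", "value_ng_l", "qualifier")])
  })
}

# brute-force endpoint benchmark: explicit loops, no dplyr
bf_benchmarks <- function(endpoints, chemicals, missing_af = 5) {
  out <- list()
  for (ch in unique(endpoints$cas)) {
    ep <- endpoints[endpoints$cas == ch & !endpoints$excluded, ]
    if (nrow(ep) == 0) next
    hl <- chemicals$half_life_weeks[chemicals$cas == ch]
    if (length(hl) == 0) hl <- NA
    for (sub in c("NoEffect", "LowEffect", "AcuteEffect")) {
      rows <- ep[!is.na(classify_endpoint(ep$endpoint_code, ep$effect_level)) &
                   classify_endpoint(ep$endpoint_code, ep$effect_level) == sub, ]
      if (nrow(rows) == 0) next
      af_e <- if (sub == "AcuteEffect") 100 else 10
      sp <- unique(rows[c("species", "species_group")])
      nf <- sum(sp$species_group == "fish")
      ni <- sum(sp$species_group == "invertebrate")
      np <- sum(sp$species_group == "plant")
      af_s <- if (nf >= 3 && ni >= 3 && np >= 1) 1 else 2
      af_p <- if (sub == "AcuteEffect") 1 else
        if (is.na(hl)) missing_af else if (hl >= 8) 5 else 1
      out[[length(out) + 1]] <- tibble::tibble(
        cas = ch, subset = sub,
        benchmark_ug_l = min(rows$conc_ug_l) / (af_e * af_s * af_p)
      )
    }
  }
  dplyr::bind_rows(out)
}

# brute-force site flags: loops over sites and chemicals
bf_site_flags <- function(ear_chem, tq, samples, ear_thr, tq_thr) {
  reg <- samples[samples$qc_type == "regular", ]
  all_cas <- union(unique(ear_chem$cas), unique(tq$cas))
  out <- list()
  for (s in unique(reg$site_id)) {
    sids <- reg$sample_id[reg$site_id == s]
    for (ch in all_cas) {
      e <- ear_chem$ear_chem[ear_chem$sample_id %in% sids & ear_chem$cas == ch]
      q <- tq$tq[tq$sample_id %in% sids & tq$cas == ch]
      if (length(e) == 0 && length(q) == 0) next
      out[[length(out) + 1]] <- tibble::tibble(
        site_id = s, cas = ch,
        max_ear_chem = if (length(e)) max(e) else NA_real_,
        max_tq = if (length(q)) max(q) else NA_real_,
        exceeds_ear = if (length(e)) max(e) > ear_thr else NA,
        exceeds_tq = if (length(q)) max(q) > tq_thr else NA
      )
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), site_id, cas)
}

# brute-force sum of per-pair maxima
bf_sum_max_ear <- function(ear, samples) {
  reg <- samples[samples$qc_type == "regular", ]
  out <- numeric()
  for (s in unique(reg$site_id)) {
    sids <- reg$sample_id[reg$site_id == s]
    sub <- ear[ear$sample_id %in% sids, ]
    total <- 0
    for (key in unique(paste(sub$cas, sub$assay_id))) {
      rows <- sub[paste(sub$cas, sub$assay_id) == key, ]
      total <- total + max(rows$ear)
    }
    out[s] <- total
  }
  out
}
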