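test_that("the generator is deterministic for a fixed seed", {
  cfg <- sim_config(seed = 5, n_sites = 6, n_chemicals = 12)
  a <- generate_bundle(cfg)
  b <- generate_bundle(cfg)
  expect_identical(a$bundle$measurements, b$bundle$measurements)
  expect_identical(a$bundle$chemicals, b$bundle$chemicals)
  expect_identical(a$truth$planted_sites, b$truth$planted_sites)
  c <- generate_bundle(sim_config(seed = 6, n_sites = 6, n_chemicals = 12))
  expect_false(identical(a$bundle$measurements, c$bundle$measurements))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(planted_priority = 99, n_chemicals = 10),
               class = "tribscreen_config_error")
  expect_error(sim_config(acc_coverage = 0, endpoint_coverage = 0),
               class = "tribscreen_config_error")
  expect_silent(sim_config(acc_coverage = 0, endpoint_coverage = 0,
                           planted_priority = integer(0)))
  expect_error(sim_config(low_flow_multiplier = 0))
  expect_error(sim_config(acc_coverage = 1.5))
})

test_that("endpoint generation inverts benchmark derivation exactly", {
  # species-poor, persistent, NoEffect at target 0.5 -> minimum endpoint 50
  ep <- generate_endpoints("C1", 0.5, subset = "NoEffect",
                           species_rich = FALSE, half_life_weeks = 12)
  expect_equal(min(ep$conc_ug_l), 50)
  b <- derive_benchmarks(ep, chem_row("C1", half_life = 12))
  expect_equal(b$benchmark_ug_l, 0.5)
  expect_equal(b$af_species, 2)
  expect_equal(b$af_persistence, 5)

  # well-characterized species recover AF_Species 1
  ep2 <- generate_endpoints("C1", 0.5, species_rich = TRUE,
                            half_life_weeks = 12)
  b2 <- derive_benchmarks(ep2, chem_row("C1", half_life = 12))
  expect_equal(b2$af_species, 1)

  withr::with_seed(77, {
    for (i in 1:100) {
      target <- 10^runif(1, -4, 3)
      subset <- sample(c("NoEffect", "LowEffect", "AcuteEffect"), 1)
      rich <- runif(1) < 0.5
      hl <- sample(c(NA, runif(1, 1, 20)), 1)
      ep <- generate_endpoints("C1", target, subset = subset,
                               species_rich = rich, half_life_weeks = hl)
      got <- chemical_benchmarks(
        derive_benchmarks(ep, chem_row("C1", half_life = hl)))
      expect_lt(abs(got$benchmark_ug_l - target) / target, 1e-9)
    }
  })
})

test_that("ACC generation plants the minimum and supports closed-form EARs", {
  one <- generate_acc("C1", 0.25, 1)
  expect_equal(one$acc_um, 0.25)
  withr::with_seed(55, {
    ten <- generate_acc("C1", 0.25, 10)
    expect_equal(min(ten$acc_um[ten$included]), 0.25)
    expect_true(all(ten$acc_um[ten$included] >= 0.25))

    # EAR_Chem of a known concentration is the sum of conc/ACC over assays
    chems <- chem_row("C1", mw = 200)
    meas <- tibble::tibble(sample_id = "s1", cas = "C1",
                           curated_value = 50000, qualifier = "detect")
    ear <- compute_ear(meas, chems, ten)
    conc_um <- 50000 / (1000 * 200)
    expect_equal(sum_ear_chem(ear)$ear_chem,
                 sum(conc_um / ten$acc_um[ten$included]))
  })
  # excluded decoys sit below the included minimum but must not move it
  withr::with_seed(56, {
    dec <- generate_acc("C1", 1, 3, include_excluded = TRUE)
    expect_equal(min(dec$acc_um), 0.1)
    expect_equal(min(dec$acc_um[dec$included]), 1)
  })
})

test_that("planted priority chemicals exceed both thresholds at their sites only", {
  sim <- generate_bundle(sim_config(seed = 8, n_sites = 12, n_chemicals = 30))
  b <- sim$bundle
  res <- run_pipeline(b)
  for (p in sim$truth$priority_cas) {
    fl <- res$flags[res$flags$cas == p, ]
    exceed_sites <- fl$site_id[fl$exceeds_ear | fl$exceeds_tq]
    expect_setequal(exceed_sites, sim$truth$planted_sites[[p]])
    # margin: both metrics clear their thresholds by the configured factor
    mx <- fl[fl$site_id %in% sim$truth$planted_sites[[p]], ]
    expect_true(all(mx$max_ear_chem > 2 * 1e-3))
    expect_true(all(mx$max_tq > 2 * 0.1))
  }
})

test_that("planted benchmark and ACC targets are recovered from the tables", {
  sim <- generate_bundle(sim_config(seed = 14, n_sites = 6, n_chemicals = 20))
  b <- sim$bundle
  got_bench <- chemical_benchmarks(derive_benchmarks(b$endpoints, b$chemicals))
  joined <- dplyr::inner_join(got_bench, sim$truth$benchmarks, by = "cas")
  expect_equal(nrow(joined), nrow(sim$truth$benchmarks))
  expect_equal(joined$benchmark_ug_l.x, joined$benchmark_ug_l.y,
               tolerance = 1e-9)

  got_acc <- min_acc_summary(b$acc)
  j2 <- dplyr::inner_join(got_acc, sim$truth$min_acc, by = "cas")
  expect_equal(j2$min_acc_um.x, j2$min_acc_um.y, tolerance = 1e-12)
})

test_that("generated bundles carry the study's structural features", {
  sim <- generate_bundle(sim_config(seed = 2))
  b <- sim$bundle
  expect_equal(nrow(b$sites), 44L)
  expect_equal(nrow(b$chemicals), 266L)
  expect_equal(sum(b$chemicals$is_pharmaceutical), 257L)
  # every site runs M1; only a subset runs the M2 panels
  reg <- b$samples[b$samples$qc_type == "regular", ]
  expect_true(all(vapply(reg$panels, function(p) "M1" %in% p, TRUE)))
  m2_sites <- unique(reg$site_id[vapply(reg$panels,
                                        function(p) "M2neg" %in% p, TRUE)])
  expect_lt(length(m2_sites), 44L)
  expect_gt(length(m2_sites), 0L)
  # tier-1 sites have four samples, tier-2 two
  per_site <- table(reg$site_id)
  tier1 <- b$sites$site_id[b$sites$tier == 1L]
  expect_true(all(per_site[tier1] == 4L))
  expect_true(all(per_site[setdiff(names(per_site), tier1)] == 2L))
  # roughly half of the detected chemicals lack any screening value
  res <- run_pipeline(b)
  n_det <- sum(res$detection$sites_detected > 0)
  expect_gt(nrow(res$gap_report) / n_det, 0.25)
  expect_lt(nrow(res$gap_report) / n_det, 0.75)
})

test_that("a planted positive WWTP effect is recovered across seeds", {
  rej <- vapply(1:100, function(s) {
    cfg <- sim_config(seed = s, n_sites = 44, n_chemicals = 40, n_context = 0,
                      acc_coverage = 0, endpoint_coverage = 0,
                      planted_priority = integer(0), n_blanks = 0,
                      n_duplicates = 0)
    b <- generate_bundle(cfg)$bundle
    meas <- curate_measurements(b$measurements, b$chemicals)
    reg <- b$samples[b$samples$qc_type == "regular", ]
    sums <- sum_panel_concentrations(meas, reg, b$chemicals, "M1")
    wc <- wwtp_correlation(sums, b$sites)
    wc$r > 0 && wc$p_value < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.95)
})
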