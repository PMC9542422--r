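test_that("censoring rules map raw values to the right qualifiers", {
  out <- curate_measurement(c(5, 20, 100, NA), mdl = 13, mrl = 30)
  expect_equal(out$qualifier, c("nondetect", "estimate", "detect", "nondetect"))
  expect_equal(out$curated_value, c(0, 20, 100, 0))

  sev <- curate_measurement(100, 13, 30, interference = "severe")
  expect_equal(sev$qualifier, "interference")
  expect_true(is.na(sev$curated_value))

  minor <- curate_measurement(100, 13, 30, interference = "minor")
  expect_equal(minor$qualifier, "estimate")
  expect_equal(minor$curated_value, 100)

  expect_error(curate_measurement(-1, 13, 30), class = "tribscreen_validation_error")
  expect_error(curate_measurement(5, -1, 30))
})

test_that("curation is idempotent and monotone in the detection limit", {
  withr::with_seed(42, {
    v <- c(0, rlnorm(200, log(20), 1))
    once <- curate_measurement(v, 13, 30)
    twice <- curate_measurement(once$curated_value, 13, 30)
    expect_equal(twice, once)

    # raising the MDL can only push values toward nondetect, never away
    lo <- curate_measurement(v, 10, 30)$qualifier
    hi <- curate_measurement(v, 25, 30)$qualifier
    expect_false(any(lo == "nondetect" & hi %in% c("detect", "estimate")))
  })
})

test_that("curate_measurements joins limits by CAS and preserves interference", {
  chems <- dplyr::bind_rows(chem_row("C1", mdl = 13, mrl = 30),
                            chem_row("C2", mdl = 50, mrl = 100))
  m <- tibble::tibble(
    sample_id = "A1", cas = c("C1", "C2", "C2"),
    value_ng_l = c(20, 20, 200),
    qualifier = c("detect", "detect", "interference")
  )
  out <- curate_measurements(m, chems)
  expect_equal(out$qualifier, c("estimate", "nondetect", "interference"))
  expect_equal(out$curated_value, c(20, 0, NA))

  expect_error(
    curate_measurements(tibble::tibble(sample_id = "A1", cas = "XX",
                                       value_ng_l = 1), chems),
    "unknown cas"
  )
})

test_that("detection frequency uses chemical-specific monitored-site denominators", {
  # C1 on M1 is monitored at both sites; C2 on M2neg only at S1
  chems <- dplyr::bind_rows(chem_row("C1", "M1"), chem_row("C2", "M2neg"))
  sites <- dplyr::bind_rows(site_row("S1"), site_row("S2"))
  samples <- dplyr::bind_rows(
    sample_row("A1", "S1", panels = list(c("M1", "M2neg"))),
    sample_row("A2", "S2", panels = list("M1"))
  )
  meas <- tibble::tibble(
    sample_id = c("A1", "A2", "A1"),
    cas = c("C1", "C1", "C2"),
    value_ng_l = c(100, 0, 100),
    qualifier = c("detect", "nondetect", "detect")
  ) |> curate_measurements(chems)

  df <- detection_frequency(meas, samples, chems)
  expect_equal(df$sites_monitored, c(2L, 1L))
  expect_equal(df$sites_detected, c(1L, 1L))
  expect_equal(df$det_freq, c(50, 100))
})

test_that("detection frequency matches a brute-force site-set computation", {
  for (seed in 1:5) {
    b <- random_fixture(seed)
    meas <- curate_measurements(b$measurements, b$chemicals)
    got <- detection_frequency(meas, b$samples, b$chemicals)
    for (i in sample(nrow(got), 4)) {
      ch <- got$cas[i]
      panel <- b$chemicals$panel[b$chemicals$cas == ch]
      mon <- unique(b$samples$site_id[vapply(b$samples$panels,
                                             function(p) panel %in% p, TRUE)])
      det <- unique(b$samples$site_id[match(
        meas$sample_id[meas$cas == ch &
                         meas$qualifier %in% c("detect", "estimate")],
        b$samples$sample_id)])
      expect_equal(got$sites_monitored[i], length(mon))
      expect_equal(got$sites_detected[i], length(intersect(det, mon)))
    }
  }
})

test_that("relative percent difference is symmetric and matches hand arithmetic", {
  expect_equal(relative_percent_difference(100, 100), 0)
  expect_equal(relative_percent_difference(3, 1), 100)
  expect_equal(relative_percent_difference(100, 81), 19 / 90.5 * 100)
  expect_equal(relative_percent_difference(81, 100),
               relative_percent_difference(100, 81))
  expect_warning(out <- relative_percent_difference(0, 0))
  expect_true(is.na(out))
})

test_that("blank screening reports detections without touching regular data", {
  chems <- chem_row("C1", mrl = 30)
  sites <- site_row("S1")
  samples <- dplyr::bind_rows(
    sample_row("A1", "S1"),
    sample_row("B1", "S1", discharge = NA, qc_type = "blank"),
    sample_row("B2", "S1", discharge = NA, qc_type = "blank"),
    sample_row("B3", "S1", discharge = NA, qc_type = "blank")
  )
  meas <- tibble::tibble(
    sample_id = c("A1", "B1", "B2", "B3"),
    cas = "C1",
    value_ng_l = c(100, 15, 20, 25),
    qualifier = c("detect", "estimate", "estimate", "estimate"),
    curated_value = c(100, 15, 20, 25)
  )
  rep <- blank_screen(meas, samples, chems)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$n_blank_detections, 3L)
  expect_equal(rep$max_blank_value, 25)
  expect_true(rep$below_mrl)

  none <- blank_screen(meas[1, ], samples, chems)
  expect_equal(nrow(none), 0L)
})

test_that("panel sums skip other panels and refuse samples without the panel", {
  chems <- dplyr::bind_rows(
    chem_row("C1", "M1"), chem_row("C2", "M1"), chem_row("C3", "M1"),
    chem_row("C4", "M2neg")
  )
  sites <- site_row("S1")
  samples <- sample_row("A1", "S1", panels = list(c("M1", "M2neg")))
  meas <- tibble::tibble(
    sample_id = "A1", cas = c("C1", "C2", "C3", "C4"),
    value_ng_l = c(100, 0, 50, 77777),
    qualifier = c("detect", "nondetect", "detect", "detect"),
    curated_value = c(100, 0, 50, 77777)
  )
  out <- sum_panel_concentrations(meas, samples, chems, "M1")
  expect_equal(out$sum_ng_l, 150)
  # varying the M2 chemical leaves the M1 sum unchanged
  meas2 <- dplyr::mutate(meas, curated_value = ifelse(cas == "C4", 1, curated_value))
  expect_equal(sum_panel_concentrations(meas2, samples, chems, "M1")$sum_ng_l, 150)
  # row order invariance and additivity over disjoint chemical subsets
  shuf <- meas[c(3, 1, 4, 2), ]
  expect_equal(sum_panel_concentrations(shuf, samples, chems, "M1")$sum_ng_l, 150)
  part1 <- sum_panel_concentrations(meas[meas$cas %in% c("C1"), ], samples, chems, "M1")
  part2 <- sum_panel_concentrations(meas[meas$cas %in% c("C2", "C3"), ], samples, chems, "M1")
  expect_equal(part1$sum_ng_l + part2$sum_ng_l, 150)

  expect_error(sum_panel_concentrations(meas, samples, chems, "M2pos"),
               class = "tribscreen_panel_error")
})

test_that("bundles round-trip through CSV and enforce integrity", {
  b <- tiny_bundle()
  expect_equal(nrow(b$measurements), 1L)

  dir <- withr::local_tempdir()
  write_study_tables(b, dir)
  back <- read_study_tables(dir)
  expect_equal(back$chemicals, b$chemicals)
  expect_equal(back$measurements, b$measurements)
  expect_equal(back$samples$panels, b$samples$panels)

  expect_error(
    study_bundle(b$chemicals, b$sites, b$samples,
                 tibble::tibble(sample_id = "A1", cas = "NOPE",
                                value_ng_l = 1, qualifier = "detect")),
    class = "tribscreen_integrity_error"
  )
  expect_error(
    study_bundle(dplyr::select(b$chemicals, -mrl_ng_l), b$sites, b$samples,
                 b$measurements),
    class = "tribscreen_schema_error"
  )
})

test_that("the default synthetic bundle reads back with the study's site count", {
  sim <- generate_bundle(sim_config(seed = 11, n_chemicals = 30))
  dir <- withr::local_tempdir()
  write_study_tables(sim$bundle, dir)
  back <- read_study_tables(dir)
  expect_equal(nrow(back$sites), 44L)
  expect_s3_class(back, "study_bundle")
})
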