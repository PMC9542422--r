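test_that("endpoint codes map to the three benchmark subsets", {
  expect_equal(classify_endpoint("NOEC"), "NoEffect")
  expect_equal(classify_endpoint("NOEL"), "NoEffect")
  expect_equal(classify_endpoint("LOEC"), "LowEffect")
  expect_equal(classify_endpoint("EC", 10), "NoEffect")
  expect_equal(classify_endpoint("EC", 25), "LowEffect")
  expect_equal(classify_endpoint("LC", 50), "AcuteEffect")
  # beyond-half effect levels and unknown codes are excluded, not guessed
  expect_true(is.na(classify_endpoint("EC", 90)))
  expect_true(is.na(classify_endpoint("MATC")))
  expect_error(classify_endpoint("EC"), "effect level")
  expect_error(classify_endpoint("EC", 150),
               class = "tribscreen_validation_error")
})

test_that("species characterization needs 3 fish, 3 invertebrates and a plant", {
  rich <- tibble::tibble(
    species = c("f1", "f2", "f3", "i1", "i2", "i3", "p1"),
    species_group = c(rep("fish", 3), rep("invertebrate", 3), "plant")
  )
  expect_equal(species_af(rich), 1)
  expect_equal(species_af(rich[rich$species_group != "plant", ]), 2)
  # distinct species, not record counts: the same fish tested 10 times is 1
  dup <- rich[c(1, 1, 1, 4, 4, 4, 7), ]
  expect_equal(species_af(dup), 2)
  many <- tibble::tibble(
    species = c(paste0("f", 1:10), paste0("i", 1:10), paste0("p", 1:5)),
    species_group = rep(c("fish", "invertebrate", "plant"), c(10, 10, 5))
  )
  expect_equal(species_af(many), 1)
})

test_that("persistence factor follows the 8-week rule and skips acute subsets", {
  expect_equal(persistence_af(12, "NoEffect"), 5)
  expect_equal(persistence_af(4, "LowEffect"), 1)
  expect_equal(persistence_af(12, "AcuteEffect"), 1)
  expect_equal(persistence_af(8, "NoEffect"), 5)   # boundary: persistent
  expect_equal(persistence_af(NA, "NoEffect"), 5)  # conservative default
  expect_equal(persistence_af(NA, "NoEffect", missing_af = 1), 1)
})

test_that("benchmarks divide the subset minimum by the overall AF", {
  # species-poor, persistent chemical: NoEffect {100, 50} -> 50/(10*2*5)
  ep <- tibble::tibble(
    cas = "C1", endpoint_code = "NOEC", effect_level = NA_real_,
    conc_ug_l = c(100, 50), species = c("f1", "f2"),
    species_group = "fish", excluded = FALSE
  )
  chems <- chem_row("C1", half_life = 12)
  b <- derive_benchmarks(ep, chems)
  expect_equal(b$min_conc_ug_l, 50)
  expect_equal(b$overall_af, 100)
  expect_equal(b$benchmark_ug_l, 0.5)

  # adding an acute subset: 500/(100*2*1) = 2.5; chemical minimum stays 0.5
  ep2 <- dplyr::bind_rows(ep, tibble::tibble(
    cas = "C1", endpoint_code = "LC", effect_level = 50, conc_ug_l = 500,
    species = "f1", species_group = "fish", excluded = FALSE
  ))
  b2 <- derive_benchmarks(ep2, chems)
  expect_equal(sort(b2$benchmark_ug_l), c(0.5, 2.5))
  cb <- chemical_benchmarks(b2)
  expect_equal(cb$benchmark_ug_l, 0.5)
  expect_equal(cb$subset, "NoEffect")

  # excluded endpoints and chemicals without qualifying records yield nothing
  ep3 <- dplyr::mutate(ep, excluded = TRUE)
  expect_equal(nrow(derive_benchmarks(ep3, chems)), 0L)
})

test_that("benchmarks are monotone under added endpoints and scale-equivariant", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      n <- sample(3:12, 1)
      ep <- tibble::tibble(
        cas = "C1",
        endpoint_code = sample(c("NOEC", "LOEC", "EC", "LC"), n, replace = TRUE),
        species = sample(paste0("sp", 1:6), n, replace = TRUE),
        species_group = sample(c("fish", "invertebrate", "plant"), n,
                               replace = TRUE),
        conc_ug_l = rlnorm(n, 3, 1),
        excluded = FALSE
      )
      ep$effect_level <- ifelse(ep$endpoint_code %in% c("EC", "LC"),
                                sample(c(5, 25, 50), n, replace = TRUE), NA)
      chems <- chem_row("C1", half_life = sample(c(NA, 4, 12), 1))

      base <- derive_benchmarks(ep, chems)
      # adding one endpoint never increases any existing subset benchmark
      extra <- ep[sample(nrow(ep), 1), ]
      extra$conc_ug_l <- rlnorm(1, 3, 1)
      more <- derive_benchmarks(dplyr::bind_rows(ep, extra), chems)
      joined <- dplyr::inner_join(base, more, by = c("cas", "subset"))
      expect_true(all(joined$benchmark_ug_l.y <= joined$benchmark_ug_l.x + 1e-12))

      # multiplying all concentrations by k scales every benchmark by k
      k <- runif(1, 0.1, 10)
      scaled <- derive_benchmarks(dplyr::mutate(ep, conc_ug_l = conc_ug_l * k),
                                  chems)
      expect_equal(scaled$benchmark_ug_l, base$benchmark_ug_l * k)
    }
  })
})

test_that("derive_benchmarks agrees with a brute-force reference", {
  withr::with_seed(7, {
    for (rep in 1:30) {
      n_chem <- sample(2:5, 1)
      n <- sample(5:50, 1)
      ep <- tibble::tibble(
        cas = sample(paste0("C", 1:n_chem), n, replace = TRUE),
        endpoint_code = sample(c("NOEC", "NOEL", "LOEC", "LOEL", "EC", "LC",
                                 "MATC"), n, replace = TRUE),
        species = sample(paste0("sp", 1:8), n, replace = TRUE),
        species_group = sample(c("fish", "invertebrate", "plant", "other"),
                               n, replace = TRUE),
        conc_ug_l = rlnorm(n, 2, 2),
        excluded = runif(n) < 0.15
      )
      ep$effect_level <- ifelse(ep$endpoint_code %in% c("EC", "LC"),
                                sample(c(5, 10, 25, 50, 90), n, replace = TRUE),
                                NA)
      chems <- dplyr::bind_rows(lapply(paste0("C", 1:n_chem), function(ch) {
        chem_row(ch, half_life = sample(c(NA, 2, 20), 1))
      }))
      got <- derive_benchmarks(ep, chems)
      want <- bf_benchmarks(ep, chems)
      got <- dplyr::arrange(got, cas, subset)
      want <- dplyr::arrange(want, cas, subset)
      expect_equal(got[c("cas", "subset", "benchmark_ug_l")],
                   want[c("cas", "subset", "benchmark_ug_l")])
    }
  })
})

test_that("admissible AF combinations span exactly {10, 20, 50, 100, 200}", {
  combos <- af_combinations()
  expect_setequal(unique(combos$overall_af), c(10, 20, 50, 100, 200))
  expect_equal(max(combos$overall_af), 200)
  expect_equal(min(combos$overall_af), 10)
  # the acute subset never carries a persistence factor
  expect_true(all(combos$af_persistence[combos$subset == "AcuteEffect"] == 1))
})
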