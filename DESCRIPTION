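Package: tribscreen
Title: Risk-Based Screening of Pharmaceuticals in Tributary Surface Waters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for risk-based screening of pharmaceuticals and other
    organic contaminants measured in surface waters. Implements curation of
    left-censored concentration data (method detection and reporting limits,
    interference qualifiers), derivation of screening-level benchmarks from
    in vivo ecotoxicity endpoints via endpoint-subset classification and
    application factors, exposure-activity ratios (EARs) against in vitro
    activity concentrations at cutoff, toxicity quotients (TQs), a
    sites-based prioritization framework, per-site hazard summaries,
    hydrologic condition comparisons, and wastewater-effluent correlation
    analysis. Includes a seeded synthetic-data generator that emulates a
    multi-site tributary monitoring study with known ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
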