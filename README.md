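# tribscreen

Risk-based screening of pharmaceuticals in tributary surface waters.

Monitoring programs routinely detect dozens of pharmaceuticals in streams,
but almost none of these compounds have formally established water-quality
benchmarks. `tribscreen` implements the screening workflow used to rank
such contaminants by their potential for biological effects: measured
concentrations are compared against two kinds of *alternative benchmarks* —
high-throughput in vitro activity concentrations (ToxCast-style ACC values)
and screening-level benchmarks derived from in vivo ecotoxicity endpoints
(ECOTOX-style records) — and chemicals are prioritized by how often they
exceed either threshold across the monitored site network. The package is
aimed at environmental toxicologists and water-quality analysts who want a
tested, reusable implementation of this pipeline, together with a seeded
synthetic-data generator for methods work and power analysis.

## The screening model

For a chemical–assay pair, the **exposure–activity ratio** is

    EAR = C_uM / ACC_uM,            EAR_Chem = sum_i EAR_i

where `C_uM` is the measured water concentration (µM) and `ACC_uM` the
assay's activity concentration at cutoff; `EAR_Chem` sums a chemical's
relevant assays per sample.

In vivo endpoints are classified into three subsets — *No Effect*
(NOEC/NOEL, EC/LC with x ≤ 10), *Low Effect* (LOEC/LOEL, EC/LC with
10 < x < 50) and *Acute Effect* (EC/LC50) — and each subset's minimum
concentration is divided by an overall **application factor**:

    benchmark = min(conc_ug_L) / (AF_Endpoint × AF_Species × AF_Persistence)

with `AF_Endpoint` 10 (No/Low Effect) or 100 (Acute), `AF_Species` 1 when
the subset covers ≥ 3 fish, ≥ 3 invertebrate and ≥ 1 plant species (else
2), and `AF_Persistence` 5 for chemicals with a biodegradation half-life of
at least 8 weeks (else 1; never applied to the acute subset). Admissible
overall factors are {10, 20, 50, 100, 200}. The **toxicity quotient** uses
the minimum benchmark per chemical:

    TQ = C_ug_L / benchmark

A chemical is **high priority** when `EAR_Chem > 1e-3` or `TQ > 0.1` at
≥ 10% of the sites monitored for its presence (site value = maximum across
that site's regular samples; denominators are chemical-specific because
the two analytical method panels cover different site subsets).

Around this core the package provides censored-data curation (MDL/MRL
qualifiers, interference, blank and duplicate QC), detection frequencies,
per-site hazard summaries with incremental ×1/×10/×100 exceedance tiers, a
low-flow vs increased-flow comparison of site-normalized concentration
sums, and the correlation of site median concentrations with the fraction
of streamflow attributable to wastewater-treatment-plant (WWTP) effluent.

## Worked example

```r
library(tribscreen)

sim <- generate_bundle(sim_config(seed = 1))   # 44 sites, 266 chemicals
res <- run_pipeline(sim$bundle)
res
#> <screening_results>
#>   chemicals detected: 116
#>   with >=1 screening value: 69
#>   lacking screening values: 47
#>   high-priority chemicals: 3
#>   flow effect: +67% (p = 8.17e-19)
#>   WWTP correlation: r = 0.79 (p = 1.32e-10)
```

Of 266 monitored chemicals, 116 were detected somewhere; 47 of those carry
neither an ACC value nor a derivable endpoint benchmark, so no hazard
quotient exists for them (they appear in `res$gap_report`, ordered by
detection frequency — the knowledge-gap list). The three flagged
high-priority chemicals are exactly the three the generator planted with
forced exceedance geometry:

```r
dplyr::filter(res$priority, priority)
#>   cas        name       ear_exceed_sites tq_exceed_sites sites_monitored
#> 1 SIM-0001-7 pharma_001               11              11              44
#> 2 SIM-0002-4 pharma_002               11              11              44
#> 3 SIM-0003-1 pharma_003               11              11              44
```

Eleven of 44 sites (25%) exceed both thresholds, well past the 10% rule.
The hydrology results are broom-style objects:

```r
tidy(res$flow_test)
#>   statistic    df  p_value median_low median_increased percent_difference
#> 1      10.9  104. 8.17e-19       1.25            0.748               67.4
autoplot(res$wwtp)   # site medians vs WWTP fraction, with the OLS line
```

Site-normalized concentration sums during low-flow sampling are 67% higher
at the median than during increased flow (the generator's planted 1.5×
low-flow elevation plus sampling noise), and site median concentrations
rise with the WWTP effluent fraction (r = 0.79). A thin command-line
wrapper is included at `inst/scripts/tribscreen.R`
(`validate` / `simulate` / `run` subcommands).

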