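---
title: "Risk-based screening of pharmaceuticals in tributary monitoring data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-based screening of pharmaceuticals in tributary monitoring data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tribscreen)
library(dplyr)
```

## The screening problem

Streams receiving treated wastewater carry low (ng/L) but nearly ubiquitous
concentrations of pharmaceuticals. Regulatory water-quality benchmarks exist
for almost none of them, so a screening assessment must rank chemicals using
whatever biological-effects information is available: high-throughput in
vitro assay potencies (activity concentrations at cutoff, ACC, in µM) and
collations of in vivo ecotoxicity endpoints (NOEC/LOEC/EC50-type records, in
µg/L). `tribscreen` implements that workflow end to end on tabular
monitoring data: curation of left-censored measurements, derivation of
screening-level benchmarks, exposure–activity ratios and toxicity quotients,
a sites-based prioritization rule, per-site hazard summaries, and two
hydrologic analyses (flow-condition comparison, wastewater-effluent
correlation).

The package makes three structural assumptions. First, evidence absence is
never hazard absence: a chemical with no ACC record and no derivable
endpoint benchmark produces *no* quotient (reported as unavailable, "–"),
lands in the gap report, and can never be prioritized. Second, screening is
deliberately conservative where the data are thin: minimum endpoint
concentrations, minimum benchmarks (hence maximum TQs), application factors
that grow when species coverage or persistence information is weak. Third,
all joins run on CAS identifiers; chemical names are display-only.

## Curation rules

Raw values are compared with two per-chemical limits: the method detection
limit (MDL) and the larger method reporting limit (MRL). Values below the
MDL become zero-valued nondetects; values in [MDL, MRL) are kept but
qualified as estimates; values at or above the MRL are detects. Severe
analytical interference suppresses the value entirely (an `interference`
row, distinct from a nondetect); minor interference downgrades a detect to
an estimate. The rules were left open for one case — whether minor
interference retains detect status — and we chose the downgrade because an
interference-affected quantitation is by construction an estimate.

Estimates count as detections everywhere: in detection frequencies, panel
sums, EARs and TQs. Zeroing sub-MDL values biases sums low; summary
statistics therefore use only above-detection values, and the censoring
choice is exposed in the generator (`censor_at_mdl`) so its effect can be
measured. Curation is idempotent, and raising the MDL can only move values
toward nondetect.

Field QC is kept strictly out of the screening path: blanks feed
`blank_screen()` (which never adjusts regular data), duplicates feed
relative-percent-difference checks, and only `regular` samples enter
detection frequencies, site flags and hydrology.

## Benchmarks, EARs, TQs, prioritization

Endpoints are classified into No Effect (NOEC/NOEL, EC/LC with effect level
x ≤ 10), Low Effect (LOEC/LOEL, 10 < x < 50) and Acute Effect (EC/LC50).
Codes outside this inventory (e.g. MATC) and EC/LC with x > 50 are
excluded rather than guessed — a beyond-half effect level has no place in a
minimum-based benchmark, and silently mapping unknown codes would be worse
than dropping them. Each non-empty subset yields

benchmark = min(conc) / (AF_Endpoint × AF_Species × AF_Persistence)

with AF_Endpoint = 10 (No/Low Effect) or 100 (Acute), AF_Species = 1 only
when the subset spans at least three distinct fish, three distinct
invertebrate and one plant species (else 2), and AF_Persistence = 5 for
half-lives of at least 8 weeks (else 1), never applied to the acute subset.
Two boundary decisions: a half-life of exactly 8 weeks counts as persistent
(the non-persistent class is defined as *shorter than* 8 weeks), and a
chemical lacking a half-life defaults to the conservative factor 5
(`missing_af`, overridable). Enumerating the admissible combinations gives
overall factors of exactly {10, 20, 50, 100, 200}:

```{r af}
af_combinations()
```

TQs divide the measured concentration (µg/L) by the *minimum* benchmark per
chemical, so the reported quotient is the maximum over subsets. EARs divide
the molar concentration by each included ACC and are summed per chemical
(`EAR_Chem`); assay inclusion is an input flag because the underlying assay
curation (data-quality remarks, curve inspection) is not mechanizable here.

Prioritization: a site exceeds when the *maximum* across its regular
samples is strictly greater than the threshold (EAR_Chem > 10⁻³,
TQ > 0.1); a chemical is high priority when either exceedance fraction
reaches at least 10% of the sites monitored for it. Site-level maxima
(rather than per-sample counting) keep multi-sample sites from inflating
counts; strict `>` at the threshold and `>=` at the 10% fraction follow the
rule's wording. Denominators are chemical-specific because the two
analytical method panels cover different site subsets — a panel-2 chemical
monitored at 37 sites is judged against 37.

Per-site summaries band each exceeding chemical by its site maximum into
(t, 10t], (10t, 100t] and (100t, ∞) — one order of magnitude per tier,
matching how such exceedances are usually described. The site-level "sum of
maximum EARs" takes the maximum per chemical–assay pair across samples and
sums over pairs; the per-chemical variant (maximum of EAR_Chem) is exposed
as an option (`per_chemical = TRUE`) since both summaries are defensible.

## Hydrology

Within each site, regular samples split at the median mean daily discharge
into `low` and `increased` flow (for two-sample sites, lowest vs highest);
sites lacking discharge or a second sample are excluded and named. Only
panel-1 analytes enter the concentration sums because only that panel was
run everywhere. Sums are normalized by the site mean so every site
contributes values centered on 1, and the two flow groups are compared with
a Welch two-sample t test plus the percent difference of group medians.
Site medians of the same sums are correlated (Pearson) and regressed
against the WWTP effluent fraction of streamflow.

One statistical caveat is worth stating plainly. Site-mean normalization
couples the groups: a site's normalized values sum to a constant, so its
low-flow and increased-flow values are negatively dependent, while the
Welch test assumes independent groups. For two samples per site the
variance of the group-mean difference is exactly twice what the Welch
statistic estimates, so the test is anti-conservative — simulation with
this package's generator puts its null rejection rate near 15% at a nominal
5% with two samples per site (about 9% with four). We implement the
procedure as prescribed and report it as such, but the p-value should be
read as a descriptive screen, not an exact error rate; a paired or
site-level permutation test would be the calibrated alternative.

## The synthetic-data generator

`sim_config()` / `generate_bundle()` emit a complete study bundle plus
ground truth. The defaults mirror the monitoring design the package
targets: 44 sites across five lake basins, 20% of them tier-1 (four
samples) and the rest tier-2 (two samples), 257 pharmaceutical and 9
contextual analytes split across three method panels (the universal panel
M1 with ~41% of analytes; 60% of sites also run the M2 negative-mode panel
and 40% the positive-mode panel), MRLs lognormal around a 30 ng/L median
with MDLs at 40–80% of the MRL, and two blank plus three duplicate QC
samples.

Concentrations are lognormal — environmental concentration data are
strictly positive and right-skewed — with a chemical-level scale
(median 0.8 ng/L, log-SD 2.3, calibrated once so that roughly 110 of the
257 pharmaceuticals are detected somewhere under default censoring), a
site effect of `wwtp_slope = 3` log-units per unit WWTP fraction (an
effluent-dominated stream carries ~20× the concentration of an
effluent-free one), a `low_flow_multiplier = 1.5` applied to below-median
discharge samples, and per-sample noise of 0.7 log-units. Sparse benchmark
coverage (45% ACC, 25% endpoints) leaves roughly half of detected
chemicals without any screening value, reproducing the knowledge-gap
structure that motivates the gap report.

Ground truth is planted by inverse construction. Priority chemicals are
zeroed everywhere except one detect sample at each of a chosen 25% of
their monitored sites, at a concentration that clears both thresholds by a
configurable margin (default 3×) given the ACC and benchmark targets
planted for them; non-priority chemicals get benchmark targets set from
their realized maximum concentration so they top out at 20% of each
threshold, with supporting assays at least 50× above the minimum ACC so
summed EARs cannot creep over. This makes `prioritize()`'s expected answer
exact, not probabilistic. `generate_endpoints()` inverts the benchmark
formula (round-trip relative error below 1e-9), and `generate_acc()`
plants an exact minimum ACC. Each table draws from its own substream of
the seed, so adding a table never perturbs earlier draws and a fixed seed
is bit-reproducible.

What the generator does *not* emulate: spatial correlation among sites,
seasonal structure within the sampling year, correlated co-occurrence of
chemicals from shared sources, matrix effects on detection limits, or any
fitting to real deposited monitoring data. Tests that pass on these
bundles validate the pipeline's arithmetic and decision rules, and the
statistical behavior of the planted effects — they do not certify that
real tributary data meet the generator's distributional assumptions.

## Numerical choices and problem sizes

Thresholds default to EAR 10⁻³, TQ 0.1 and a 10% site fraction, all
overridable in `run_pipeline()`. EARs and benchmarks are kept at full
double precision; only reports round. Degenerate inputs are flagged rather
than coerced: both-zero RPD pairs are NA with a warning, all-zero sites are
excluded from normalization by name, zero-variance correlation inputs
error, and a sample summed over a panel it never ran is an error rather
than a silent zero.

The simulation studies in the test suite use deliberately scaled problem
sizes, chosen as a sensible compromise between resolution and turnaround:
priority recovery runs 50 seeds of 44-site, 60-chemical bundles;
flow-test calibration runs 2000 null bundles and 500 powered bundles of 24
panel-1-only chemicals with censoring off; brute-force cross-checks use
200 fixtures of at most 10 sites × 10 chemicals × 20 endpoints or assays.
The WWTP-effect recovery check uses 100 seeds of 40-chemical bundles. The
generator's planted `wwtp_slope` acts on the log scale while the reporting
regression is linear in the site medians, so recovery is asserted on the
sign and significance of the correlation rather than on the slope's
numerical value.

## Known limitations

Beyond the Welch-test caveat above: endpoint relevance filtering (exposure
media, routes, literature verification of outliers) is consumed as an
`excluded` flag, not computed; assay curation is likewise an input;
biodegradation half-lives are inputs (a category-to-half-life lookup can
be supplied upstream, but no biodegradation model is embedded); and the
pipeline performs no mixture or additivity modeling across chemicals —
EAR_Chem sums assays within a chemical, never across chemicals.
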