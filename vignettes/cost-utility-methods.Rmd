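---
title: "Trial-based cost-utility analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-based cost-utility analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialcua)
```

trialcua implements a societal-perspective cost-utility analysis alongside a
two-arm randomized trial: a guided internet-based cognitive behavioural
therapy (ICBT) add-on versus care as usual (CAU) for rheumatoid arthritis
patients with elevated distress. The package covers the full pipeline —
utility scoring, QALY integration, costing, and bootstrap uncertainty — and
ships a calibrated synthetic cohort generator because patient-level trial
data of this kind are not publicly deposited. This vignette explains the
models, the tunable parameters, the numerical choices, and what the
synthetic data can and cannot show.

## Effects: EQ-5D-3L utilities and QALYs

Health-related quality of life is measured with the EQ-5D-3L: five
dimensions (mobility, self-care, usual activities, pain/discomfort,
anxiety/depression), three levels each, giving 243 health states. A value
set maps states to utilities anchored at 1 (full health) and 0 (death);
states worse than death are negative. Scoring is additive:

$$u = 1 - c\,[\text{any level} > 1] - \sum_d \delta_{d,\ell_d} - N_3\,[\text{any level} = 3]$$

The bundled `dutch_tariff_3l` set is the Dutch time trade-off tariff
(Lamers et al. 2006), whose worst state 33333 scores −0.329. The scoring
engine is value-set-agnostic: any YAML file with the same coefficient
fields can be supplied, and a hand-checkable `toy_linear` set is bundled
for testing. Construction-time validation enforces the two tariff
invariants (11111 scores exactly 1; the brute-force minimum over all 243
states equals the declared minimum).

Missing waves are imputed by **last observation carried forward** (LOCF):
the most recent observed utility is carried into later missing waves, never
backwards. QALYs are the **trapezium-rule** integral of the utility
trajectory, i.e. the exact integral of the piecewise-linear interpolant,
with months converted to years.

Two modelling choices here were genuinely open:

* **QALY horizon.** Measurements are at months 0 (baseline), 6
  (post-intervention) and quarterly thereafter (months 9, 12, 15, 18). The
  published analysis is "based on a 1-year follow-up period"; whether that
  year is anchored at baseline or post-intervention is not stated. We
  integrate from month 6 to month 18 — the four follow-up quarters — so the
  baseline measurement characterises patients but does not enter the QALY.
  The horizon is a configuration field (`qaly_horizon_months`).
* **Baseline adjustment.** The arms differ (non-significantly) in baseline
  utility (0.69 vs 0.74). The published analysis describes no
  regression-based baseline adjustment of QALYs, so none is performed;
  QALY differences are plain arm-mean differences.
* **Exclusion rule.** A patient observed only at baseline would, under
  LOCF, have a single pre-treatment measurement extrapolated across the
  whole year. Such patients are excluded from the QALY analysis with a
  warning rather than imputed.

## Costs: societal perspective, 2015 euros

Six per-patient components, all config-driven:

1. **Health-care use** — contact counts per TiC-P-derived category
   (rheumatologist through alternative medicine) times unit prices.
2. **Medication** — self-reported class use costed as dose units/day ×
   days covered × tariff price per unit.
3. **Travel** — counts × standard round-trip distance per category ×
   €0.19/km.
4. **Absenteeism** — friction-cost method: per merged absence episode,
   costed weeks are capped at the friction period (12 weeks) plus a
   vacancy-filling allowance (4 weeks), then multiplied by contracted
   hours/week and €34.90/h. The two cap components are separate
   configuration fields because the published wording ("an additional
   period of 4 weeks was taken into consideration") is ambiguous between a
   12- and a 16-week cap; the default combines them into a 16-week cap.
   Episodes overlapping in time are merged by contiguity *before* capping.
   No labour-elasticity correction is applied — the method is plain
   multiplication.
5. **Presenteeism** — reported hours of lost on-the-job productivity ×
   €34.90/h.
6. **Intervention** — an amortized development share
   (development cost / 5 years, spread over prevalence × 30% eligible ×
   10% reach), therapist time at the salary tier's rate, a 30-minute
   assistant session, and intake travel. Control patients cost €0.

Only the €34.90/h and €0.19/km rates are published; all other unit prices
ship as a documented example tariff of realistic Dutch magnitude and are
meant to be replaced for real analyses. Prices are never rounded
internally; whole-euro rounding happens only in the report writer.

**Recall-window stitching.** Each wave's resource-use and productivity
report is taken to cover the quarter preceding it (window lengths are not
published; this matches the quarterly schedule). Annual costs sum the four
follow-up windows (waves at months 9, 12, 15, 18). A wave missed through
dropout carries the previous quarter's amounts forward — the same LOCF rule
used for utilities, applied at the quarterly-cost level. Absence episodes
are attributed to the window containing their (merged) start.

## Incremental analysis and uncertainty

Point estimates are full-sample arm-mean differences; the incremental
cost-utility ratio is ICUR = ΔCost/ΔQALY, flagged undefined when
ΔQALY = 0. Uncertainty comes from a nonparametric bootstrap (default 1000
replications): patients are resampled with replacement *within arm*
(preserving arm sizes) with each patient's (QALY, cost) pair kept intact
(preserving the within-patient cost–effect correlation). The published
description says only "bootstrapping (1000 replications)"; stratified
paired resampling is the standard design for two-arm cost-effectiveness
data. Intervals are simple 2.5/97.5 percentile intervals with R's default
quantile definition (linear interpolation between order statistics, rank
$1 + p(n-1)$), matching the published table's percentile columns; the
bootstrap flavour behind the published intervals is not stated, and BCa is
out of scope.

The CE plane classifies replicates into quadrants (NE: more effective &
costlier; SE: dominant; NW: dominated; SW: cheaper & less effective).
Boundary draws with an exact zero — possible with LOCF-duplicated data —
go to the adjacent quadrant *worse* for the intervention (ΔCost = 0 → NE
over SE; ΔQALY = 0 → NE over NW, SW when ΔCost < 0); this is documented,
testable, and immaterial at n = 1000. The CEAC reports, for each
willingness-to-pay λ, the fraction of replicates with strictly positive net
monetary benefit λ·ΔQALY − ΔCost, rather than thresholding replicate-wise
ICURs, whose sign is ambiguous across quadrants. The Dutch appraisal
ceiling of €80,000/QALY is always included in the default grid.

The secondary analysis excludes medication costs (biologics dominate the
totals and are unrelated to the intervention): patient totals are recomputed
with the medication component removed before bootstrapping. Cost-category
exclusion can never change ΔQALY, and the secondary ΔCost equals the primary
ΔCost minus the medication difference — both are tested identities. Note
that the published secondary cost difference (€1863) does not exactly equal
the difference of the published secondary arm averages (4774 − 2846 = 1928),
presumably a rounding artefact; this package always reports the full-sample
difference.

## The synthetic cohort generator

`generate_cohort()` emulates the *statistical shape* of the trial's
economic data so every downstream stage is testable: 71 control and 62
intervention patients, waves at months 0/6/9/12/15/18, baseline utilities
with mean 0.69 (SD 0.23) and 0.74 (SD 0.19), follow-up utility means of
0.80 and 0.86 (so arm QALY means land on the published values), monotone
MCAR dropout with per-wave hazards chosen so the all-wave completer
fractions are 42% and 27%, 43% employment, heavy-tailed medication-
dominated costs calibrated near the published per-category means, and
intervention treatment durations of 9–65 (mean 26.07, SD 12.22) weeks with
weekly-or-biweekly therapist contact.

Notable mechanisms:

* **Utilities are generated as profiles, not numbers.** Downstream code
  consumes EQ-5D-3L profiles, so the generator draws latent utilities from
  a truncated normal on [tariff minimum, 1] (with a patient-level random
  effect, Gaussian-copula style, share 0.7 of the latent variance) and
  snaps each draw to the nearest achievable utility, emitting a
  representative profile for that value. Because snapping and truncation
  shift the mean (the achievable-utility grid is sparse near 1), the
  latent mean is recalibrated per arm and wave by solving
  E[snap(truncnorm)] = target in closed form (cell probabilities between
  grid midpoints) with root finding. The configured means are therefore
  recovered *exactly in expectation*; SDs are nominal dispersion
  parameters, not calibration targets.
* **Zero-inflated heavy-tailed costs.** Per category, a patient is a user
  with probability 1 − p₀; users get a lognormal annual contact rate
  (mean fixed so the configured annual euro mean is exact) thinned into
  quarterly Poisson counts. Published cost SDs exceed means, indicating
  exactly this kind of right tail. Medication use is Bernoulli per class
  at the published per-arm user fractions with doses calibrated to the
  per-class euro means.
* **Productivity.** Employed patients have Bernoulli absence episodes per
  quarter (truncated-geometric durations of at most 16 weeks, mean 3.5
  control / 6 intervention) and zero-inflated lognormal presenteeism
  hours. Parameters were set once so the implied annual euro means match
  the published category means.
* **Dropout is MCAR** (outcome-independent per-wave Bernoulli hazard),
  monotone by construction. The published analysis applies LOCF without
  modelling informativeness; informative missingness is out of scope.
* Within-patient correlation across *cost categories* is not modelled
  (independence by default); the trial publication reports nothing about
  it.

`expected_generator_means()` returns the analytic expectations implied by a
configuration (baseline utilities, completer fractions, per-category annual
euro means including the friction arithmetic), and the test suite verifies
over ≥100 replicate cohorts that the full generate→score→cost pipeline
recovers them within 3 Monte-Carlo standard errors.

**What passing tests do not show.** The generator reproduces first moments
and the broad dispersion/missingness structure, not the real joint
distribution: no informative dropout, no cost–utility correlation within
patient, no seasonal or disease-flare dynamics, and cost–category
correlations only through shared employment/arm. Pipeline correctness on
synthetic data therefore does not certify the published point estimates —
the published patient-level quantities are unrecoverable in principle —
only that the methods compute what they claim on data of the assumed shape.

## Numerical choices and degenerate inputs

* Percentile definition: quantile type 7 throughout, documented so
  degenerate examples are reproducible; constant draws give degenerate
  intervals equal to the point estimate.
* Tie rules on the CE plane as above; quadrant proportions always sum to 1.
* `qaly_trapezoid()` refuses horizons whose endpoints are not measurement
  waves and missing values inside the horizon (directing to
  `apply_locf()`); LOCF refuses all-missing trajectories.
* Baseline tables use the pooled-variance t test by default (Welch by
  flag) and chi-square without continuity correction (Yates by flag) —
  the uncorrected form reproduces the published employment comparison
  (χ² = 0.292, p = .59). Variables constant in both arms and 2×2 tables
  with a zero margin are skipped with a note rather than tested.
* All randomness is seeded: identical config + seed gives byte-identical
  cohorts, bootstrap draws and reports.

## Problem sizes used in the shipped checks

The test suite exercises: all 243 health states against an independent
coefficient-sum oracle; 1000 random trajectories against an exact
piecewise-linear integral; exhaustive bootstrap enumeration at 2–3 patients
per arm against 10⁴ replicates; all 64 cost-category exclusion subsets; and
110 replicate cohorts at the default 133-patient configuration for
calibration recovery. The acceptance script simulates 50 × 1000 draws from
normal approximations calibrated to the published incremental summaries to
reproduce the CE-plane north-east share and the CEAC values at €80,000/QALY.

## Known limitations

LOCF is a single-imputation method and the only one implemented (matching
the published analysis); multiple imputation, covariate-adjusted
cost-effectiveness regression, multi-year discounting and EQ-5D-5L are
out of scope. The example unit-price table is not an authoritative 2015
tariff. The interface is the R API plus `scripts/acceptance.R`; there is no
shell CLI.
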