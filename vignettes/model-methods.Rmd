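---
title: "Model and methods: biomarker screening for PDAC in new-onset diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: biomarker screening for PDAC in new-onset diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdacscreen)
```

## The decision problem

Pancreatic ductal adenocarcinoma (PDAC) is usually diagnosed late; resectable
disease has a median survival of 3.7 years against 0.4 years for metastatic
disease, so shifting diagnoses toward the resectable stage is the lever early
detection pulls. New-onset diabetes in people aged 50+ is a practical
screening trigger: PDAC prevalence there is ~1% (50× the general
population's 0.02%), and ~10% of the group has type 3c, pancreatogenic
diabetes (T3cD), within which PDAC concentrates (~10%). The model therefore
assumes PDAC cases are nested inside the T3cD subgroup.

`pdacscreen` evaluates three screening strategies against standard of care
(diagnosis on symptoms, stage mix 10/15/20/55 across
resectable/borderline/locally-advanced/metastatic):

* **cancer_specific** — one cancer biomarker for everyone (base Se 0.32,
  Sp 0.95: prediagnostic CA19-9-like performance);
* **t3cd** — one pancreatogenic-diabetes biomarker for everyone (base Se
  0.80, Sp 0.98);
* **combination** — the T3cD biomarker first; its positives take the cancer
  biomarker; only stage-2 positives are imaged.

Screening-detected patients enter the downstaged mix 40/25/25/10. Missed
(false-negative) patients are assumed to present symptomatically within the
same cycle and follow standard care with no additional stage penalty — this
makes the incremental QALYs a pure function of the detected fraction, which
is what the internal consistency of the base-case increments requires
(`delta_qalys` ratios across strategies equal the detected-fraction ratios
0.0032 : 0.008 : 0.00256). False positives pay the diagnostic work-up
(£2,363) and return to the healthy stream with no disutility; work-up harms
and incidental findings are out of scope.

## Survival and the cohort trace

Each stage runs a two-state (alive/dead) Markov trace over a 5-year horizon
with 1-year cycles. Survival within a stage is exponential with the stage's
median `m`, so the annual death probability is `p = 1 - 0.5^(1/m)`
(`annual_death_probability()`), giving 0.17/0.39/0.41/0.82 at the base-case
medians. There are no stage-to-stage progression transitions: the published
model supplies stage-specific death rates only, so each diagnosed patient
remains in the diagnosed stage until death. Patients alive at 5 years are
censored without a terminal reward. The model consciously uses the
transition probabilities *rounded to two decimals* by default
(`transition_digits = 2`), mirroring the published figure; the exact
conversion is available with `transition_digits = NULL` and changes results
by well under 1%.

## Accrual conventions and their calibration

Cohort models differ in bookkeeping details that a publication rarely
states. All of them are explicit dials of `accrual_convention()`:

| dial | options | default |
|---|---|---|
| `reward_timing` | start-of-cycle occupancy, end-of-cycle survivors, half-cycle average | start |
| `discount_start` | first cycle undiscounted (`cycle1`) or discounted (`cycle0`) | cycle1 |
| `cost_timing` | treatment cost lump-sum at diagnosis, or spread over occupancy and discounted | lump_sum |
| `cost_staging` | treatment costs aggregated over each arm's own stage mix (`shifted`) or over the standard-care mix for both arms (`unshifted`) | shifted |
| `transition_digits` | death-probability rounding | 2 |

The default is the simplest spreadsheet reading. Because the published
increments could not be reproduced under any combination of the first three
dials alone (incremental costs come out 11–30% high), the package calibrates
the convention (`calibrate_convention()`): phase 1 selects reward timing,
discount start and rounding by minimising the maximum relative deviation of
the three incremental-QALY values from the published ones; phase 2, holding
those, selects the cost dials against the incremental costs. The winner —
half-cycle rewards, discounting from cycle 0, spread discounted costs,
**unshifted** costing — reproduces all twelve published increments (ΔC, ΔQ,
Δlife-years, ICER × three strategies) to within 1%, the incremental costs to
within pennies (165.90 vs 165.88; 267.50 vs 267.43; 63.19 vs 63.16). It is
returned by `calibrated_convention()`.

The decisive dial is `cost_staging`. Under `shifted` costing, downstaging
moves 45% of detected patients from cheap metastatic care (£28,418) into
expensive resectable care (£47,581), adding ≈£5,900 per detected patient net
of the avoided standard work-up; the published increments instead imply
detected patients *save* ≈£1,140 each. Only treatment costing at the
standard-care stage mix — early detection changes which care pathway's unit
costs apply, but not the cost-side stage composition — reproduces that
number. We document this as the published model's evident costing behaviour
rather than endorse it as health-economic best practice; `shifted` costing
remains available and is arguably the more defensible model, at the price of
roughly 12–30% higher ICERs.

## Strategy-level accounting

Per screened person: everyone pays the biomarker unit cost (£45 per test
administered; in the sequential strategy only stage-1 positives pay for the
second test); every final cascade positive pays the biomarker-pathway
diagnostic work-up (£2,363); detected patients accrue the biomarker-pathway
treatment mixture; false negatives pay standard diagnostics (£3,087) plus
the standard treatment mixture; everyone without PDAC accrues the healthy
utility stream (0.86), which cancels exactly between arms. The single-test
strategies take PDAC prevalence directly from `pdac_incidence` (or
`pdac_incidence_general`); the T3cD-led strategies derive it as
`t3cd_incidence × pdac_incidence_in_t3cd` (0.10 × 0.10 = 0.01 at base).
These three incidences are all published inputs, so the identity is checked
with a warning rather than enforced.

ICERs are handled with dominance quadrants (`compare_outcomes()`): an
intervention that is cheaper and at least as effective is dominant, the
reverse dominated, zero-increment comparisons are "equivalent", and the ICER
is reported as `NA` whenever the QALY increment is zero. Cost-effectiveness
is always the sign of net monetary benefit at λ = £30,000/QALY.

## One-way sensitivity analysis

`one_way_dsa()` re-evaluates the ICER at each ranged parameter's bounds with
everything else at base, ranking by bar width. Two design choices matter:

* **Stage-distribution components.** Varying one starting-stage proportion
  leaves the simplex; the other three components are rescaled
  proportionally to `1 - value`. (A largest-remainder scheme is an
  integer-apportionment construct with no meaningful continuous analogue.)
* **The T3cD enrichment share is structural.** The published tornado
  listings never vary the 10% T3cD share, and with it varied it would enter
  every T3cD-led ranking near the top — the strategies are *defined* as
  screening the T3cD-enriched subgroup, so changing the share redefines the
  screened population rather than perturbing an input. The default
  parameter set for the one-way analysis therefore excludes
  `t3cd_incidence` (PDAC risk inside the subgroup still varies through
  `pdac_incidence_in_t3cd`); pass `parameters =` to vary it anyway. The PSA
  always varies it.

## Probabilistic sensitivity analysis

The published analysis states only "10,000 simulations, all parameters
varied simultaneously". Families are therefore a design choice:

* default: independent **uniform** on each published (low, high) range —
  the only family the printed ranges fully determine;
* `psa_distributions(families = "beta_gamma")`: beta for probabilities,
  utilities and proportions, gamma for costs and medians, each
  moment-matched with mean at base and SD a quarter of the range;
* `triangular` with mode at base.

Parameters are sampled independently (no correlation structure is
published); stage-distribution draws are rescaled to the simplex. Each
parameter owns a deterministic substream derived from the master seed, so a
given seed reproduces a PSA bitwise and adding a parameter to the spec does
not perturb the others' draws.

Because several ranges are strongly asymmetric around their base values
(cancer Se 0.32 on (0.30, 0.70); both specificities on (0.70, 0.99)), the
*marginal* cost-effectiveness fractions are family-sensitive, and the
package does not claim to reproduce the published percentages — under
default uniforms it finds ≈96% of cancer-specific draws not cost-effective
(published: 92.3%) and ≈16% of combination draws cost-effective (published:
26%). The qualitative findings are stable across families: the
cancer-specific strategy is not cost-effective in the large majority of
draws, the T3cD strategy almost never crosses the threshold, and the
fractions are reproducible to well within ±2 percentage points across
seeds at 10,000 draws.

`head_to_head()` compares two strategies on the *same* draws (common random
numbers) and classifies each draw by which strategy attains the lower ICER
against standard care (dominance wins outright; NMB breaks undefined-ICER
cases). This per-draw relative classification — whose two fractions
partition 100% — is what a published head-to-head split of 55.6%/44.4% must
be, and under default uniforms the package finds 56.1%/43.9% in favour of
the T3cD strategy. The marginal cost-effectiveness fractions are reported
alongside.

## The microsimulation oracle

`simulate_cohort()` realises the same model at the individual level:
Bernoulli T3cD status, Bernoulli PDAC status within T3cD, Bernoulli test
results, categorical stage assignment, and geometric per-cycle death — the
exact individual-level counterpart of the cohort's annual death
probability, not an approximation. Per-individual discounted accrual mirrors
every convention dial cycle for cycle (for half-cycle rewards an individual
alive at cycle start contributes half, plus half if still alive at cycle
end; for unshifted costing a detected individual draws an independent
costing stage from the standard-care mix together with its own costing
survival, whose expectation equals the cohort formula exactly).
`oracle_check()` z-scores every cascade count (binomial SE) and per-person
mean (empirical SE) against the deterministic engine; at the full cohort
size of 200,000 everything sits within 4 Monte Carlo standard errors, and
the mean absolute error of per-person QALYs decays as `n^(-1/2)` across
n = 10³–10⁵.

What passing these checks shows is *internal* consistency: the
closed-form engine and an independent stochastic realisation agree. The
generator emulates the statistical structure the cohort model assumes —
fixed incidences, homogeneous test performance, stage-wise exponential
survival, no background mortality, no individual heterogeneity in costs or
utilities — so agreement says nothing about how real screening cohorts
deviate from those assumptions.

## Numerical choices and problem sizes

* All expected counts are kept as exact floating-point products; rounding
  (half away from zero, matching the published tables) happens only in the
  reporting layer (`round_half_up()`).
* Discounted series use the closed geometric form
  `(1 - x^H) / (1 - x)` with the `x → 1` limit handled explicitly, which is
  what makes the 10,000-draw PSA a sub-second matrix computation.
* Stage distributions are validated to sum to 1 within 1e-9; the engine
  renormalises defensively.
* The test suite runs the full published problem sizes where they are
  cheap (200,000-person cascades and microsimulation; 10,000-draw PSA) and
  smaller cohorts (≈60,000) for the per-convention oracle sweeps; the
  root-n convergence study uses 8 replicates at each of n = 10³, 10⁴, 10⁵.

## Known limitations

* The accrual convention and the unshifted costing are *recovered by
  calibration*, not stated by the source analysis; alternative conventions
  change ICERs by up to ~30% and are available via `accrual_convention()`.
* Only direct medical costs enter; no societal perspective, no work-up
  harms, no benefit from earlier chronic-pancreatitis management in
  T3cD-positive, PDAC-negative individuals.
* The published imaging ratio of 2.4 scans per detected case for the
  sequential strategy is not recoverable from the published counts
  (1,412 / 512 = 2.76); the package reports the internally consistent
  value. Likewise 19,600 / 16,000 = 1.225 scans per T3cD case, published
  as 1.3.
* No background (non-PDAC) mortality over the 5-year horizon, and no
  stage progression before diagnosis: prevalence, stage mixes and test
  performance are single-time-point quantities.
* PSA distribution families and correlations are unpublished; marginal PSA
  percentages are family-dependent and reproduced only qualitatively.
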