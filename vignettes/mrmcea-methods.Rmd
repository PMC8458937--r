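---
title: "Methods: the screening cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the screening cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmcea)
```

## The question and the model

Extremely dense breast tissue both raises breast-cancer risk and masks
tumors on x-ray mammograms, so women in this group screened with x-ray
mammography (XM, sensitivity 41.2%) have many cancers detected late.
MR-mammography (MRM) detects almost all prevalent cancers (sensitivity
95.2%) but costs more per examination, and its specificity improves from
92% in the first screening round to 97% once prior images are available for
comparison. The package quantifies the trade-off as an incremental
cost-effectiveness ratio (ICER) over a 20-year horizon of biennial
screening from age 55, from the perspective of the U.S. healthcare system.

The model has two layers:

1. **A per-round decision tree.** Each attended round splits the screened
   population into true/false positives and negatives from the prevalence
   of undetected disease and the round-specific test accuracy
   (`round_outcome()`). False positives trigger a workup — always a biopsy
   for XM; for MRM a biopsy with the round-dependent biopsy rate and
   otherwise a follow-up examination — and a one-cycle utility decrement.
2. **An annual-cycle Markov cohort model.** Eight public health states
   (healthy; undetected tumor; detected small/large/advanced; post-simple
   and post-intensive treatment; dead) propagated for 20 one-year cycles
   (`run_strategy()`), with screening events at cycles 0, 2, ..., 18.

Both screening strategies are run on identical rate tables and parameters;
`screen_cea()` pairs them into the cost-effectiveness comparison.

## Cycle semantics and accrual

Each cycle accrues, on its start-of-cycle occupancy and at the cycle's
discount factor $(1+r)^{-t}$ with $r = 3\%$/year (cycle 0 undiscounted):

* the state utility of every occupant (QALYs; dead contributes 0),
* examination costs for the screened states (healthy + undetected),
* expected false-positive workup costs and the 0.01 utility decrement for
  disease-free screened women (false positives stay in the healthy state;
  the consequences are cycle modifiers, not a state change, since a
  false-positive finding does not alter disease natural history),
* the one-time stage-specific treatment cost for anyone spending this
  cycle in a detected state. Detected states always empty into
  post-treatment states (or death) after one cycle, so mass in a detected
  state *is* the newly detected inflow and treatment is charged exactly
  once on entry. A large tumor with a failed R0 resection (probability
  $1 - 0.90$) moves to the advanced state and accrues the advanced
  treatment cost there — a second-line treatment.

No half-cycle correction is applied: occupancy at cycle start accrues the
full year. With all risks and prices zeroed this makes the 20-cycle QALY
total exactly the annuity $\sum_{t=0}^{19} 1.03^{-t} = 15.32380$ and the
biennial XM examination stream exactly
$101.52 \sum_{k=0}^{9} 1.03^{-2k} = \$789.33$ — both pinned by unit tests
as closed-form oracles.

## Transitions

Death is a competing risk everywhere: the age-specific all-cause
probability $q(a)$ from the life table combines with a state-specific
excess $e$ as $1-(1-q)(1-e)$, an order-independent form that stays inside
$[0,1]$. The excesses are the annualised 10%-in-10-years risk while a
tumor is undetected ($e = 1 - 0.9^{1/10} \approx 0.0105$/year) and the
annual stage-specific risks 0.11% / 0.78% / 1.81% after detection, applied
during a finite post-detection window (below). Onset is
healthy → undetected at $(1-q(a))\,i(a)$ with $i$ the age-specific
incidence.

**Stage at detection follows dwell time.** The model carries undetected
dwell compartments counting missed screening rounds: a tumor detected
within one screening interval of onset (dwell 0) is small (<1 cm, treated
simply and always successfully), consistent with the input that 100% of
tumors detected within one interval are successfully treated small tumors;
a tumor that has been missed is large (>1 cm, intensive treatment,
R0 resection 90%, 40% node-positive); beyond a calibrated number of missed
rounds it is advanced. Symptomatic (interval) detections between screens
stage by the same dwell rule. Routing every interval cancer to the
advanced stage instead would contradict the 100%-small-within-one-interval
input and systematically inflate the XM arm's treatment costs; the dwell
rule is the minimal mechanism consistent with the inputs, given that no
tumor-growth rates are available.

Because dwell compartments and the post-detection excess-risk window are
not Markov on eight states, the engine expands the state space internally
(dwell compartments `U0..Uthr`; post-treatment tunnel states over years
since detection) and aggregates back to the eight public states in every
reported trajectory. `build_transition_matrix()` exposes the full internal
matrix; rows sum to 1 within 1e-10 and death is absorbing, enforced by
tests, and a brute-force enumeration of all state paths on a 3-cycle model
reproduces the engine's discounted totals to 1e-9.

## Free parameters and calibration

Three structural quantities are not derivable from the printed inputs:

* `interval_detection` — per-cycle probability that an undetected tumor
  presents symptomatically in a non-screening year;
* `advanced_dwell_threshold` — missed rounds before detection is advanced;
* `excess_risk_duration` — years after detection during which the
  stage-specific excess death risk applies (after the window, survivors
  revert to all-cause mortality only).

`fit_free_parameters()` fits them by exhaustive deterministic grid search
(no stochastic optimiser: the space is tiny and reproducibility matters),
minimising a weighted sum of squared relative errors against the published
base-case cumulative costs and QALYs of both strategies plus the ICERs at
the two ends of the later-round specificity sweep (92% and 99%) — targets
that span both specificity regimes. Ties break toward the
lexicographically smallest candidate. The shipped defaults in
`cea_parameters()` are the grid optimum on the packaged fixtures
(`interval_detection = 0.85`, threshold 3, 5-year window); the acceptance
script recomputes this calibration from scratch on every run. Parameter
recovery from noise-free synthetic targets is exact for every grid point,
by test. The fitted interval-detection probability is high — in this
structure it absorbs every unmodelled route to earlier diagnosis
(clinical presentation, incidental imaging, short-interval follow-up), so
it should be read as an effective rate, not a literal symptom-onset rate.

A deliberate consequence of applying the full life-table background
mortality: absolute QALY totals sit about 5% below the published
cumulative effects (which lie close to the mortality-free annuity 15.324),
while costs, incremental quantities, ICERs and break-even costs match
closely. The calibration therefore weighs the QALY targets as printed but
cannot — and does not silently try to — close that structural gap;
the residuals are reported per target.

## Sensitivity analyses

**Tornado (`one_way_tornado()`).** Each parameter in turn to the ends of
its range, both strategies re-run, ICERs recorded, entries sorted by span.
Default ranges: costs ±25%; the two MRM specificities over their published
round-1/round-2 bounds (92–97%); XM specificity ±2.5 percentage points
(the scale of the uncertainty reported for screening mammography — a 10%
relative drop to 81% would double the false-positive rate, outside
anything observed); remaining probabilities ±10% relative, truncated to
[0, 1]. All ranges are overridable. Signed ratios are reported (negative
values indicate a dominance quadrant) so that spans remain well-defined.

**Two-way (`two_way_cost_specificity()`)** varies the MRM examination cost
against the later-round specificity; its base-cost row is the published
specificity sweep and is strictly decreasing in specificity.

**Break-even (`break_even_mrm_cost()`)** bisects the MRM examination cost
to $0.01 for zero incremental cost — "equal costs of both strategies",
not ICER = WTP — and errors with diagnostic bounds if the bracket does not
contain a sign change.

**Probabilistic (`probabilistic_sa()`, `simulate()`).** The published
analysis does not state its Monte Carlo distributions. The package's
defaults are standard practice: beta for probabilities and utilities,
moment-matched to the base value with coefficient of variation 0.1, and
gamma for costs with CV 0.2, all configurable per parameter. Values at the
boundary of their domain (utility 1, probability 0 or 1, cost 0) admit no
such beta/gamma and are held fixed, as are the three calibrated structural
parameters. Moment matching is applied literally even where it implies
J-shaped beta densities (means near 1 with CV 0.1); these are faithful to
the stated mean/CV, at the price of occasional extreme draws. 30,000
iterations run in under a second because the engine is re-expressed as
vectorised arithmetic across draws (`.run_strategy_batch()`), pinned to
the matrix engine by unit tests at 1e-9. The CEAC reports, at each
willingness-to-pay, the fraction of iterations with positive incremental
net monetary benefit; at WTP 0 this equals the fraction in which MRM is
cheaper, an identity the tests assert exactly. Under these default
distributions the PSA reproduces the published acceptability
qualitatively: roughly four fifths of iterations cost-effective at
$100,000/QALY and roughly two fifths with MRM cheaper (the README shows an
actual run); the exact published percentages depend on the original,
unstated distribution choices.

## Rate tables and the synthetic generator

The packaged fixtures cover ages 55–75: age-specific breast-cancer
incidence (SEER-style magnitudes, interpolated to single years) and
all-cause female mortality (period-life-table style, strictly increasing
in age). Both are synthetic emulations — approximate transcriptions of the
public reference tables' magnitudes, not verbatim copies; their CSV
headers say so. Lookups outside a table's coverage raise rather than
extrapolate, so coverage bugs cannot pass silently.

`generate_rate_tables()` produces structurally valid synthetic pairs for
property tests: linear-in-age incidence and exponential-in-age (Gompertz-
like) mortality with optional multiplicative log-normal noise, clipped to
[0, 1] and deterministic given a seed. The generator emulates the *shape*
constraints real tables satisfy (levels, monotone mortality); it does not
emulate cohort effects, period shocks, or registry sampling noise, so
model properties verified on generated tables are structural (mass
conservation, monotonicity), not epidemiological.

## Numerical choices

* Conservation tolerances: occupancy rows 1e-10; decision-tree fractions
  1e-12; path-enumeration oracle 1e-9.
* Cumulative-to-annual risk conversion uses constant-probability
  compounding, exactly invertible to 1e-12.
* Discounting at cycle start, cycle 0 undiscounted, enabling closed-form
  annuity checks.
* Bisection bracket $[0, 2000]$ and tolerance $0.01 for break-even costs.
* Grid-search tie-break: lexicographically smallest candidate; enumeration
  order cannot change the result.
* Config files serialise doubles with 17 significant digits so parameter
  sets round-trip bit-identically.
* Problem sizes: 20-cycle horizon throughout; calibration grid 20 × 2 × 5;
  PSA 30,000 iterations; the brute-force oracle uses a 3-cycle model with
  a reduced state space.

## Known limitations

* A cohort model: no individual-level heterogeneity or microsimulation.
* No tumor-growth model; dwell-time staging is a surrogate, and the
  interval-detection probability is an effective, calibrated rate.
* No recurrence after treatment beyond the finite excess-mortality window;
  no DCIS/invasive distinction; no second primaries after treatment.
* 100% screening attendance; no recall tiers beyond the biopsy/follow-up
  split; no radiologist variability.
* Undetected tumors carry the full healthy utility (the utility inputs
  are defined by *detected* disease); treating occult disease as
  asymptomatic is an assumption worth varying in sensitivity analyses.
* Screening stops after cycle 18; women in detected or post-treatment
  states are not screened.
* Single currency and price year; no differential discounting.
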