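---
title: "Modelling dietary salt reduction and cardiovascular disease in India"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dietary salt reduction and cardiovascular disease in India}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltcvd)
```

## The model

`saltcvd` implements an open-cohort Markov (state-transition) model of
myocardial infarction (MI) and stroke among Indian adults aged 40–69, built to
ask whether population-wide reductions in dietary salt intake would avert
cardiovascular events — and whether they would do so outside urban
populations, or at the cost of new iodine deficiency.

The population is split into twelve cohorts (gender × ten-year age band ×
urban/rural). In each monthly cycle a person occupies one of seven states:
*well* (no cardiovascular history), *acute MI*, *acute stroke*, *post-MI*,
*post-stroke*, *cardiovascular death* and *other death*. From *well*, first
MI, first stroke and other-cause death compete; from the post-event states,
recurrence competes with other-cause death. Acute states last exactly one
month and resolve to death (with the cohort's case fatality) or the
corresponding post-event state. Annual rates convert to monthly probabilities
as `p = 1 − exp(−rate/12)`, and simultaneous causes are allocated with the
standard competing-risks split (total cycle probability shared in proportion
to cause-specific rates), so per-cycle probabilities can never exceed one.

Three demographic mechanisms make the cohort *open*:

* secular trends: each rate is multiplied by `trend^(years since 1998)`,
  stepped at calendar-year boundaries;
* aging: each month a fraction 1/120 of every living state moves up one age
  band (memoryless ten-year bands), with 60–69 occupants aging out of the
  model (tracked, so persons are conserved exactly);
* entrants: census-style annual counts of people turning 40 enter the *well*
  state of the 40–49 cohorts, spread uniformly over the year.

The engine is an expected-value cohort simulation with real-valued counts:
central estimates are deterministic, and parameter uncertainty is handled
separately by the PSA module. An individual-level stochastic microsimulation
exists only in the test suite, as an independent oracle for the engine's
expectations.

## The exposure chain

Salt scenarios are linear ramps: the main scenario reduces intake by
3 g/day reached over 30 years (0.1 g/year from 2013 through 2043, the pace
achieved historically in Finland); 1 g and 4 g variants ramp over the same
period. The effect of a scenario reaches event rates in two stages.

**Salt → blood pressure.** A 3 g/day reduction lowers systolic blood pressure
by 3.6 mmHg (95% CI 2.8–4.4) in hypertensive and 1.8 mmHg (95% CI 1.0–2.6) in
normotensive persons, linearly in the reduction. Each cohort's mean reduction
is the prevalence-weighted mixture of the two; the cohort blood-pressure
distribution is represented by exactly this binary split because that is all
the underlying meta-analysis distinguishes. An alternative *age-dependent*
dose-response (used in a sensitivity analysis) sets the reduction to
`0.0598 × (mmol salt) + 0.0431 × max(age − 48, 0)` mmHg with 17.1 mmol per
gram of salt; we clamp the age term at zero below 48 to avoid sign reversal
and gate the whole effect to zero at zero exposure so a null intervention
confers no benefit.

**Blood pressure → relative risk.** Risk is log-linear in the reduction:
`RR = exp(−slope × ΔSBP)` applied equally to first and recurrent events. The
exact endpoint- and age-specific slopes used in the original analysis are not
published; the package default is ln(2)/20 per mmHg (risk halves per 20 mmHg)
attenuated by 20% per decade of age band — a documented, overridable
approximation, which is why aggregate *totals* are matched by calibration
rather than asserted from rate defaults.

**Lagged phase-in.** Benefit is not instantaneous: stroke risk reduction
phases in linearly over 3 years; for MI two-thirds arrives linearly over
3 years and the remainder over the following 7. Because the ramp changes
exposure continuously, the engine convolves the monthly *increments* of each
cohort's achieved ΔSBP with the lag kernel (FFT convolution). Convolving
increments — rather than applying the kernel to RR — keeps the operation
linear and order-independent; applying it to RR differs only at second order
but is not additive across increments, so it was rejected.

## Synthetic inputs and calibration

The stratified rate tables behind the original analysis exist only in
unpublished supplementary material, so the package generates synthetic inputs
with the same schema and statistical structure: first-event rates rising
strictly with age and highest among urban men for MI, recurrent rates a
multiple of first-event rates, case fatalities rising with age, competing
background mortality, rising MI/stroke trends against declining background
mortality, hypertension prevalence in the 10–40% range (urban > rural, rising
with age), and provincial iodization strata including one low-content
province. Defaults are order-of-magnitude plausible for India's 40–69
population (about 170 million initially, ~7.5 million entrants/year);
`calibrate_to_totals()` is the supported route to published aggregate
magnitudes: iterative proportional fitting of the event rates (and case
fatalities for a deaths target) until a baseline run reproduces the stated
annual totals within 1%.

What passing tests on these inputs do show: the engine's bookkeeping
(conservation, competing risks, aging), the exposure chain's algebra, and the
qualitative results (monotone and near-linear dose response, benefit in every
cohort). What they do not show: agreement with India's true stratified rates,
urban–rural contrasts beyond the generator's assumptions, or migration
effects (not modelled; the original analysis inferred them from census
projections).

## Worked magnitudes

```{r calibrated, eval = FALSE}
bundle <- generate_inputs(seed = 11)
bundle <- calibrate_to_totals(bundle,
                              list(mi = 8.3e6, stroke = 8.3e5, deaths = 2.0e6))
base <- run_model(bundle)
main <- run_model(bundle, scenario_preset("3g30y"))
averted(base, main)
```

On this calibrated bundle the 3 g scenario averts roughly 250,000 MIs,
22,000 strokes and 57,000 cardiovascular deaths per year over 2013–2042
(about 3% of each baseline total), with averted events split roughly 55/45
between rural and urban cohorts and roughly two-thirds among men. These are
properties of the synthetic inputs under the package defaults, not estimates
for India; they are recomputed, not quoted, by the test suite.

## Iodine side-model

Iodine intake per stratum is `salt × coverage × content` µg/day against a
150 µg/day requirement. Within-stratum salt intake is a normal distribution
truncated at zero, discretized on an equal-probability grid (default 2001
points) so threshold crossings are counted exactly. The *pessimistic* mode —
the configurable stand-in for the original worst case, whose exact
assumptions are unpublished — takes the entire reduction from iodized salt,
applies the upper requirement bound (default 250 µg/day), and allows no
compensatory iodization. Strata with zero iodization coverage contribute zero
excess cases under any mode: deficiency there reflects lack of access to
iodized salt, which reducing intake does not change.

A caveat on magnitudes: under the multiplicative intake model with a
truncated-normal spread, a 3 g reduction sweeps a salt-intake window that
always carries appreciable probability mass, so *absolute* excess counts on
synthetic defaults are large fractions of the population. Real intake data
are far more concentrated away from the requirement threshold (which is why
published worst-case counts are tiny and confined to low-iodization
provinces); treat the module's absolute counts as structural outputs of the
synthetic inputs, and its null/headroom/zero-coverage/monotonicity behaviour
as the validated content.

## Uncertainty and sensitivity analyses

The PSA redraws, per simulation: the two dose-response coefficients
(zero-truncated normals with SD = CI width/3.92), lognormal multipliers
(median 1, default log-SD 0.1) on the RR slopes, and lognormal multipliers on
the rate tables — the main-text sources do not specify these distributions,
so they are package defaults, all overridable. Draws are counter-based on
`(seed, draw index)`, so results are reproducible regardless of execution
order. Summaries report both mean ± 2 SD and percentile intervals, since
both conventions appear in practice. With all SDs at zero the PSA reproduces
the deterministic run bit-for-bit (multiplication by exactly 1.0 is exact in
floating point).

Two named sensitivity scenarios are built in:

* `lower_rr_benefit` — lowering an elevated blood pressure confers only
  two-thirds of the benefit of having natively maintained it. We apply the
  2/3 factor to the *hypertensive* dose-response coefficient (3.6 → 2.4 mmHg
  per 3 g) rather than to the log-RR of everyone: normotensive persons'
  pressure already is at its native level, so the adjustment has nothing to
  discount for them. Under this reading the population benefit falls by about
  12–16% at realistic hypertension prevalences — the magnitude reported for
  this sensitivity analysis — whereas a uniform 2/3 scaling of log-RR would
  cut benefit by a third, which matches no reported result.
* `age_dependent_sbp` — switches the cohort ΔSBP to the age-dependent
  dose-response above.

## Numerical choices and limitations

* Monthly cycles over 1998–2050 (636 steps); the 1998 burn-in lets trends act
  before the 2013 intervention. Analysis windows are half-open year ranges
  (`[2013, 2043)` = 30 years).
* Rates are stored annual; conversion to monthly probabilities happens in one
  place, inside the engine.
* Acute-state occupants face only case fatality during their acute month (no
  background mortality); survivors join the post-event state the next cycle.
* Cross-morbidity transitions (post-MI → first stroke and conversely) are off
  by default — the original state diagram does not fully specify them — and
  can be enabled with `model_params(cross_morbidity = TRUE)`, which uses
  first-event rates; event history is then tracked by the most recent event.
* Zero-rate states receive zero transition probability exactly (no 0/0).
* FFT round-off in the lag convolution is clamped at zero so a null scenario
  yields relative risks of exactly 1 and a bit-identical baseline.
* Calibration caps case fatalities at 0.95 and errors with residuals if
  targets are infeasible for the population size.
* Test problem sizes (small populations via `population_scale`, 200-replicate
  microsimulation over 12 months, 500-draw PSA reproducibility) were chosen
  as the smallest sizes at which the statistical comparisons are meaningful.
* Not modelled, by scope: ages outside 40–69, renal disease and gastric
  cancer endpoints, non-blood-pressure-mediated salt effects, non-linear
  salt–pressure relationships, explicit migration, and cost-effectiveness.
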