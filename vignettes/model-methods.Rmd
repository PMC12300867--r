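---
title: "Methods: a Markov cohort model of yogurt intake and type 2 diabetes in Japan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model of yogurt intake and type 2 diabetes in Japan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietmarkov)
```

## The model

`dietmarkov` projects the 10-year health and economic consequences of
raising mean yogurt intake in the Japanese population aged 40–79 years. The
population is partitioned into 8 closed strata (2 sexes × 4 ten-year age
bands); each stratum is traced independently through a four-state Markov
model with annual cycles:

* **Healthy** — never diagnosed with T2D;
* **Chronic T2D** — diagnosed; no remission is modelled;
* **Death from T2D** and **Death from other causes** — absorbing.

The trace is a deterministic expected-value computation with fractional
persons: occupancy at cycle $t+1$ is occupancy at cycle $t$ times the
stratum's transition matrix, with all transitions evaluated simultaneously
from start-of-cycle occupancy and no half-cycle correction. Per-cycle flows
(new diagnoses, T2D deaths) are recorded from start-of-cycle occupancy, so
a newly diagnosed person cannot die of T2D within the diagnosis year.
Persons are conserved exactly: every occupancy row sums to the stratum
population.

Key simplifications, inherited from the closed-cohort design: nobody enters
the population, nobody ages across bands, and all rates are constant over
the horizon. The model is therefore a short-horizon projection, not a
demographic forecast.

## Transition probabilities

For a stratum with published annual rates per 100,000 population —
incidence $I$, prevalence $P$, T2D mortality $m_{\mathrm{T2D}}$ and
all-cause mortality $m_{\mathrm{all}}$ — the annual probabilities are

$$
p(\mathrm{H}\to\mathrm{C}) \;=\; \frac{I}{100{,}000 - P}\;
  \mathrm{RR}^{\,x/g},
\qquad
p(\cdot\to\mathrm{death\ other}) \;=\; \frac{m_{\mathrm{all}} -
  m_{\mathrm{T2D}}}{100{,}000},
\qquad
p(\mathrm{C}\to\mathrm{death\ T2D}) \;=\; \frac{m_{\mathrm{T2D}}}{100{,}000}.
$$

Three calibration choices deserve comment, because each was genuinely open
and each is visible in the projected counts:

1. **At-risk denominator for incidence.** Burden-of-disease incidence rates
   are published per 100,000 total population, while the transition applies
   to the healthy (never-diagnosed) pool. Dividing by $100{,}000 - P$
   converts the rate to the at-risk denominator. Without this conversion
   the projected caseload is biased low by the prevalence share (2–15%
   depending on stratum), and the projections no longer reproduce the
   published per-stratum counts our acceptance tests check.

2. **Zero-intake reference for the dose–response factor.** The relative
   risk $\mathrm{RR}$ (0.93 per $g = 50$ g/day, 95% CI 0.89–0.97) enters as
   $\mathrm{RR}^{x/g}$ with $x$ the scenario's achieved mean intake — the
   2019 mean under baseline, $\max(\text{mean}, \text{target})$ under an
   intervention. Every arm, baseline included, is attenuated relative to a
   hypothetical zero-intake cohort. Epidemiologically one would expect the
   published incidence already to reflect current intake (multiplier 1 at
   baseline); the package exposes that convention too
   (`scenario_rr_table(reference = "baseline")`). The engine uses the
   zero-intake reference because it is the calibration that reproduces the
   published absolute projections; the reference cancels exactly in every
   baseline-versus-scenario difference and percentage, so intervention
   effects are identical under either convention.

3. **Rates used directly as probabilities.** No $1-e^{-r}$
   rate-to-probability conversion is applied. At these magnitudes (annual
   probabilities below 0.03) the difference is under 0.2%, and the direct
   reading is the one consistent with the published projections.

T2D mortality is applied to the chronic pool even though burden-of-disease
mortality rates are population-denominated; this is the reading that
matches the published death counts, and we implement it without endorsing
it epidemiologically. Death from other causes strikes both living states at
the same rate, obtained by subtracting T2D mortality from all-cause
mortality (their ordering is validated on input).

## Scenarios and the dose–response model

A scenario is a target mean daily intake applied immediately and maintained
for the whole horizon; strata already above the target are unchanged
(`intake_delta()` floors at zero), and intake decreases are outside the
modelled domain (`rr_for_intake_change()` rejects negative changes — a
protective RR extrapolated to a decrease would imply harm the source
meta-analysis does not quantify). The extrapolation is log-linear:
$\mathrm{RR}(\delta) = \mathrm{RR}^{\delta/g}$, multiplicative in $\delta$
to machine precision, which is the standard reading of a "per 50 g/day"
dose–response estimate. The full effect applies from the first cycle
("immediate increase"); no uptake lag or adherence decay is modelled. The
same mean shift applies to the whole stratum: real intake is highly skewed
(the population median is zero), but only stratum means are available.

## Costs

The only costs modelled are outpatient care (including dispensing) for
diabetes. Each stratum's annual expenditure (2019 USD) divided by its 2019
prevalent count gives a per-patient annual cost (`per_patient_annual_cost()`,
roughly USD 600–940 across strata). Cycle $t \in \{0,\dots,H-1\}$ accrues

$$\mathrm{cost}_t = C_{t+1} \cdot c \cdot (1+r)^{-t},$$

with $C_{t+1}$ the end-of-cycle chronic occupancy, $c$ the unit cost and
$r = 0.02$/year: the people in the chronic state at the end of a model year
carry that year's outpatient cost (so a newly diagnosed patient incurs
costs from the diagnosis year), and the first year is undiscounted. The
accrual timing of the original TreeAge implementation is not documented;
we chose end-of-cycle occupancy with the discount exponent starting at 0
because it reproduces the published expenditure projections to within
0.01%, and kept a `timing = "start"` switch for the conventional
start-of-cycle accrual (which differs by about 2% here). A one-time
transition cost per incident case was rejected: calibrating it to the 2019
expenditure cannot reproduce the published cumulative totals, which behave
as person-year accrual on the prevalent pool.

## Sensitivity analysis

`one_way()` moves one parameter to its lower and then upper uncertainty
bound — 95% CI bounds for the four stratified rates and the relative risk,
0% and 4% for the discount rate — in **all** strata and **both** arms
simultaneously, holding everything else at point values, and reports the
resulting savings per sex and overall. Perturbing the prevalence
consistently re-derives the initial state split, the at-risk denominator
and the per-patient unit cost from the perturbed prevalent count. Columns
are labelled by parameter bound (`savings_at_lower`/`savings_at_upper`)
*and* by output order (`savings_low`/`savings_high`), because the two
orderings invert for protective parameters: the lower RR bound (stronger
protection) yields the higher savings. `tornado()` stacks all six
parameters and sorts by the induced range width, ties broken alphabetically
so collapsed CIs give a stable order. No probabilistic sensitivity analysis
is provided; the source analysis is deterministic one-way only.

## Synthetic data and the microsimulation oracle

`sample_parameter_set()` generates random parameter sets with the same
statistical structure as the Japan-2019 tables: rates within
fixture-spanning ranges, log-symmetric CI bounds
($\text{point}\cdot e^{\mp f}$), all-cause mortality sampled above
$m_{\mathrm{T2D}} e^{2f}$ so that even CI-bound perturbations keep every
transition probability non-negative, and costs drawn through a positive
per-patient annual cost. One RNG stream per stratum (derived from the
single seed) keeps existing strata stable when `n_strata` grows. The
generator emulates the *table structure*, not the epidemiology: rates are
drawn independently across strata, so it contains none of the real
age-gradient correlation, and it makes no attempt to model the skewed
individual intake distribution. Tests passing on synthetic sets therefore
establish the engine's arithmetic and invariants, not the realism of any
particular projection.

`microsim_oracle()` is the stochastic ground truth for the deterministic
trace: it simulates individual state paths through the same transition
matrix by per-cycle multinomial draws and scales counts to the stratum
population. Because each individual's cycle-$t$ state is an independent
draw from the same chain, scaled counts are exactly binomial around the
deterministic occupancy; agreement within Monte Carlo error at
$n = 10{,}000$ is asserted in the test suite. Two caveats are handled
explicitly in the tests: the standard error is evaluated at the
deterministic (null) probability with a one-individual floor, because the
normal approximation is meaningless for near-Poisson cells with expected
counts below one; and across many strata the per-cell 3-SE exceedance
*rate* is asserted against its binomial envelope rather than demanding a
universal bound that chance alone would break.

## Numerical and degenerate-input behaviour

* Probabilities are validated at matrix-build time; a negative remainder
  (e.g. T2D mortality above all-cause mortality, or incidence so high the
  healthy row exceeds 1) is an error naming the stratum, not a silent
  clamp.
* Horizon 0 returns the initial split with zero flows; zero prevalence
  puts everyone in Healthy (and makes the per-patient cost undefined — an
  error, not infinity); zero rates give the identity matrix and a constant
  trace.
* Aggregates are exact sums over strata; percentages are computed from
  unrounded values and rounded only for display.
* Everything is double-precision linear algebra on 4-vectors; there are no
  tolerances or iterative solvers anywhere in the engine.

## Problem sizes

The shipped tests trace 8-stratum parameter sets over 10 cycles (a few
hundred 4×4 products), run the microsimulation oracle at $n = 10{,}000$
individuals for about two dozen strata, and sweep 100 synthetic seeds for
the generator invariants; the full suite and the reproduction script each
complete in well under a minute on a single CPU.

## Known limitations

The model inherits every exclusion of its source analysis: no T2D
complications, no inpatient or dialysis costs, no yogurt purchase cost, no
QALYs or ICERs, no population change over the horizon, and intake measured
as fermented-milk-and-probiotic-beverage consumption because yogurt-only
intake is not published for Japan. Projections are specific to the 2019
Japanese parameter tables; the dose–response estimate comes from an
international meta-analysis, and it is the dominant uncertainty in the
tornado analysis.
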