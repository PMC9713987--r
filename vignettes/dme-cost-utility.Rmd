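---
title: "A Markov cohort cost-utility model for intravitreal DME treatments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model for intravitreal DME treatments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmecea)
```

## The decision problem

Diabetic macular edema (DME) is a leading cause of vision loss in working-age
and older diabetic populations. Two first-line intravitreal options — an
anti-VEGF agent (aflibercept, roughly ten injections per year under a PRN
regimen) and a delayed-release dexamethasone implant (roughly three per
year) — differ sharply in drug acquisition cost, monitoring intensity,
adverse-event profile, and visual-acuity (VA) outcomes. `dmecea` implements a
cohort state-transition model to compare their lifetime costs and
quality-adjusted life years (QALYs) from a societal perspective, in 2020
euros.

## Model structure

The health states are five Snellen bands of VA in the *better-seeing eye*,
ordered best to worst (`>20/40` down to `<=20/400`), plus an absorbing death
state. Within a 3-month cycle a patient can improve one band, stay, or
worsen one or two bands; death can occur from any state. The cohort starts
at age 68.1 distributed over the five bands, and the model runs until the
cohort is fully absorbed (lifetime horizon) or a fixed number of years.

Per-cycle dynamics factor into two pieces:

1. **Treatment-specific VA transitions.** A 5×5 row-stochastic matrix per
   arm, transcribed per 3-month cycle. One-year trial probabilities are
   converted with the constant-rate transformation
   \(p_t = 1 - e^{-rt} = 1 - (1-p_1)^{t}\); four quarter-cycles compose back
   to the annual probability exactly, which the tests assert to `1e-12`.
2. **Background mortality.** An annual life table \(q_x\) is converted to a
   cycle probability at `floor(age)` and *embedded mortality-first*: each VA
   row is scaled by the cycle survival and the death probability placed in
   the death column. The competing-risk ordering is not dictated by the
   source material; mortality-first is the standard cohort convention and
   preserves row-stochasticity by construction. Mortality is identical
   across arms and across VA states.

Costs and QALYs accrue at each cycle start from the occupancy at that time,
discounted at \((1+d)^{-kt}\) with \(d = 3.5\%\)/year applied to both. The
death state accrues nothing. A half-cycle correction (trapezoid averaging of
adjacent occupancies) is available but **off by default**: the source
analysis was built in a tool whose common usage omits it, and the tests
exercise both settings. Incremental results are summarised as
\(\mathrm{ICER} = \Delta C / \Delta Q\) (euro/QALY), suppressed in favour of
a dominance label when the signs of the increments disagree in the
conventional way; the signed ratio is always carried alongside for scenario
tables.

## Parameters

All published inputs ship in `inst/extdata/dme_parameters.yaml` and are
audited field by field against a checked-in manifest. The key tunables:

| Parameter | Default | Units | Notes |
|---|---|---|---|
| cycle length | 0.25 | years | 1-year cycles available; off-diagonal probabilities re-aggregated by the rate transformation |
| discount rate | 0.035 | /year | applied at cycle start times |
| starting age | 68.1 | years | cohort mean age |
| horizon | lifetime | — | or fixed N years |
| utility method | TTO | — | standard gamble carried alongside |
| extrapolation | continuous | — | see below |
| injections/year | 9.8 / 3.1 | — | aflibercept / dexamethasone |

Utilities by VA state come from a published DME cohort under two elicitation
methods (time trade-off and standard gamble); death is exactly 0. The
standard-gamble upper range of the worst state is 1.11 as printed, but
probabilistic draws are clipped at 1 — utilities above perfect health have
no meaning in QALY arithmetic.

Two published annual figures (771 and 1577 euros) describe DME-comorbidity
medical costs and non-medical costs. The sentence introducing them is
ambiguous about whether they are per cost *category* or per *arm*. The
package defaults to the **category** reading — the sum applied to both arms —
because the figures follow a paragraph enumerating exactly those two
categories and the same source states the costs did not differ significantly
across VA levels. The per-arm reading is available via
`shared_costs.other_cost_interpretation = "arm"`, and both figures are also
stored per arm so either interpretation is reproducible. Under the category
reading these costs cancel in the increments (mortality is identical across
arms); under the per-arm reading they add 806 euros/year to the implant arm.

Adverse events (endophthalmitis, lens damage, retinal detachment) enter as
*expected annual costs* (rate × unit cost), not as transitions: the source
prices them but gives no transition structure for them.

### Inputs that were never published

Two required inputs are not printed anywhere and ship as clearly labelled
synthetic stand-ins, swappable by the user:

* **Starting VA distribution** — a placeholder `(0.25, 0.35, 0.25, 0.10,
  0.05)`, weighted to the middle bands as is typical at presentation of
  clinically significant DME. Every load emits a provenance note.
* **Life table** — a Gompertz–Makeham schedule
  \(q_x = 1 - \exp\{-(c + \tfrac{a}{b}(e^{b(x+1)} - e^{bx}))\}\) with
  \(a = 1.05\times10^{-5}\), \(b = 0.105\), \(c = 5\times10^{-4}\), chosen
  once so that remaining life expectancy at 68 is ≈ 17 years, the order of
  magnitude of southern-European national tables, with \(q = 1\) forced at
  age 100. `read_life_table()` accepts any national table as a two-column
  CSV.

## Extrapolation beyond the first treatment year

Trial efficacy covers one year; three approaches project it over a lifetime:

* **Continuous treatment effect** (reference case): each arm's matrix and
  full treatment costs persist for the whole horizon.
* **One-time benefit**: both treatments stop after one year. Both arms then
  follow a single *natural decline* matrix and treatment-specific costs
  stop, while comorbidity, rehabilitation, equipment and (if enabled)
  indirect costs continue. The common matrix is not published; the default
  zeroes the improvement entries of the *reference arm's* matrix and moves
  the freed mass to the diagonal, and is overridable.
* **Rebound (catch-up)**: as one-time benefit, but the better-responding
  arm's decline probabilities are multiplied by a factor (default 2.0) until
  its conditional-on-alive VA mix matches the reference arm's within a
  total-variation distance of 0.01, after which it follows the common
  decline. No functional form is published for this erosion; a single
  multiplier with a distributional stopping rule is the simplest
  parameterisation with the right qualitative behaviour. The stopping rule
  also triggers if the accelerated arm is about to overshoot past the
  reference trajectory (discrete cycles can step across the tolerance band),
  which guarantees the catch-up arm's QALY gain stays between zero and the
  one-time-benefit gain.

## Probabilistic sensitivity analysis

Each Monte Carlo draw samples a full parameter set:

* transition rows: independent betas on the off-diagonal entries
  (method-of-moments from mean and SD), diagonal as the complement, with a
  logged renormalisation fallback if the complement goes negative. The
  published 20% variation coefficient is stated for unit costs; mirroring it
  for transition probabilities is this package's documented default
  (`cv_transitions`).
* utilities of the active method: betas with SD taken as (range)/4 — the
  printed ranges read naturally as ±2 SD intervals — clipped at 1.
* unit costs, drug prices, adverse-event costs, comorbidity and non-medical
  annual costs: gammas at their reported coefficients of variation.
* resource use: uniform over the reported low–high ranges.
* fixed: adverse-event *rates* and injection counts, which the source
  examines deterministically, and background mortality.

Per-draw seeds are derived from the master seed up front, so results are
bit-identical regardless of execution order. Outputs are the incremental
scatter with plane-quadrant fractions (boundary points are assigned against
the intervention), the per-arm absolute scatter, and the cost-effectiveness
acceptability curve: at willingness-to-pay \(\lambda\), the fraction of
draws with \(\lambda\,\Delta Q - \Delta C > 0\), ties counted for the
reference arm. The default \(\lambda\) grid is 0–100,000 euro/QALY in steps
of 500, covering the 30,000 euro/QALY threshold conventionally cited in
Spain. Every run asserts internally that the CEAC equals its quadrant-wise
decomposition.

## Validation strategy

* **Microsimulation oracle.** An individual-level simulator consumes the
  *same* cycle-matrix sequence, cost rates and discount factors as the
  cohort engine, so the cohort trace is its exact expectation. Tests require
  agreement of mean cost and QALYs within 3 standard errors at
  n = 100,000, and empirical state frequencies to match cohort occupancies
  within 3 binomial SEs at spot-checked cycles. (This oracle deliberately
  shares the matrix-construction path: it validates the trace arithmetic —
  accumulation, discounting, absorption — while the matrices themselves are
  validated against the printed tables separately.) This test caught a
  genuine double-transition bug during development.
* **Closed forms.** Degenerate single-state cohorts reproduce \(u \cdot T\)
  exactly; with constant mortality and discounting, engine life-years match
  the continuous annuity \(\int e^{-(\mu+\delta)s}\,ds\) within 1% at
  quarterly cycles and converge as the cycle shrinks.
* **Synthetic models.** `make_synthetic_model()` generates random valid
  parameter sets with the same banded sparsity and a `decline_gap` knob;
  conservation, death monotonicity, and the monotone effect of the gap on
  \(\Delta Q\) are property-tested across seeds. The generator emulates the
  *structure* of real inputs (band pattern, monotone utilities, positive
  costs) but not their empirical correlations — passing these tests
  demonstrates engine correctness, not clinical realism.

Problem sizes used by the shipped tests and acceptance script: 10,000 PSA
draws, 100,000 simulated patients, 129 quarterly cycles for the lifetime
reference case.

## What the transcribed inputs imply — and a reproducibility caveat

With the published unit costs, the implant arm's annual cost (drug
750.92 × 3.1 plus lighter monitoring) is several thousand euros *below* the
aflibercept arm's (588.8 × 9.8 plus heavier monitoring), while its
transition matrix is the more favourable one and mortality is identical in
both arms. Run on these inputs, the reference-case comparison is therefore
*dominance* — the implant strategy is simultaneously cheaper and more
effective — rather than a positive ICER, and the acceptance script reports
the computed increments and the signed ratio \(\Delta C/\Delta Q\)
accordingly. The published headline results (a positive incremental cost
with an ICER just under 30,000 euro/QALY) cannot be reproduced from the
printed inputs alone; indeed the printed per-arm QALY totals are not
jointly attainable with the printed utility range (0.59–0.85) under any
life table, since a QALY gain of 2.667 requires more discounted life-years
than the lower per-arm total permits. The package faithfully models the
printed inputs and leaves the corresponding direction checks in
`test-acceptance.R` red rather than adjusting any input toward the published
numbers; the scenario *magnitudes* (short horizons and fewer injections
shrink the cost-per-QALY magnitude, one-time benefit and rebound shrink the
QALY gain, the time horizon is the largest tornado driver) mirror the
published orderings.

## Known limitations

* Better-seeing-eye perspective only; no per-eye modelling or tunnel states.
* No within-first-year waning of treatment effect; no time-varying dosing.
* Transition rows are sampled as independent betas (with renormalisation),
  not Dirichlet; utilities are sampled independently across states.
* No EVPI or other value-of-information output.
* The indirect-cost scenario adds a single annual amount (default 2,000
  euros/year, a deliberately round figure for part-time informal care by
  family members — no published value exists) equally to both arms, so under
  equal mortality it shifts absolute costs but not increments.

## A worked example

```{r example, eval = FALSE}
library(dmecea)
params <- default_parameters()
res <- run_model(params)
res

psa <- run_psa(params, n = 2000, seed = 1)
psa
head(tornado(params), 3)
```
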