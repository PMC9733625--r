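---
title: "A Markov cohort cost-effectiveness model for focused ultrasound in essential tremor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-effectiveness model for focused ultrasound in essential tremor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremorcea)
```

## The decision problem

Medically refractory essential tremor (mrET) can be treated surgically with
deep brain stimulation (DBS), non-invasively with MR-guided focused
ultrasound (MRgFUS), or managed with medication alone. From the perspective
of a national healthcare payer, the question is whether unilateral MRgFUS
is worth its cost: against DBS for patients fit for neurosurgery, and
against medication-only care for patients who are not. `tremorcea`
implements a cohort-level decision model answering both questions, with
deterministic and probabilistic sensitivity analysis and a set of scenario
analyses.

## Model structure

The model is a Markov cohort model with five states and one-year cycles:

* **BT** — baseline disabling tremor (also the destination of an
  unsuccessful procedure, defined as under 10% improvement on the Clinical
  Rating Scale for Tremor);
* **MMT** — mild-to-moderately improved tremor (10–50% improvement);
* **MT** — markedly improved tremor (50–100% improvement);
* **TR** — tremor recurrence that leads to re-operation; a transient state
  occupied for exactly one cycle;
* **DEAD** — absorbing; entered from any state by all-cause mortality.

A procedure splits the cohort at cycle 0 across `MT`/`MMT`/`BT` by its
outcome proportions; medication-only care starts fully in `BT`. Each cycle,
conditional on surviving the year, patients in an improved state may
experience tremor recurrence (annual probability `recurrence_annual`,
meaning loss of tremor control back to baseline). A recurrence leads to
re-operation with probability `p_reop_given_recurrence` (base case 5%),
entering `TR`; the following cycle `TR` redistributes by the primary
outcome proportions, since re-operation is assumed to have the same outcome
profile as the primary procedure. Recurrence without re-operation moves the
patient to `BT`, where they remain: the model allows no later re-treatment
after a failed or abandoned pathway. Patients in `MT` who do not recur may
drift to `MMT` as the procedural effect wanes (`waning_annual`). Tremor
itself is treated as stable over the horizon; deterioration happens only
through recurrence or waning.

Competing risks within a cycle are nested in a fixed precedence — death,
then recurrence, then waning — which keeps every transition row stochastic
by construction. The cohort is aged one integer year per cycle and the
annual death probability is looked up in a sex-blended life table
(`male_fraction * q_male + (1 - male_fraction) * q_female`).

## Economic accounting

Per-patient outcomes are discounted total cost (2019 GBP) and discounted
QALYs over the horizon (default 5 years, the extent of the available
follow-up data for MRgFUS; the model deliberately does not extrapolate to
lifetime). Costs and QALYs are both discounted at 3.5% per year, the NICE
reference-case rate.

The accounting conventions, fixed once when the model was put together:

* cycle-`t` accruals (t = 1..T) use the **end-of-cycle** occupancy row and
  the end-of-cycle discount factor `(1 + r)^(-t)`;
* the primary procedure is charged once, undiscounted, at cycle 0;
* **no half-cycle correction** is applied. The source results this model
  is calibrated against come from a spreadsheet cohort model, and
  end-of-cycle accounting without half-cycle correction reproduces the
  published medication-only QALY total to within a third of a percent with
  the bundled life table, while a half-cycle-corrected variant overshoots
  it by roughly a tenth of a QALY.

Cost flows per cycle: every alive patient pays the annual medication cost
(tremor medication continues even in the `MT` state, because the untreated
arm still trembles) plus the monitoring band in force that model year, and
the fraction passing through `TR` is charged one full procedure cost.
Monitoring is a year-band map because each procedure cost bundles some
follow-up: the DBS price (£47,627) covers everything in year 1, with
£3,172/yr from year 2; the MRgFUS price (£16,500) covers years 1–5, with
£169/yr from year 6 (which matters only for horizons beyond 5 years);
medication-only care pays £169/yr throughout. Adverse-event unit costs are
carried in the inputs for sensitivity analysis, but produce no base-case
cash flow: for MRgFUS the source model states adverse events are managed
within routine follow-up, and for DBS the published totals are consistent
with procedure + monitoring + medication alone.

QALY flows per cycle weight occupancy by state utilities. The improvement
utilities are adverse-event-adjusted and split into a first-year and a
year-2+ value; `TR` carries baseline utility, and `DEAD` contributes
nothing. In cycle 1 only, the improved-state utilities are blended with
baseline utility by the onset-delay fraction: DBS benefit begins around
3 months after surgery (device optimisation), so a quarter of its first
year is spent at baseline utility; MRgFUS benefit is immediate.

Incremental comparisons report `ΔC`, `ΔQ` (intervention minus comparator)
and the ICER `ΔC/ΔQ`, or a dominance label when the intervention is both
cheaper and more effective (no ratio is meaningful there). Reports round
currency to the pound and QALYs to two decimals; internal arithmetic is at
full precision.

```{r base-case, eval = FALSE}
base_case_table()
```

## The mortality input

The published model uses national all-cause mortality, but the rates
themselves are not part of the published inputs, and neither is the exact
male proportion. The package therefore treats the life table as a model
*input* (CSV with `age,q_male,q_female`) and bundles a synthetic stand-in:
a Gompertz–Makeham schedule for ages 40–85 calibrated to the level of
recent (2017–2019 era) national life tables for England, with a default
male fraction of 0.46 at age 70. This table was fixed once, before any
result was compared, and is not adjusted thereafter; users with access to
official rates should substitute their own CSV. With this input the model
reproduces the published medication-only QALY total (2.95) to within a
third of a percent, which is the closest available calibration check on the
mortality assumption.

## One-way (deterministic) sensitivity analysis

`build_ranges()` assigns every numeric parameter a low/high range: a
supplied 95% CI where one exists (Wilson score intervals are provided for
small-sample trial proportions via `wilson_interval()`), otherwise ±20% of
the base value, clipped to the parameter's legal domain. `run_dsa()`
re-evaluates the full model at each bound, reports parameters whose ICER
moves by more than 5% relative to base, and orders rows by descending
bound-to-bound span (ties broken alphabetically) — the tornado ordering.
Varying one outcome proportion rescales the other two proportionally so the
simplex constraint survives; dominant comparisons are shown as the raw
(negative) cost-per-QALY ratio, as is conventional on tornado diagrams.

## Probabilistic sensitivity analysis

`run_psa()` performs Monte Carlo evaluation of the whole model
(default 1,000 iterations). Distributions follow the field's convention:
**beta** for probabilities, **gamma** for costs, both parameterised by
method of moments around the base value (`shape = (mean/sd)^2`,
`scale = sd^2/mean` for the gamma). Utilities are also sampled as beta —
they are bounded in [0, 1]; the convention in the source material assigns
beta explicitly only to probabilities, so this is recorded as a package
design choice. The standard deviation defaults to 20% of the mean,
mirroring the ±20% DSA rule, unless a CI override implies
`sd = (high − low)/(2 × 1.96)`.

Two coupling rules implement the principle that *inputs shared by the two
procedure strategies take the same value within an iteration*:

1. parameters that are literally the same input (outcome proportions,
   re-operation probability, medication cost, baseline utility) appear as
   one `shared.*` row and are drawn once per iteration;
2. the four adverse-event-adjusted improvement utilities per family
   (marked, mild) derive from a single underlying state utility each
   (0.91 marked, 0.80 mild, one literature source), so the family's rows
   draw from one shared quantile per iteration (comonotone coupling via
   inverse-CDF sampling). Each marginal distribution is untouched; only
   the joint behaviour changes, so a strategy never draws a high marked
   utility while its twin draws a low one.

Baseline utility remains an independent draw from the improvement
utilities. A consequence worth knowing: with the default 20%-of-mean
spreads, the baseline draw occasionally exceeds the improvement draws,
flipping the sign of small QALY differences. Coupling the entire utility
block comonotonically would suppress those crossings, but it also strips
most of the utility-driven spread out of the ICER distribution; the
family-level coupling was chosen as the structure actually implied by the
shared-input rule, not for the results it produces.

The outcome simplex is sampled as two draws: the marked proportion, and
the mild share of the non-marked remainder, which keeps
`p_marked + p_mild + p_none = 1` exactly. The onset delay is structural
and held fixed. Reproducibility: a master seed generates one sub-seed per
iteration, so iteration `i` is bit-identical regardless of how many other
iterations run.

`ceac()` turns the iteration records into cost-effectiveness acceptability
curves: at each willingness-to-pay `λ` on the grid (default 0–100,000 by
1,000 GBP/QALY), the fraction of iterations with incremental net monetary
benefit `λ·ΔQ − ΔC > 0`. Per-iteration ICERs are deliberately *not*
averaged — ratio averages are unstable when `ΔQ` approaches zero — so
summaries are the CEAC and the `(ΔQ, ΔC)` scatter (`autoplot()` on a
`psa_result`).

## Scenario analyses

All scenarios are parameterised re-runs of the same machinery:

* **Start age** (`run_age_scenario()`): only the mortality slice changes;
  clinical, cost and utility inputs stay at base. Sex mix is held constant
  across ages.
* **Time horizon** (`run_horizon_scenario()`): post-bundle monitoring
  bands engage automatically when the horizon outruns a cost bundle.
* **Current care** (`run_current_care_blend()`): the comparator is a
  population mixture — a fraction `f` receives DBS, `1 − f` medication
  only. The blend mixes strategy-level *outputs*, so blended cost and QALY
  are exactly linear in `f`; mixing transition matrices instead would not
  be, and a population mixture of two fixed treatment pathways is
  output-mixing by definition.
* **No discounting** (`run_no_discount_scenario()`).
* **Alternative inputs** (`run_alternative_inputs()`): the full pipeline
  on a substituted config file. A template with the required keys ships
  with the package; values from other trials are not bundled.

## Synthetic inputs and what the tests show

`random_strategy_inputs()`/`random_strategy_set()` generate random
parameter sets that always satisfy the validators (simplex outcome
proportions, ordered utilities, log-uniform costs), and
`gompertz_life_table()` generates monotone parametric mortality schedules.
These exist so every stage — validation, cohort engine, accounting,
sensitivity machinery — can be property-tested and fuzzed without any
external data: trace conservation, monotone death columns, and agreement
with an exhaustive path-enumeration oracle at short horizons are checked
over hundreds of generated models. What passing those tests does *not*
show is anything about real patients: the generators emulate the *shape*
of valid inputs, not the epidemiology of essential tremor, and the bundled
base case remains a transcription of one published input set.

## Numerical choices and edge cases

* Trace rows sum to 1 within 1e-12 by construction; validation rejects
  `recurrence_annual + waning_annual > 1` (competing-risk overflow).
* `q_death = 1` sends every alive state to `DEAD` in one cycle;
  `p_cum = 1` converts to an annual probability of 1.
* A zero QALY difference with a nonzero cost difference yields an
  "undefined ICER" outcome, not an error; equal results compare as
  "equivalent".
* Beta moment-matching refuses means outside (0, 1) and variances at or
  above `mean(1 − mean)`; degenerate (sd = 0) rows become point masses,
  which is also how `degenerate_psa_spec()` collapses the PSA onto the
  deterministic base case for testing.
* Monitoring-band lookup below year 1 is a configuration error; bands must
  start at year 1 and be strictly increasing.

## Problem sizes

The shipped analyses run at the scale of the published study: deterministic
runs are 6 × 5 matrix-vector products and complete in milliseconds; the PSA
default is 1,000 full model evaluations (a few seconds); the test suite
fuzzes a few hundred random models and runs the path-enumeration oracle at
horizon 3.

## Known limitations

* The payer perspective only: no productivity or carer costs, no
  perspective switches.
* Cohort fractions only; no patient-level simulation, no heterogeneity
  beyond the sex blend of mortality.
* The bundled life table is a synthetic approximation; substitute official
  rates for production estimates.
* DBS adverse-event costs are zero in the base case (see above); if
  per-event incidence data are available they belong in `ae_costs` plus a
  custom cost hook, which the current engine does not wire into cash flow.
* No re-treatment of `BT` patients after a failed primary procedure, and
  no battery-replacement cost for DBS beyond the horizon.
* No expected-value-of-perfect-information analysis.
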