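# tremorcea

A Markov cohort cost-effectiveness model of unilateral MR-guided focused
ultrasound (MRgFUS) for medically refractory essential tremor (mrET) in
England, compared against unilateral deep brain stimulation (DBS) and
against medication-only care, from the perspective of a national healthcare
payer (2019 GBP). The package is for health economists and HTA analysts who
want the published decision model as tested, configurable, scriptable code:
base-case evaluation, one-way deterministic sensitivity analysis (tornado),
Monte Carlo probabilistic sensitivity analysis with beta/gamma sampling and
shared-parameter coupling, cost-effectiveness acceptability curves, and the
standard scenario analyses (start age, time horizon, blended current care,
no discounting, alternative input sets).

## The model

Five health states — baseline tremor (BT), mild-to-moderately improved
(MMT), markedly improved (MT), transient recurrence awaiting re-operation
(TR), and death — with one-year cycles over a 5-year horizon. A procedure
splits the cohort at cycle 0 by its outcome proportions
(p_MT = 0.889, p_MMT = 0.100, p_BT = 0.011 in the base case); each cycle,
survivors in improved states face recurrence *r* (split 5%/95% into
re-operation vs permanent return to baseline) and waning *w* (MT → MMT),
nested after all-cause mortality from a sex-blended life table.

Discounted per-patient outcomes at rate *ρ* = 3.5%:

    Cost  = c_proc + Σ_{t=1..T} (1+ρ)^{-t} [ alive_t·(c_med + c_mon(t)) + TR_t·c_proc ]
    QALY  =          Σ_{t=1..T} (1+ρ)^{-t} Σ_s occ_{t,s}·u_s(t)

with first-year vs later utilities for the improved states and an
onset-delay blend in cycle 1 (DBS benefit starts at 3 months). The ICER
between strategies is ΔCost/ΔQALY, with dominance reported when a strategy
is both cheaper and more effective. See the methods vignette
(`vignettes/markov-cea-model.Rmd`) for every convention and design choice.

## Worked example

```r
library(tremorcea)

base_case_table()
#> # A tibble: 3 × 7
#>   strategy   cost delta_cost  qaly delta_qaly   icer label
#>   <chr>     <dbl>      <dbl> <dbl>      <dbl>  <dbl> <chr>
#> 1 MRGFUS   19707.        NA   3.67    NA         NA  ""
#> 2 DBS      61678.    -41971.  3.58     0.0947    NA  "intervention dominant"
#> 3 NONE      3893.     15813.  2.94     0.730  21669. "ICER"
```

Reading the table: over five discounted years MRgFUS costs about £19,700
per patient for 3.67 QALYs. Against DBS it saves about £42,000 and gains
QALYs, so it is dominant (no ratio is meaningful). Against medication-only
care it costs about £15,800 more and gains 0.73 QALYs, an ICER of about
£21,700 per QALY — inside the usual £20,000–30,000 willingness-to-pay
range used in England.

Everything is a plain function over data frames, so the rest of the
analysis chains naturally:

```r
psa <- run_psa(n = 1000, seed = 42)          # beta/gamma Monte Carlo
glance(psa)                                  # per-comparison summary
autoplot(ceac(psa))                          # acceptability curves
run_dsa(base_case_strategies(), econ_settings(), england_life_table()) |>
  autoplot()                                 # tornado
run_horizon_scenario(1:10)                   # scenario sweeps
```

Inputs live in one YAML config (see
`system.file("extdata", "base_case.yaml", package = "tremorcea")`), the
life table is a CSV input (a synthetic England-style table is bundled), and
a thin command-line shim (`inst/cli/tremorcea`) exposes `run`, `dsa`,
`psa`, `scenario` and `synth` subcommands for shell use.

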