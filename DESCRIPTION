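Package: tremorcea
Title: Markov Cohort Cost-Effectiveness Model of Focused Ultrasound for
    Essential Tremor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-state Markov cohort model comparing unilateral magnetic
    resonance-guided focused ultrasound (MRgFUS) against unilateral deep
    brain stimulation (DBS) and against medication-only care for medically
    refractory essential tremor, from the perspective of a national
    healthcare payer (costs in 2019 GBP). Computes discounted per-patient
    costs and quality-adjusted life-years, incremental cost-effectiveness
    ratios, one-way deterministic sensitivity analyses, Monte Carlo
    probabilistic sensitivity analyses with beta/gamma sampling and shared
    parameter coupling, cost-effectiveness acceptability curves, and
    scenario analyses (start age, time horizon, blended current care, no
    discounting, alternative input sets). All inputs are supplied as plain
    config files; a synthetic-input module generates random valid parameter
    sets and parametric life tables so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
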