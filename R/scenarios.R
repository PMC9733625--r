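#' Start-age scenario
#'
#' Re-runs the model with different cohort entry ages. Only the mortality
#' slice of the life table changes; every clinical, cost and utility input
#' is held at base.
#'
#' @param ages Integer vector of start ages.
#' @inheritParams base_case_table
#' @return A tibble: the base-case results table per age, stacked, with a
#'   leading `start_age` column.
#' @export
#' @examples
#' run_age_scenario(c(40, 70))
run_age_scenario <- function(ages = c(40, 50, 60, 70),
                             strategies = base_case_strategies(),
                             settings = econ_settings(),
                             lt = england_life_table()) {
  dplyr::bind_rows(purrr::map(ages, function(a) {
    st <- settings
    st$start_age <- as.integer(a)
    dplyr::mutate(base_case_table(strategies, st, lt),
                  start_age = a, .before = 1)
  }))
}

#' Time-horizon scenario
#'
#' Re-runs the model over alternative horizons. Post-bundle monitoring
#' bands apply automatically when the horizon outruns a procedure's cost
#' bundle (e.g. 169/yr for MRgFUS from year 6).
#'
#' @param horizons Integer vector of horizons in years.
#' @inheritParams base_case_table
#' @return Stacked results tables with a leading `horizon_years` column.
#' @export
run_horizon_scenario <- function(horizons = c(1, 5, 10),
                                 strategies = base_case_strategies(),
                                 settings = econ_settings(),
                                 lt = england_life_table()) {
  dplyr::bind_rows(purrr::map(horizons, function(T) {
    st <- settings
    st$horizon_years <- as.integer(T)
    dplyr::mutate(base_case_table(strategies, st, lt),
                  horizon_years = T, .before = 1)
  }))
}

#' Current-care blend scenario
#'
#' Compares the intervention against "current care": a population mixture
#' in which a fraction `f` of patients receives the surgical comparator
#' and `1 - f` receives medication only. The blend mixes strategy-level
#' outputs, so blended cost and QALYs are exactly linear in `f`.
#'
#' @param fractions Vector of eligibility fractions in \[0, 1\].
#' @param intervention,procedure,no_procedure Strategy names within
#'   `strategies` for the intervention and the two blended arms.
#' @inheritParams base_case_table
#' @return A tibble with one row per fraction: blended comparator cost and
#'   QALYs, differences (intervention minus blend), ICER and dominance
#'   label.
#' @export
#' @examples
#' run_current_care_blend(c(0, 0.5, 1))
run_current_care_blend <- function(fractions = seq(0, 1, by = 0.1),
                                   strategies = base_case_strategies(),
                                   settings = econ_settings(),
                                   lt = england_life_table(),
                                   intervention = "MRGFUS",
                                   procedure = "DBS",
                                   no_procedure = "NONE") {
  stopifnot(all(fractions >= 0), all(fractions <= 1))
  res <- purrr::map(strategies[c(intervention, procedure, no_procedure)],
                    evaluate_strategy, settings = settings, lt = lt)
  ri <- res[[intervention]]; rp <- res[[procedure]]; rn <- res[[no_procedure]]
  dplyr::bind_rows(purrr::map(fractions, function(f) {
    cost <- f * rp$total_cost + (1 - f) * rn$total_cost
    qaly <- f * rp$total_qaly + (1 - f) * rn$total_qaly
    dc <- ri$total_cost - cost
    dq <- ri$total_qaly - qaly
    dominant <- dc < 0 && dq > 0
    tibble(fraction = f,
           cost = cost, qaly = qaly,
           delta_cost = dc, delta_qaly = dq,
           icer = if (dq != 0) dc / dq else NA_real_,
           label = if (dominant) "intervention dominant" else "ICER")
  }))
}

#' No-discounting scenario
#'
#' @inheritParams base_case_table
#' @return The base-case results table with `discount_rate = 0`.
#' @export
run_no_discount_scenario <- function(strategies = base_case_strategies(),
                                     settings = econ_settings(),
                                     lt = england_life_table()) {
  settings$discount_rate <- 0
  base_case_table(strategies, settings, lt)
}

#' Alternative-inputs scenario
#'
#' Runs the full machinery (base table, one-way DSA, PSA) on a substituted
#' config file -- e.g. parameter values from a different trial. A template
#' config with the required keys ships with the package
#' (`system.file("extdata", "alternative_inputs_template.yaml",
#' package = "tremorcea")`); its values must be filled in by the user.
#'
#' @param path Path to a config file ([load_config()] schema).
#' @param psa_n PSA iterations (set to 0 to skip DSA/PSA).
#' @param seed PSA seed.
#' @return A list with elements `base_table`, and when `psa_n > 0`,
#'   `dsa` and `psa`.
#' @export
run_alternative_inputs <- function(path, psa_n = 1000, seed = 42) {
  cfg <- load_config(path)
  out <- list(base_table = base_case_table(cfg$strategies, cfg$settings,
                                           cfg$life_table))
  if (psa_n > 0) {
    out$dsa <- run_dsa(cfg$strategies, cfg$settings, cfg$life_table)
    out$psa <- run_psa(cfg$strategies, cfg$settings, cfg$life_table,
                       n = psa_n, seed = seed)
  }
  out
}
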