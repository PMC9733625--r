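#' Construct a validated strategy input set
#'
#' Bundles every clinical, cost and utility parameter the model needs for one
#' treatment strategy. All probabilities are annual (per one-year cycle),
#' all costs are 2019 GBP, all utilities are preference weights in \[0, 1\].
#'
#' @param name Strategy label, one of [strategy_names()]. `"NONE"` is the
#'   medication-only comparator: it must have `p_none = 1` and no procedure
#'   cost, and the cohort starts fully in the baseline-tremor state.
#' @param p_marked,p_mild,p_none Post-procedure outcome proportions (marked
#'   improvement, mild/moderate improvement, unsuccessful procedure). Must
#'   sum to 1.
#' @param waning_annual Annual probability of drifting from marked to
#'   mild/moderate improvement as procedural effect wanes.
#' @param recurrence_annual Annual probability of tremor recurrence (return
#'   to baseline tremor control) from either improved state.
#' @param p_reop_given_recurrence Probability that a recurrence leads to
#'   re-operation (entering the transient `TR` state).
#' @param onset_delay_fraction Fraction of the first cycle spent at baseline
#'   utility before treatment benefit begins (0 for MRgFUS whose benefit is
#'   immediate; 0.25 for DBS, whose stimulator needs ~3 months of
#'   optimisation).
#' @param procedure_cost One-off procedure cost charged to the whole cohort
#'   at cycle 0, and again per re-operation. Includes `bundle_years` of
#'   follow-up/monitoring.
#' @param bundle_years Number of leading years whose monitoring is already
#'   inside `procedure_cost`.
#' @param monitoring_annual Year-band map of ongoing monitoring cost: a data
#'   frame with columns `year_from` (first model year the band applies to)
#'   and `amount` (GBP per year). Lookup takes the last band whose
#'   `year_from` does not exceed the cycle index.
#' @param medication_annual Annual tremor-medication cost, charged to every
#'   alive patient in every state and strategy.
#' @param u_bt,u_tr Utility of baseline tremor and of the recurrence state
#'   (equal in the base case).
#' @param u_mt_y1,u_mt_y2plus,u_mmt_y1,u_mmt_y2plus Adverse-event-adjusted
#'   utilities of the improved states, split into first-year and subsequent
#'   values.
#' @param ae_costs Named numeric vector of per-event adverse-event costs.
#'   Carried for sensitivity analysis; produces no base-case cash flow.
#'
#' @return An object of class `strategy_inputs` (a named list).
#' @seealso [base_case_strategies()] for the bundled base-case parameter
#'   sets, [validate_strategy_inputs()] for the invariants enforced.
#' @export
#' @examples
#' s <- base_case_strategies()$MRGFUS
#' s$p_marked
strategy_inputs <- function(name,
                            p_marked, p_mild, p_none,
                            waning_annual = 0,
                            recurrence_annual = 0,
                            p_reop_given_recurrence = 0,
                            onset_delay_fraction = 0,
                            procedure_cost = 0,
                            bundle_years = 0L,
                            monitoring_annual = monitoring_bands(0),
                            medication_annual = 0,
                            u_bt, u_tr = u_bt,
                            u_mt_y1 = u_bt, u_mt_y2plus = u_mt_y1,
                            u_mmt_y1 = u_bt, u_mmt_y2plus = u_mmt_y1,
                            ae_costs = c()) {
  s <- structure(
    list(
      name = name,
      p_marked = p_marked, p_mild = p_mild, p_none = p_none,
      waning_annual = waning_annual,
      recurrence_annual = recurrence_annual,
      p_reop_given_recurrence = p_reop_given_recurrence,
      onset_delay_fraction = onset_delay_fraction,
      procedure_cost = procedure_cost,
      bundle_years = as.integer(bundle_years),
      monitoring_annual = as_tibble(monitoring_annual),
      medication_annual = medication_annual,
      u_bt = u_bt, u_tr = u_tr,
      u_mt_y1 = u_mt_y1, u_mt_y2plus = u_mt_y2plus,
      u_mmt_y1 = u_mmt_y1, u_mmt_y2plus = u_mmt_y2plus,
      ae_costs = ae_costs
    ),
    class = "strategy_inputs"
  )
  validate_strategy_inputs(s)
}

#' Build a monitoring year-band table
#'
#' @param ... Annual monitoring amounts (GBP); `year_from` gives the first
#'   model year each amount applies to. With a single unnamed amount the
#'   band starts at year 1.
#' @param year_from Integer vector, same length as the amounts, strictly
#'   increasing, starting at 1.
#' @return A tibble with columns `year_from`, `amount`.
#' @export
#' @examples
#' monitoring_bands(0, 169, year_from = c(1, 6)) # free while bundled, then £169
monitoring_bands <- function(..., year_from = 1L) {
  amount <- c(...)
  if (length(amount) != length(year_from)) {
    abort("`year_from` must have one entry per amount.",
          class = "tremorcea_validation_error")
  }
  tibble(year_from = as.integer(year_from), amount = as.numeric(amount))
}

#' Validate a strategy input set
#'
#' Enforces the model's input invariants: outcome proportions sum to one,
#' probabilities and utilities lie in \[0, 1\], costs are non-negative,
#' recurrence and waning do not overflow the cycle (competing risks), the
#' monitoring band table is well formed and starts at year 1, and the
#' `NONE` strategy carries no procedure.
#'
#' @param s A `strategy_inputs` object.
#' @return `s`, invisibly unchanged, if valid; otherwise an error of class
#'   `tremorcea_validation_error` naming the offending field and rule.
#' @export
validate_strategy_inputs <- function(s) {
  fail <- function(field, rule) {
    abort(sprintf("Invalid strategy inputs (%s): field `%s` %s.",
                  s$name %||% "?", field, rule),
          class = "tremorcea_validation_error")
  }
  if (!is.character(s$name) || !(s$name %in% strategy_names())) {
    fail("name", sprintf("must be one of %s",
                         paste(strategy_names(), collapse = ", ")))
  }
  probs <- c("p_marked", "p_mild", "p_none", "waning_annual",
             "recurrence_annual", "p_reop_given_recurrence",
             "onset_delay_fraction")
  for (f in probs) {
    v <- s[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      fail(f, "must be a probability in [0, 1]")
    }
  }
  if (abs(s$p_marked + s$p_mild + s$p_none - 1) > 1e-9) {
    fail("p_marked + p_mild + p_none", "must sum to 1 (within 1e-9)")
  }
  if (s$recurrence_annual + s$waning_annual > 1) {
    fail("recurrence_annual + waning_annual",
         "must not exceed 1 (competing-risk overflow)")
  }
  for (f in c("u_bt", "u_tr", "u_mt_y1", "u_mt_y2plus",
              "u_mmt_y1", "u_mmt_y2plus")) {
    v <- s[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      fail(f, "must be a utility in [0, 1]")
    }
  }
  if (!is.numeric(s$procedure_cost) || s$procedure_cost < 0) {
    fail("procedure_cost", "must be a non-negative cost")
  }
  if (!is.numeric(s$medication_annual) || s$medication_annual < 0) {
    fail("medication_annual", "must be a non-negative cost")
  }
  m <- s$monitoring_annual
  if (!all(c("year_from", "amount") %in% names(m)) || nrow(m) < 1) {
    fail("monitoring_annual", "must have columns year_from, amount")
  }
  if (m$year_from[1] != 1L || is.unsorted(m$year_from, strictly = TRUE)) {
    fail("monitoring_annual$year_from",
         "must start at 1 and be strictly increasing")
  }
  if (any(m$amount < 0)) fail("monitoring_annual$amount", "must be >= 0")
  if (length(s$ae_costs) && any(s$ae_costs < 0)) {
    fail("ae_costs", "must be >= 0")
  }
  if (s$name == "NONE") {
    if (s$p_none != 1 || s$p_marked != 0 || s$p_mild != 0) {
      fail("p_none", "must be 1 for NONE (no post-procedure outcomes)")
    }
    if (s$procedure_cost != 0) fail("procedure_cost", "must be 0 for NONE")
  }
  invisible(s)
}

#' @export
print.strategy_inputs <- function(x, ...) {
  cat(sprintf("<strategy_inputs: %s>\n", x$name))
  cat(sprintf("  outcomes  marked %.3f / mild %.3f / none %.3f\n",
              x$p_marked, x$p_mild, x$p_none))
  cat(sprintf("  dynamics  waning %.3f, recurrence %.3f, re-op|rec %.2f\n",
              x$waning_annual, x$recurrence_annual, x$p_reop_given_recurrence))
  cat(sprintf("  costs     procedure £%s, medication £%s/yr\n",
              format(x$procedure_cost, big.mark = ","),
              format(x$medication_annual, big.mark = ",")))
  cat(sprintf("  utilities BT %.2f, MT %.2f/%.2f, MMT %.2f/%.2f\n",
              x$u_bt, x$u_mt_y1, x$u_mt_y2plus, x$u_mmt_y1, x$u_mmt_y2plus))
  invisible(x)
}

#' Monitoring cost in force at a given model year
#'
#' @param s A `strategy_inputs` object.
#' @param year Model year (cycle index, >= 1).
#' @return Annual monitoring cost in GBP for that year.
#' @export
monitoring_cost <- function(s, year) {
  m <- s$monitoring_annual
  i <- findInterval(year, m$year_from)
  if (i < 1) {
    abort(sprintf("No monitoring band covers year %d for %s.", year, s$name),
          class = "tremorcea_config_error")
  }
  m$amount[i]
}

#' Economic evaluation settings
#'
#' @param discount_rate Annual discount rate applied to both costs and
#'   QALYs (NICE reference case: 0.035).
#' @param horizon_years Model time horizon in one-year cycles.
#' @param start_age Cohort age at entry (years).
#' @param male_fraction Male proportion of the cohort, used to blend the
#'   sex-specific life table columns.
#' @param wtp_grid Strictly increasing willingness-to-pay grid (GBP/QALY)
#'   for acceptability curves.
#' @param population_size Eligible population, used only for optional budget
#'   scaling; per-patient results never depend on it.
#' @param cycle_years Cycle length; fixed at 1 year.
#' @return An object of class `econ_settings`.
#' @export
#' @examples
#' econ_settings(horizon_years = 10)
econ_settings <- function(discount_rate = 0.035,
                          horizon_years = 5L,
                          start_age = 70L,
                          male_fraction = 0.46,
                          wtp_grid = seq(0, 100000, by = 1000),
                          population_size = 1415L,
                          cycle_years = 1) {
  if (discount_rate < 0) {
    abort("`discount_rate` must be >= 0.", class = "tremorcea_validation_error")
  }
  if (horizon_years < 1) {
    abort("`horizon_years` must be >= 1.", class = "tremorcea_validation_error")
  }
  if (cycle_years != 1) {
    abort("`cycle_years` is fixed at 1 year.",
          class = "tremorcea_validation_error")
  }
  if (male_fraction < 0 || male_fraction > 1) {
    abort("`male_fraction` must lie in [0, 1].",
          class = "tremorcea_validation_error")
  }
  if (length(wtp_grid) && is.unsorted(wtp_grid, strictly = TRUE)) {
    abort("`wtp_grid` must be strictly increasing.",
          class = "tremorcea_validation_error")
  }
  structure(
    list(discount_rate = discount_rate,
         horizon_years = as.integer(horizon_years),
         start_age = as.integer(start_age),
         male_fraction = male_fraction,
         wtp_grid = as.numeric(wtp_grid),
         population_size = as.integer(population_size),
         cycle_years = 1),
    class = "econ_settings"
  )
}

#' @export
print.econ_settings <- function(x, ...) {
  cat(sprintf(paste0("<econ_settings: %d-year horizon, %.1f%% discount, ",
                     "start age %d, male fraction %.2f>\n"),
              x$horizon_years, 100 * x$discount_rate, x$start_age,
              x$male_fraction))
  invisible(x)
}

# Base-case adverse-event unit costs (2019 GBP); zero cash flow in the base
# case, retained so sensitivity analyses can price them.
.base_ae_costs <- c(
  infection = 657,
  intracranial_haemorrhage = 20545,
  lead_fracture_or_migration = 14777,
  gait_disturbance = 0,
  speech_problem = 42
)

#' Bundled base-case strategy parameter sets
#'
#' The base case for England: both procedures share the trial outcome
#' distribution (88.9% marked / 10.0% mild / 1.1% none) and differ in
#' waning (9.2% vs 7.7%/yr), recurrence (1% vs 3.9%/yr), onset delay
#' (immediate vs 3 months), procedure cost (16,500 covering 5 years of
#' follow-up vs 47,627 covering 1 year), post-bundle monitoring (169 vs
#' 3,172/yr) and long-term adverse-event-adjusted utilities. Medication-only
#' care stays at baseline utility 0.69 with 744/yr medication and 169/yr
#' monitoring.
#'
#' @return Named list of `strategy_inputs` for `MRGFUS`, `DBS`, `NONE`.
#' @export
#' @examples
#' names(base_case_strategies())
base_case_strategies <- function() {
  list(
    MRGFUS = strategy_inputs(
      name = "MRGFUS",
      p_marked = 0.889, p_mild = 0.100, p_none = 0.011,
      waning_annual = 0.092,
      recurrence_annual = 0.01,
      p_reop_given_recurrence = 0.05,
      onset_delay_fraction = 0,
      procedure_cost = 16500, bundle_years = 5L,
      monitoring_annual = monitoring_bands(0, 169, year_from = c(1, 6)),
      medication_annual = 744,
      u_bt = 0.69, u_tr = 0.69,
      u_mt_y1 = 0.91, u_mt_y2plus = 0.90,
      u_mmt_y1 = 0.80, u_mmt_y2plus = 0.79,
      ae_costs = .base_ae_costs
    ),
    DBS = strategy_inputs(
      name = "DBS",
      p_marked = 0.889, p_mild = 0.100, p_none = 0.011,
      waning_annual = 0.077,
      recurrence_annual = 0.039,
      p_reop_given_recurrence = 0.05,
      onset_delay_fraction = 0.25,
      procedure_cost = 47627, bundle_years = 1L,
      monitoring_annual = monitoring_bands(0, 3172, year_from = c(1, 2)),
      medication_annual = 744,
      u_bt = 0.69, u_tr = 0.69,
      u_mt_y1 = 0.91, u_mt_y2plus = 0.91,
      u_mmt_y1 = 0.80, u_mmt_y2plus = 0.76,
      ae_costs = .base_ae_costs
    ),
    NONE = strategy_inputs(
      name = "NONE",
      p_marked = 0, p_mild = 0, p_none = 1,
      monitoring_annual = monitoring_bands(169),
      medication_annual = 744,
      u_bt = 0.69
    )
  )
}
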