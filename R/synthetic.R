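# Synthetic-input generators: random valid parameter sets and parametric
# life tables, so the whole pipeline can be exercised (and fuzzed) with no
# external data.

#' Random valid strategy inputs
#'
#' Draws a parameter set that always passes [validate_strategy_inputs()]:
#' outcome proportions from a normalised simplex draw, probabilities and
#' utilities uniform within bounds, costs log-uniform within bounds.
#' Intended for property tests and pipeline fuzzing, not for inference.
#'
#' @param name Strategy label. For `"NONE"` the procedure block is forced
#'   to the medication-only constraints.
#' @param bounds Optional named list overriding the default sampling
#'   bounds; each entry is `c(low, high)`. Recognised names:
#'   `waning_annual`, `recurrence_annual`, `p_reop_given_recurrence`,
#'   `onset_delay_fraction`, `procedure_cost`, `medication_annual`,
#'   `monitoring_annual`, `utility`.
#' @return A validated `strategy_inputs` object. Uses the session RNG;
#'   seed with [set.seed()] for reproducibility.
#' @export
#' @examples
#' set.seed(1)
#' random_strategy_inputs()
random_strategy_inputs <- function(name = "MRGFUS", bounds = list()) {
  b <- modifyList(list(
    waning_annual = c(0, 0.3),
    recurrence_annual = c(0, 0.3),
    p_reop_given_recurrence = c(0, 0.5),
    onset_delay_fraction = c(0, 0.5),
    procedure_cost = c(1000, 100000),
    medication_annual = c(50, 5000),
    monitoring_annual = c(10, 10000),
    utility = c(0.3, 1)
  ), bounds)
  runif1 <- function(lim) stats::runif(1, lim[1], lim[2])
  logunif <- function(lim) exp(stats::runif(1, log(lim[1]), log(lim[2])))
  if (name == "NONE") {
    u_bt <- runif1(b$utility)
    return(strategy_inputs(
      name = "NONE", p_marked = 0, p_mild = 0, p_none = 1,
      monitoring_annual = monitoring_bands(logunif(b$monitoring_annual)),
      medication_annual = logunif(b$medication_annual),
      u_bt = u_bt
    ))
  }
  simplex <- stats::runif(3)
  simplex <- simplex / sum(simplex)
  # utilities ordered so improved states sit above baseline
  us <- sort(stats::runif(3, b$utility[1], b$utility[2]))
  u_bt <- us[1]; u_mmt <- us[2]; u_mt <- us[3]
  year1_bump <- function(u) min(1, u * stats::runif(1, 1, 1.02))
  strategy_inputs(
    name = name,
    p_marked = simplex[1], p_mild = simplex[2], p_none = simplex[3],
    waning_annual = runif1(b$waning_annual),
    recurrence_annual = runif1(b$recurrence_annual),
    p_reop_given_recurrence = runif1(b$p_reop_given_recurrence),
    onset_delay_fraction = runif1(b$onset_delay_fraction),
    procedure_cost = logunif(b$procedure_cost),
    bundle_years = sample(0:5, 1),
    monitoring_annual = monitoring_bands(
      logunif(b$monitoring_annual), logunif(b$monitoring_annual),
      year_from = c(1L, sample(2:6, 1))
    ),
    medication_annual = logunif(b$medication_annual),
    u_bt = u_bt,
    u_mt_y1 = year1_bump(u_mt), u_mt_y2plus = u_mt,
    u_mmt_y1 = year1_bump(u_mmt), u_mmt_y2plus = u_mmt
  )
}

#' Random full strategy set
#'
#' @inheritParams random_strategy_inputs
#' @return Named list of random `strategy_inputs` for all of
#'   [strategy_names()].
#' @export
random_strategy_set <- function(bounds = list()) {
  out <- purrr::map(setNames(strategy_names(), strategy_names()),
                    random_strategy_inputs, bounds = bounds)
  # shared parameters coherent across the set, as in real input files
  out$DBS$p_marked <- out$MRGFUS$p_marked
  out$DBS$p_mild <- out$MRGFUS$p_mild
  out$DBS$p_none <- out$MRGFUS$p_none
  for (nm in strategy_names()) {
    out[[nm]]$medication_annual <- out$MRGFUS$medication_annual
    out[[nm]]$u_bt <- out$MRGFUS$u_bt
    out[[nm]]$u_tr <- out$MRGFUS$u_bt
  }
  out$NONE$u_mt_y1 <- out$NONE$u_mt_y2plus <-
    out$NONE$u_mmt_y1 <- out$NONE$u_mmt_y2plus <- out$NONE$u_bt
  purrr::map(out, validate_strategy_inputs)
}

#' Parametric (Gompertz) life table
#'
#' Annual death probability under a Gompertz hazard `a * exp(b * x)`:
#' `q(x) = 1 - exp(-a * exp(b * x) * (exp(b) - 1) / b)`, clipped to
#' \[0, 1\] and monotone increasing in age. A synthetic stand-in for
#' official mortality schedules; both sexes get the same column unless
#' separate parameters are given.
#'
#' @param a,b Gompertz level and slope (> 0).
#' @param age_lo,age_hi Age range (inclusive).
#' @param a_female,b_female Optional female-specific parameters.
#' @return A `life_table` tibble.
#' @export
#' @examples
#' gompertz_life_table(2e-5, 0.1, 40, 85)
gompertz_life_table <- function(a, b, age_lo, age_hi,
                                a_female = a, b_female = b) {
  stopifnot(a > 0, b > 0, a_female > 0, b_female > 0, age_lo < age_hi)
  q <- function(a, b, x) pmin(1, 1 - exp(-a * exp(b * x) * (exp(b) - 1) / b))
  ages <- age_lo:age_hi
  validate_life_table(tibble(
    age = ages,
    q_male = q(a, b, ages),
    q_female = q(a_female, b_female, ages)
  ))
}
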