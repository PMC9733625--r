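#' Cohort distribution immediately post-procedure
#'
#' Procedures split the cohort across the improvement states by the trial
#' outcome proportions; medication-only care starts fully at baseline.
#'
#' @param s A `strategy_inputs` object.
#' @return Named numeric vector over [health_states()], summing to 1.
#' @export
#' @examples
#' initial_distribution(base_case_strategies()$MRGFUS)
initial_distribution <- function(s) {
  c(BT = s$p_none, MMT = s$p_mild, MT = s$p_marked, TR = 0, DEAD = 0)
}

#' Convert a cumulative probability to an annual probability
#'
#' Assumes a constant hazard over the period:
#' `1 - (1 - p_cum)^(1 / years)`, so applying the annual probability
#' `years` times recomposes `p_cum` exactly.
#'
#' @param p_cum Cumulative probability over the whole period, in \[0, 1\].
#' @param years Period length in years (> 0).
#' @return Annual probability.
#' @export
#' @examples
#' annual_probability(0.19, 2) # 0.1
annual_probability <- function(p_cum, years) {
  stopifnot(p_cum >= 0, p_cum <= 1, years > 0)
  1 - (1 - p_cum)^(1 / years)
}

#' One-cycle transition matrix
#'
#' Row-stochastic 5x5 matrix over [health_states()]. Death acts first
#' (every alive state moves to `DEAD` with `q_death`); conditional on
#' survival, recurrence precedes waning as competing risks:
#' * `MT`: recurrence with `recurrence_annual`, split
#'   `p_reop_given_recurrence` to `TR` and the rest to `BT`; otherwise
#'   waning to `MMT` with `waning_annual`; otherwise stay.
#' * `MMT`: recurrence with the same split; otherwise stay.
#' * `BT`: stay (no re-treatment after a failed primary procedure).
#' * `TR`: re-operation, redistributing by [initial_distribution()] --
#'   re-operation has the same outcome profile as the primary procedure.
#' * `DEAD`: absorbing.
#'
#' @param s A `strategy_inputs` object.
#' @param q_death Annual all-cause death probability for this cycle.
#' @return 5x5 numeric matrix with dimnames [health_states()].
#' @export
transition_matrix <- function(s, q_death) {
  if (q_death < 0 || q_death > 1) {
    abort("`q_death` must lie in [0, 1].", class = "tremorcea_range_error")
  }
  r <- s$recurrence_annual
  w <- s$waning_annual
  reop <- s$p_reop_given_recurrence
  alive <- function(row) (1 - q_death) * row + c(0, 0, 0, 0, q_death)
  P <- matrix(0, 5, 5, dimnames = list(.states, .states))
  P["BT", ] <- alive(c(1, 0, 0, 0, 0))
  P["MMT", ] <- alive(c(r * (1 - reop), 1 - r, 0, r * reop, 0))
  P["MT", ] <- alive(c(r * (1 - reop), (1 - r) * w, (1 - r) * (1 - w),
                       r * reop, 0))
  P["TR", ] <- alive(c(s$p_none, s$p_mild, s$p_marked, 0, 0))
  P["DEAD", "DEAD"] <- 1
  P
}

#' Run the cohort through the model horizon
#'
#' Row 0 of the trace is the post-procedure distribution; each subsequent
#' row is the previous row pushed through [transition_matrix()] with the
#' sex-blended death probability at the cohort's current age (age advances
#' one year per cycle).
#'
#' @param s A `strategy_inputs` object.
#' @param settings An [econ_settings()] object.
#' @param lt A `life_table` covering
#'   `[start_age, start_age + horizon_years - 1]`.
#' @return A `cohort_trace` tibble with columns `cycle`, `age`, the five
#'   state occupancies, and `reop_flow` (the fraction occupying `TR` that
#'   cycle, which drives re-operation cost).
#' @export
#' @examples
#' run_cohort(base_case_strategies()$MRGFUS, econ_settings(),
#'            england_life_table())
run_cohort <- function(s, settings, lt) {
  validate_strategy_inputs(s)
  T <- settings$horizon_years
  occ <- matrix(0, T + 1, 5, dimnames = list(NULL, .states))
  occ[1, ] <- initial_distribution(s)
  for (t in seq_len(T)) {
    q <- blended_mortality(lt, settings$start_age + t - 1,
                           settings$male_fraction)
    occ[t + 1, ] <- occ[t, ] %*% transition_matrix(s, q)
  }
  out <- as_tibble(occ)
  out <- tibble::add_column(out,
                            cycle = 0:T,
                            age = settings$start_age + 0:T,
                            .before = 1)
  out$reop_flow <- out$TR
  class(out) <- c("cohort_trace", class(out))
  out
}

# occupancy rows as a bare matrix (cycles x states)
trace_matrix <- function(trace) {
  as.matrix(trace[, .states])
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace: %d cycles>\n", max(x$cycle)))
  NextMethod()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot state occupancy over time
#'
#' @param object A `cohort_trace`.
#' @param ... Unused.
#' @return A ggplot of occupancy by state across cycles.
#' @method autoplot cohort_trace
#' @export
autoplot.cohort_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object)[c("cycle", .states)],
                              -"cycle", names_to = "state",
                              values_to = "occupancy")
  long$state <- factor(long$state, levels = .states)
  ggplot2::ggplot(long, ggplot2::aes(.data$cycle, .data$occupancy,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Cycle (years)", y = "Cohort fraction",
                  colour = "State") +
    ggplot2::theme_minimal()
}
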