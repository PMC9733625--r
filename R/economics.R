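#' End-of-cycle discount factor
#'
#' `(1 + r)^(-t)`. The model discounts every cycle-`t` accrual (t = 1..T)
#' at end of cycle; the cycle-0 procedure charge is undiscounted.
#'
#' @param t Cycle index (>= 1).
#' @param r Annual discount rate (>= 0).
#' @return Discount factor.
#' @export
discount_factor <- function(t, r) {
  stopifnot(all(t >= 1), r >= 0)
  (1 + r)^(-t)
}

#' Undiscounted cost accrued in one cycle
#'
#' Every alive patient pays medication plus the monitoring band in force
#' that model year; the fraction passing through `TR` is charged one
#' re-operation at the procedure cost. The cycle-0 primary procedure charge
#' is handled by [evaluate_strategy()], not here.
#'
#' @param row Named occupancy vector (end of the cycle).
#' @param reop_flow Fraction entering `TR` this cycle.
#' @param s A `strategy_inputs` object.
#' @param year Model year (cycle index, >= 1) for the monitoring band.
#' @return Cost in GBP.
#' @export
cycle_cost <- function(row, reop_flow, s, year) {
  alive <- 1 - row[["DEAD"]]
  alive * (s$medication_annual + monitoring_cost(s, year)) +
    reop_flow * s$procedure_cost
}

#' Undiscounted QALYs accrued in one cycle
#'
#' Occupancy-weighted utilities. Improved-state utilities use their
#' first-year values in cycle 1 and the year-2+ values thereafter; in cycle
#' 1 only, they are additionally blended with baseline utility by the
#' strategy's onset delay (benefit starting 3 months in means a quarter of
#' the first year at baseline utility). `DEAD` contributes zero; `TR`
#' carries baseline utility.
#'
#' @param row Named occupancy vector (end of the cycle).
#' @param s A `strategy_inputs` object.
#' @param year Cycle index (>= 1).
#' @return QALYs.
#' @export
cycle_qaly <- function(row, s, year) {
  if (year == 1) {
    d <- s$onset_delay_fraction
    u_mt <- d * s$u_bt + (1 - d) * s$u_mt_y1
    u_mmt <- d * s$u_bt + (1 - d) * s$u_mmt_y1
  } else {
    u_mt <- s$u_mt_y2plus
    u_mmt <- s$u_mmt_y2plus
  }
  row[["BT"]] * s$u_bt + row[["TR"]] * s$u_tr +
    row[["MT"]] * u_mt + row[["MMT"]] * u_mmt
}

#' Evaluate one strategy: discounted per-patient cost and QALYs
#'
#' Runs the cohort ([run_cohort()]) and accrues discounted costs and QALYs
#' over the horizon. Cycle-`t` accruals use the end-of-cycle occupancy row
#' and the end-of-cycle discount factor; the primary procedure is charged
#' once, undiscounted, at cycle 0.
#'
#' @inheritParams run_cohort
#' @return An object of class `strategy_result`: total discounted cost and
#'   QALYs plus the per-cycle streams and the trace that produced them.
#'   Use [tidy()][generics::tidy()] for the per-cycle tibble and
#'   [glance()][generics::glance()] for the one-row summary.
#' @export
#' @examples
#' res <- evaluate_strategy(base_case_strategies()$NONE, econ_settings(),
#'                          england_life_table())
#' glance(res)
evaluate_strategy <- function(s, settings, lt) {
  trace <- run_cohort(s, settings, lt)
  T <- settings$horizon_years
  occ <- trace_matrix(trace)
  d <- discount_factor(seq_len(T), settings$discount_rate)
  costs <- qalys <- numeric(T)
  for (t in seq_len(T)) {
    row <- occ[t + 1, ]
    costs[t] <- d[t] * cycle_cost(row, trace$reop_flow[t + 1], s, t)
    qalys[t] <- d[t] * cycle_qaly(row, s, t)
  }
  per_cycle <- tibble(
    cycle = seq_len(T),
    discount = d,
    cost = costs,
    qaly = qalys
  )
  structure(
    list(
      strategy = s$name,
      total_cost = s$procedure_cost + sum(costs),
      total_qaly = sum(qalys),
      procedure_charge = s$procedure_cost,
      per_cycle = per_cycle,
      trace = trace,
      settings = settings,
      inputs = s
    ),
    class = "strategy_result"
  )
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result: %s> cost £%s, QALYs %.3f (%d-year horizon)\n",
              x$strategy, format(round(x$total_cost), big.mark = ","),
              x$total_qaly, x$settings$horizon_years))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname evaluate_strategy
#' @param x A `strategy_result`.
#' @param ... Unused.
#' @method tidy strategy_result
#' @export
tidy.strategy_result <- function(x, ...) {
  x$per_cycle
}

#' @rdname evaluate_strategy
#' @method glance strategy_result
#' @export
glance.strategy_result <- function(x, ...) {
  tibble(strategy = x$strategy,
         total_cost = x$total_cost,
         total_qaly = x$total_qaly,
         horizon_years = x$settings$horizon_years,
         discount_rate = x$settings$discount_rate)
}

#' Incremental comparison of two evaluated strategies
#'
#' Differences are intervention minus comparator. The ICER is
#' `delta_cost / delta_qaly`; when the intervention is both cheaper and
#' more effective it is reported as dominant (and dominated in the mirror
#' case) rather than as a ratio, and a zero QALY difference with a nonzero
#' cost difference yields an undefined ICER, not an error.
#'
#' @param intervention,comparator `strategy_result` objects evaluated under
#'   identical settings.
#' @return An object of class `cea_comparison` with fields `delta_cost`,
#'   `delta_qaly`, `icer` (NA when not meaningful) and `label`.
#' @export
#' @examples
#' lt <- england_life_table(); e <- econ_settings()
#' s <- base_case_strategies()
#' compare_strategies(evaluate_strategy(s$MRGFUS, e, lt),
#'                    evaluate_strategy(s$NONE, e, lt))
compare_strategies <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "strategy_result"),
            inherits(comparator, "strategy_result"))
  if (!identical(unclass(intervention$settings),
                 unclass(comparator$settings))) {
    abort("Both results must come from identical settings.",
          class = "tremorcea_validation_error")
  }
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$total_qaly - comparator$total_qaly
  if (dq == 0 && dc == 0) {
    icer <- 0; label <- "equivalent"
  } else if (dq == 0) {
    icer <- NA_real_; label <- "undefined ICER"
  } else if (dc < 0 && dq > 0) {
    icer <- NA_real_; label <- "intervention dominant"
  } else if (dc > 0 && dq < 0) {
    icer <- NA_real_; label <- "intervention dominated"
  } else {
    icer <- dc / dq; label <- "ICER"
  }
  structure(
    list(intervention = intervention$strategy,
         comparator = comparator$strategy,
         delta_cost = dc, delta_qaly = dq,
         icer = icer, label = label),
    class = "cea_comparison"
  )
}

#' @export
print.cea_comparison <- function(x, ...) {
  hdr <- sprintf("<cea_comparison: %s vs %s>", x$intervention, x$comparator)
  val <- if (x$label == "ICER") {
    sprintf("ICER £%s/QALY", format(round(x$icer), big.mark = ","))
  } else {
    x$label
  }
  cat(sprintf("%s dCost £%s, dQALY %.3f, %s\n", hdr,
              format(round(x$delta_cost), big.mark = ","), x$delta_qaly, val))
  invisible(x)
}

#' @rdname compare_strategies
#' @param x A `cea_comparison`.
#' @param ... Unused.
#' @method tidy cea_comparison
#' @export
tidy.cea_comparison <- function(x, ...) {
  tibble(intervention = x$intervention, comparator = x$comparator,
         delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
         icer = x$icer, label = x$label)
}

#' Net monetary benefit of a strategy at a willingness-to-pay
#'
#' @param result A `strategy_result`.
#' @param wtp Willingness to pay (GBP per QALY, >= 0).
#' @return `wtp * total_qaly - total_cost`, in GBP.
#' @export
net_monetary_benefit <- function(result, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * result$total_qaly - result$total_cost
}

#' Base-case results table
#'
#' Evaluates all three strategies and lays them out as a results table:
#' one row per strategy with its discounted cost and QALYs, and for each
#' comparator the difference to the intervention and the ICER or dominance
#' label.
#'
#' @param strategies Named list of `strategy_inputs` (defaults to the
#'   bundled base case). The first element is the intervention.
#' @param settings An [econ_settings()].
#' @param lt A `life_table` (defaults to the bundled synthetic table).
#' @return A tibble with columns `strategy`, `cost`, `delta_cost`, `qaly`,
#'   `delta_qaly`, `icer`, `label`.
#' @export
#' @examples
#' base_case_table()
base_case_table <- function(strategies = base_case_strategies(),
                            settings = econ_settings(),
                            lt = england_life_table()) {
  results <- purrr::map(strategies, evaluate_strategy,
                        settings = settings, lt = lt)
  intervention <- results[[1]]
  rows <- purrr::imap(results, function(res, nm) {
    if (nm == names(results)[1]) {
      tibble(strategy = nm, cost = res$total_cost,
             delta_cost = NA_real_, qaly = res$total_qaly,
             delta_qaly = NA_real_, icer = NA_real_, label = "")
    } else {
      cmp <- compare_strategies(intervention, res)
      tibble(strategy = nm, cost = res$total_cost,
             delta_cost = cmp$delta_cost, qaly = res$total_qaly,
             delta_qaly = cmp$delta_qaly, icer = cmp$icer,
             label = cmp$label)
    }
  })
  dplyr::bind_rows(rows)
}
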