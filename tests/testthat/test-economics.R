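test_that("discounting follows the end-of-cycle convention", {
  expect_equal(discount_factor(1:10, 0), rep(1, 10))
  expect_equal(discount_factor(1, 0.035), 1 / 1.035)
  expect_equal(discount_factor(5, 0.035), 0.8419732, tolerance = 1e-7)
  expect_equal(discount_factor(5, 0.035),
               Reduce(function(x, .) x / 1.035, 1:5, accumulate = FALSE,
                      init = 1),
               tolerance = 1e-12)
})

test_that("cycle cost combines medication, monitoring band and re-operations", {
  none <- base_strats$NONE
  alive_row <- c(BT = 1, MMT = 0, MT = 0, TR = 0, DEAD = 0)
  expect_equal(cycle_cost(alive_row, 0, none, 1), 744 + 169)
  dead_row <- c(BT = 0, MMT = 0, MT = 0, TR = 0, DEAD = 1)
  expect_equal(cycle_cost(dead_row, 0, none, 3), 0)
  # DBS year 3 with 90% alive: monitoring band 2+ applies
  row <- c(BT = 0, MMT = 0, MT = 0.9, TR = 0, DEAD = 0.1)
  expect_equal(cycle_cost(row, 0, base_strats$DBS, 3), 0.9 * (744 + 3172))
  # re-operation flow charges the procedure cost
  row_tr <- c(BT = 0, MMT = 0, MT = 0.98, TR = 0.02, DEAD = 0)
  expect_equal(cycle_cost(row_tr, 0.02, base_strats$MRGFUS, 2),
               1 * (744 + 0) + 0.02 * 16500)
})

test_that("cycle QALYs weight utilities with year-1 and onset-delay rules", {
  bt_row <- c(BT = 1, MMT = 0, MT = 0, TR = 0, DEAD = 0)
  expect_equal(cycle_qaly(bt_row, base_strats$NONE, 1), 0.69)
  dead_row <- c(BT = 0, MMT = 0, MT = 0, TR = 0, DEAD = 1)
  expect_equal(cycle_qaly(dead_row, base_strats$MRGFUS, 1), 0)
  mt_row <- c(BT = 0, MMT = 0, MT = 1, TR = 0, DEAD = 0)
  # DBS benefit starts at 3 months: first-year MT utility blends 25%
  # baseline with 75% treated
  expect_equal(cycle_qaly(mt_row, base_strats$DBS, 1),
               0.25 * 0.69 + 0.75 * 0.91)
  expect_equal(cycle_qaly(mt_row, base_strats$DBS, 2), 0.91)
  expect_equal(cycle_qaly(mt_row, base_strats$MRGFUS, 1), 0.91)
  expect_equal(cycle_qaly(mt_row, base_strats$MRGFUS, 2), 0.90)
})

test_that("strategy totals match closed forms in the degenerate limit", {
  lt0 <- zero_mortality_lt()
  st <- econ_settings(discount_rate = 0)
  res <- evaluate_strategy(base_strats$NONE, st, lt0)
  expect_equal(res$total_qaly, 5 * 0.69)
  expect_equal(res$total_cost, 5 * 913)
  expect_equal(sum(res$per_cycle$cost), res$total_cost)
  expect_equal(sum(res$per_cycle$qaly), res$total_qaly)
  # discounting strictly shrinks positive accrual streams
  disc <- evaluate_strategy(base_strats$NONE, econ_settings(), lt0)
  expect_lt(disc$total_cost, res$total_cost)
  expect_lt(disc$total_qaly, res$total_qaly)
  g <- glance(res)
  expect_equal(g$total_qaly, res$total_qaly)
  expect_equal(nrow(tidy(res)), 5)
})

test_that("comparisons compute deltas, ICERs and dominance labels", {
  lt0 <- zero_mortality_lt()
  st <- econ_settings()
  r_none <- evaluate_strategy(base_strats$NONE, st, lt0)
  same <- compare_strategies(r_none, r_none)
  expect_equal(same$delta_cost, 0)
  expect_equal(same$delta_qaly, 0)
  expect_equal(same$label, "equivalent")
  # published deltas, divided by hand: 16,044 / 0.77
  expect_equal(16044 / 0.77, 20836.36, tolerance = 1e-6)
  # results from different settings refuse to compare
  r_other <- evaluate_strategy(base_strats$NONE,
                               econ_settings(horizon_years = 4), lt0)
  expect_error(compare_strategies(r_none, r_other),
               class = "tremorcea_validation_error")
})

test_that("dominance classification matches sign inspection on random pairs", {
  set.seed(7)
  n <- 10000
  dc <- stats::runif(n, -5e4, 5e4)
  dq <- stats::runif(n, -1, 1)
  mk <- function(cost, qaly) {
    structure(list(strategy = "X", total_cost = cost, total_qaly = qaly,
                   settings = base_settings), class = "strategy_result")
  }
  ref <- mk(0, 0)
  labels <- vapply(seq_len(n), function(i) {
    compare_strategies(mk(dc[i], dq[i]), ref)$label
  }, character(1))
  expect_equal(labels == "intervention dominant", dc < 0 & dq > 0)
  expect_equal(labels == "intervention dominated", dc > 0 & dq < 0)
  icers <- vapply(seq_len(n), function(i) {
    cmp <- compare_strategies(mk(dc[i], dq[i]), ref)
    if (cmp$label == "ICER") cmp$icer else NA_real_
  }, numeric(1))
  same_sign <- (dc >= 0) == (dq > 0)
  expect_equal(!is.na(icers), same_sign & dq != 0)
  expect_equal(icers[!is.na(icers)], (dc / dq)[!is.na(icers)])
})

test_that("ICER is antisymmetric under swapping the arms", {
  lt <- base_lt
  r1 <- evaluate_strategy(base_strats$MRGFUS, base_settings, lt)
  r2 <- evaluate_strategy(base_strats$NONE, base_settings, lt)
  fwd <- compare_strategies(r1, r2)
  rev <- compare_strategies(r2, r1)
  expect_equal(rev$delta_cost, -fwd$delta_cost)
  expect_equal(rev$delta_qaly, -fwd$delta_qaly)
  expect_equal(rev$icer, fwd$icer)
})

test_that("net monetary benefit is the standard linear decision rule", {
  mk <- function(cost, qaly) {
    structure(list(total_cost = cost, total_qaly = qaly),
              class = "strategy_result")
  }
  expect_equal(net_monetary_benefit(mk(20000, 2), 0), -20000)
  expect_equal(net_monetary_benefit(mk(20000, 2), 30000), 40000)
})
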