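test_that("Wilson interval matches the score formula and its oracle", {
  # boundaries forced by the formula
  expect_equal(unname(wilson_interval(0, 10)["low"]), 0)
  expect_equal(unname(wilson_interval(10, 10)["high"]), 1)
  # 5/10 at 95%, frozen from a by-hand evaluation at z = 1.959964
  ci <- wilson_interval(5, 10)
  expect_equal(unname(ci), c(0.2365931, 0.7634069), tolerance = 1e-6)
  # independent oracle: the score interval inside stats::prop.test
  pt <- suppressWarnings(stats::prop.test(5, 10, correct = FALSE))$conf.int
  expect_equal(unname(ci), as.numeric(pt), tolerance = 1e-9)
  pt89 <- suppressWarnings(stats::prop.test(8, 9,
                                            correct = FALSE))$conf.int
  expect_equal(unname(wilson_interval(8, 9)), as.numeric(pt89),
               tolerance = 1e-9)
  # always contains the point estimate and [0,1]; collapses as n grows
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(1:500, 1)
    k <- sample(0:n, 1)
    ci <- wilson_interval(k, n)
    expect_lte(ci["low"], k / n)
    expect_gte(ci["high"], k / n)
    expect_gte(ci["low"], 0)
    expect_lte(ci["high"], 1)
  }
  big <- wilson_interval(300000, 1e6)
  expect_lt(big["high"] - 0.3, 1e-3)
  expect_lt(0.3 - big["low"], 1e-3)
  expect_error(wilson_interval(5, 0), class = "tremorcea_validation_error")
})

test_that("parameter paths read and write coherently", {
  expect_equal(get_param(base_strats, "DBS.recurrence_annual"), 0.039)
  expect_equal(get_param(base_strats, "shared.medication_annual"), 744)
  expect_equal(get_param(base_strats, "DBS.monitoring_annual.2"), 3172)
  expect_error(get_param(base_strats, "DBS.nonexistent"),
               class = "tremorcea_config_error")
  expect_error(set_param(base_strats, "XXX.u_bt", 0.5),
               class = "tremorcea_config_error")

  s2 <- set_param(base_strats, "shared.medication_annual", 900)
  expect_equal(s2$MRGFUS$medication_annual, 900)
  expect_equal(s2$NONE$medication_annual, 900)
  # outcome proportion rescales its complement and stays a simplex
  s3 <- set_param(base_strats, "shared.p_marked", 0.8)
  expect_equal(s3$MRGFUS$p_marked, 0.8)
  expect_equal(s3$MRGFUS$p_mild + s3$MRGFUS$p_none, 0.2)
  expect_equal(s3$MRGFUS$p_mild / s3$MRGFUS$p_none, 0.100 / 0.011,
               tolerance = 1e-9)
  expect_equal(s3$NONE$p_none, 1) # NONE untouched by outcome paths
  # baseline utility drags the recurrence-state utility with it
  s4 <- set_param(base_strats, "shared.u_bt", 0.5)
  expect_equal(s4$DBS$u_tr, 0.5)
})

test_that("ranges default to +/-20% with domain clipping and CI overrides", {
  rg <- build_ranges(base_strats)
  med <- rg[rg$parameter == "shared.medication_annual", ]
  expect_equal(med$low, 595.2)
  expect_equal(med$high, 892.8)
  u <- rg[rg$parameter == "DBS.u_mt_y2plus", ]
  expect_equal(u$low, 0.728)
  expect_equal(u$high, 1) # 1.092 clipped to the utility domain
  ci <- wilson_interval(8, 9)
  rg2 <- build_ranges(base_strats,
                      overrides = tibble::tibble(
                        parameter = "shared.p_marked",
                        low = ci["low"], high = ci["high"]))
  pm <- rg2[rg2$parameter == "shared.p_marked", ]
  expect_equal(pm$source, "ci95")
  expect_equal(c(pm$low, pm$high), unname(ci))
})

test_that("one-way DSA filters null effects and orders by span", {
  rg <- build_ranges(base_strats)
  keep <- c("MRGFUS.procedure_cost", "MRGFUS.monitoring_annual.6",
            "shared.u_bt", "MRGFUS.ae_costs.infection")
  dsa <- run_dsa(base_strats, base_settings, base_lt,
                 ranges = rg[rg$parameter %in% keep, ], filter = 0)
  vs_none <- dsa[dsa$comparison == "MRGFUS_vs_NONE", ]
  # year-6 monitoring has no effect under a 5-year horizon; nor do
  # adverse-event costs, which carry no base-case flow
  for (p in c("MRGFUS.monitoring_annual.6", "MRGFUS.ae_costs.infection")) {
    row <- vs_none[vs_none$parameter == p, ]
    expect_equal(row$icer_low, row$icer_base, tolerance = 1e-12)
    expect_equal(row$icer_high, row$icer_base, tolerance = 1e-12)
  }
  # procedure cost moves the ICER monotonically and brackets the base
  pc <- vs_none[vs_none$parameter == "MRGFUS.procedure_cost", ]
  expect_lt(pc$icer_low, pc$icer_base)
  expect_gt(pc$icer_high, pc$icer_base)
  # the >5% filter drops the null rows
  dsa5 <- run_dsa(base_strats, base_settings, base_lt,
                  ranges = rg[rg$parameter %in% keep, ], filter = 0.05)
  expect_false("MRGFUS.monitoring_annual.6" %in%
                 dsa5$parameter[dsa5$comparison == "MRGFUS_vs_NONE"])
  # ordered by descending span within comparison
  expect_false(is.unsorted(rev(vs_none$span)))
})

test_that("PSA sampling honours moments, coupling and degeneracy", {
  spec <- build_psa_spec(base_strats)
  # degenerate spec reproduces the base values exactly
  dspec <- degenerate_psa_spec(spec)
  set.seed(1)
  s_d <- sample_inputs(base_strats, dspec)
  expect_equal(s_d, base_strats)
  # gamma method-of-moments identities: shape*scale = mean,
  # shape*scale^2 = var
  m <- 744; s <- 148.8
  shape <- (m / s)^2; scale <- s^2 / m
  expect_equal(shape * scale, m)
  expect_equal(shape * scale^2, s^2)
  # sampled means approximate the base values (coupling keeps shared
  # parameters identical across strategies within a draw)
  set.seed(42)
  draws <- replicate(400, {
    smp <- sample_inputs(base_strats, spec)
    expect_identical(smp$MRGFUS$medication_annual,
                     smp$DBS$medication_annual)
    expect_identical(smp$MRGFUS$p_marked, smp$DBS$p_marked)
    c(u_bt = smp$NONE$u_bt, med = smp$NONE$medication_annual,
      pm = smp$MRGFUS$p_marked)
  })
  # 3-standard-error bands around the base means
  se <- function(x) stats::sd(x) / sqrt(ncol(draws))
  expect_lt(abs(mean(draws["u_bt", ]) - 0.69), 3 * se(draws["u_bt", ]) + 1e-9)
  expect_lt(abs(mean(draws["med", ]) - 744), 3 * se(draws["med", ]) + 1e-9)
  expect_lt(abs(mean(draws["pm", ]) - 0.889), 3 * se(draws["pm", ]) + 1e-9)
  # infeasible beta moments are refused
  bad <- spec[spec$parameter == "shared.u_bt", ]
  bad$sd <- 0.9
  expect_error(sample_inputs(base_strats, bad),
               class = "tremorcea_validation_error")
})

test_that("PSA runs are seed-deterministic and collapse when degenerate", {
  spec <- build_psa_spec(base_strats)
  p1 <- run_psa(base_strats, base_settings, base_lt, spec, n = 20, seed = 9)
  p2 <- run_psa(base_strats, base_settings, base_lt, spec, n = 20, seed = 9)
  expect_identical(p1$draws, p2$draws)
  p3 <- run_psa(base_strats, base_settings, base_lt, spec, n = 20, seed = 10)
  expect_false(identical(p3$draws, p1$draws))
  # degenerate spec: every iteration equals the deterministic deltas
  pd <- run_psa(base_strats, base_settings, base_lt,
                degenerate_psa_spec(spec), n = 10, seed = 1)
  det_none <- compare_strategies(
    evaluate_strategy(base_strats$MRGFUS, base_settings, base_lt),
    evaluate_strategy(base_strats$NONE, base_settings, base_lt))
  vs_none <- pd$draws[pd$draws$comparison == "MRGFUS_vs_NONE", ]
  expect_equal(nrow(vs_none), 10)
  expect_equal(unique(vs_none$delta_cost), det_none$delta_cost)
  expect_equal(unique(vs_none$delta_qaly), det_none$delta_qaly)
})

test_that("acceptability curves recount net-benefit signs", {
  spec <- build_psa_spec(base_strats)
  pd <- run_psa(base_strats, base_settings, base_lt,
                degenerate_psa_spec(spec), n = 5, seed = 1)
  det <- pd$draws[pd$draws$comparison == "MRGFUS_vs_NONE", ][1, ]
  thr <- det$delta_cost / det$delta_qaly
  cc <- ceac(pd, wtp_grid = c(floor(thr) - 1000, ceiling(thr) + 1000))
  vs_none <- cc[cc$comparison == "MRGFUS_vs_NONE", ]
  # step function: 0 below the deterministic ICER, 1 above
  expect_equal(vs_none$p_cost_effective, c(0, 1))
  # wtp = 0 counts cost-saving draws only
  p <- run_psa(base_strats, base_settings, base_lt, spec, n = 50, seed = 3)
  c0 <- ceac(p, wtp_grid = c(0, 30000))
  d_none <- p$draws[p$draws$comparison == "MRGFUS_vs_NONE", ]
  expect_equal(c0$p_cost_effective[c0$comparison == "MRGFUS_vs_NONE" &
                                     c0$wtp == 0],
               mean(d_none$delta_cost < 0))
  # bounded and monotone when QALY gains are (near) sure
  cc_all <- ceac(p, wtp_grid = seq(0, 100000, 5000))
  expect_true(all(cc_all$p_cost_effective >= 0 &
                    cc_all$p_cost_effective <= 1))
  if (mean(d_none$delta_qaly > 0) >= 0.99) {
    curve <- cc_all$p_cost_effective[cc_all$comparison == "MRGFUS_vs_NONE"]
    expect_false(is.unsorted(curve))
  }
})
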