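test_that("bundled base case carries every published input value verbatim", {
  for (src in list(base_strats, load_config(base_case_config())$strategies)) {
    fus <- src$MRGFUS; dbs <- src$DBS; none <- src$NONE

    expect_equal(fus$p_marked, 0.889)
    expect_equal(fus$p_mild, 0.100)
    expect_equal(fus$p_none, 0.011)
    expect_equal(fus$waning_annual, 0.092)
    expect_equal(dbs$waning_annual, 0.077)
    expect_equal(fus$recurrence_annual, 0.01)
    expect_equal(dbs$recurrence_annual, 0.039)
    expect_equal(fus$p_reop_given_recurrence, 0.05)

    expect_equal(dbs$procedure_cost, 47627)
    expect_equal(fus$procedure_cost, 16500)
    expect_equal(fus$medication_annual, 744)
    expect_equal(monitoring_cost(none, 1), 169)
    expect_equal(monitoring_cost(dbs, 2), 3172)
    expect_equal(monitoring_cost(fus, 6), 169)
    expect_equal(unname(fus$ae_costs["infection"]), 657)
    expect_equal(unname(fus$ae_costs["intracranial_haemorrhage"]), 20545)
    expect_equal(unname(fus$ae_costs["lead_fracture_or_migration"]), 14777)
    expect_equal(unname(fus$ae_costs["gait_disturbance"]), 0)
    expect_equal(unname(fus$ae_costs["speech_problem"]), 42)

    expect_equal(fus$u_bt, 0.69)
    expect_equal(fus$u_mt_y1, 0.91)
    expect_equal(fus$u_mmt_y1, 0.80)
    expect_equal(fus$u_mt_y2plus, 0.90)
    expect_equal(fus$u_mmt_y2plus, 0.79)
    expect_equal(dbs$u_mt_y1, 0.91)
    expect_equal(dbs$u_mt_y2plus, 0.91)
    expect_equal(dbs$u_mmt_y1, 0.80)
    expect_equal(dbs$u_mmt_y2plus, 0.76)
    # recurrence-state utility equals baseline in the base case
    expect_equal(fus$u_tr, fus$u_bt)
    expect_equal(dbs$u_tr, dbs$u_bt)
  }
  st <- load_config(base_case_config())$settings
  expect_equal(st$discount_rate, 0.035)
  expect_equal(st$horizon_years, 5L)
  expect_equal(st$start_age, 70L)
  expect_equal(st$population_size, 1415L)
})

test_that("strategy input invariants are enforced with named errors", {
  good <- base_strats$MRGFUS
  expect_error(
    strategy_inputs(name = "MRGFUS", p_marked = 0.5, p_mild = 0.5,
                    p_none = 0.1, u_bt = 0.69),
    "sum to 1", class = "tremorcea_validation_error")
  expect_error(
    strategy_inputs(name = "MRGFUS", p_marked = 1.2, p_mild = -0.1,
                    p_none = -0.1, u_bt = 0.69),
    "p_marked", class = "tremorcea_validation_error")
  expect_error(
    strategy_inputs(name = "NONE", p_marked = 0, p_mild = 0, p_none = 1,
                    procedure_cost = 100, u_bt = 0.69),
    "procedure_cost", class = "tremorcea_validation_error")
  expect_error(
    strategy_inputs(name = "MRGFUS", p_marked = 0.9, p_mild = 0.1,
                    p_none = 0, waning_annual = 0.6,
                    recurrence_annual = 0.6, u_bt = 0.69),
    "competing-risk", class = "tremorcea_validation_error")
  expect_error(
    strategy_inputs(name = "MRGFUS", p_marked = 0.9, p_mild = 0.1,
                    p_none = 0, u_bt = 1.2),
    "u_bt", class = "tremorcea_validation_error")
  # monitoring bands must start at year 1
  expect_error(
    strategy_inputs(name = "MRGFUS", p_marked = 0.9, p_mild = 0.1,
                    p_none = 0, u_bt = 0.69,
                    monitoring_annual = monitoring_bands(5, year_from = 2)),
    "year_from", class = "tremorcea_validation_error")
  expect_silent(validate_strategy_inputs(good))
})

test_that("config loader applies defaults, names missing keys, round-trips", {
  cfg <- load_config(base_case_config())
  # omitted wtp grid falls back to the standard 0..100,000 by 1,000
  tmp <- tempfile(fileext = ".yaml")
  doc <- yaml::read_yaml(base_case_config())
  doc$settings$wtp_grid <- NULL
  yaml::write_yaml(doc, tmp)
  expect_equal(load_config(tmp)$settings$wtp_grid, seq(0, 100000, 1000))

  doc$strategies$MRGFUS$p_marked <- NULL
  yaml::write_yaml(doc, tmp)
  expect_error(load_config(tmp), "p_marked",
               class = "tremorcea_schema_error")

  # round trip preserves every parameter value
  out <- tempfile(fileext = ".yaml")
  write_config(cfg, out)
  cfg2 <- load_config(out)
  for (nm in names(cfg$strategies)) {
    expect_equal(cfg2$strategies[[nm]], cfg$strategies[[nm]])
  }
  expect_equal(unclass(cfg2$settings), unclass(cfg$settings))
})

test_that("econ settings validate their domains", {
  expect_error(econ_settings(discount_rate = -0.01),
               class = "tremorcea_validation_error")
  expect_error(econ_settings(horizon_years = 0),
               class = "tremorcea_validation_error")
  expect_error(econ_settings(wtp_grid = c(0, 0, 1000)),
               class = "tremorcea_validation_error")
  expect_error(econ_settings(male_fraction = 1.5),
               class = "tremorcea_validation_error")
})

test_that("blended mortality weights the sex-specific columns", {
  lt <- validate_life_table(tibble::tibble(age = 69:71,
                                           q_male = c(0.028, 0.03, 0.032),
                                           q_female = c(0.018, 0.02, 0.022)))
  expect_equal(blended_mortality(lt, 70, 1), 0.03)
  expect_equal(blended_mortality(lt, 70, 0.5), 0.025)
  expect_error(blended_mortality(lt, 60, 0.5),
               class = "tremorcea_range_error")
  # bundled fixture at age 70, hand-weighted from its two cells
  expect_equal(blended_mortality(base_lt, 70, 0.46),
               0.46 * 0.020686 + 0.54 * 0.013679, tolerance = 1e-12)
  expect_equal(blended_mortality(base_lt, 70, 0.46), 0.01690222,
               tolerance = 1e-7)
})

test_that("life table validation rejects gaps and out-of-range rates", {
  expect_error(validate_life_table(tibble::tibble(age = c(40, 42),
                                                  q_male = 0, q_female = 0)),
               "contiguous", class = "tremorcea_validation_error")
  expect_error(validate_life_table(tibble::tibble(age = 40:41,
                                                  q_male = c(0.1, 1.2),
                                                  q_female = 0)),
               class = "tremorcea_validation_error")
  expect_error(read_life_table(tempfile()),
               class = "tremorcea_config_error")
})
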