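#' Load a model configuration file
#'
#' One YAML (or JSON) document holds everything a run needs: a `strategies`
#' section (one block per strategy, flat fields matching
#' [strategy_inputs()], with `monitoring_annual` as a `year_from: amount`
#' map), a `settings` section ([econ_settings()] fields; omitted fields get
#' their defaults, e.g. the 0..100,000-by-1,000 willingness-to-pay grid), a
#' `life_table` entry (`bundled` or a CSV path resolved relative to the
#' config file), and optional `psa` / `dsa` sections. The bundled base case
#' lives at `system.file("extdata", "base_case.yaml", package =
#' "tremorcea")`.
#'
#' @param path Path to the config file (`.yaml`, `.yml` or `.json`).
#' @return A list with elements `strategies` (validated
#'   `strategy_inputs`), `settings` (`econ_settings`), `life_table`
#'   (`life_table`), `psa`, `dsa`.
#' @export
#' @examples
#' cfg <- load_config(system.file("extdata", "base_case.yaml",
#'                                package = "tremorcea"))
#' cfg$strategies$MRGFUS$p_marked
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "tremorcea_config_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need_key <- function(obj, key, where) {
    if (is.null(obj[[key]])) {
      abort(sprintf("Config schema error: missing required key `%s` in %s.",
                    key, where),
            class = "tremorcea_schema_error")
    }
    obj[[key]]
  }
  strat_raw <- need_key(raw, "strategies", "document root")

  strategies <- purrr::imap(strat_raw, function(fields, nm) {
    for (k in c("p_marked", "p_mild", "p_none", "u_bt")) {
      need_key(fields, k, sprintf("strategies.%s", nm))
    }
    mon <- fields$monitoring_annual
    fields$monitoring_annual <- if (is.null(mon)) {
      monitoring_bands(0)
    } else {
      monitoring_bands(unlist(mon, use.names = FALSE),
                       year_from = as.integer(names(mon)))
    }
    fields$ae_costs <- unlist(fields$ae_costs) %||% c()
    do.call(strategy_inputs, c(list(name = nm), fields))
  })

  st <- raw$settings %||% list()
  if (!is.null(st$wtp_grid) && is.list(st$wtp_grid)) {
    st$wtp_grid <- seq(st$wtp_grid$from, st$wtp_grid$to, by = st$wtp_grid$by)
  }
  settings <- do.call(econ_settings, st)

  lt_entry <- raw$life_table %||% "bundled"
  life_table <- if (identical(lt_entry, "bundled")) {
    england_life_table()
  } else {
    lt_path <- if (file.exists(lt_entry)) lt_entry else {
      file.path(dirname(path), lt_entry)
    }
    read_life_table(lt_path)
  }
  floor_needed <- settings$start_age
  ceil_needed <- settings$start_age + settings$horizon_years - 1
  if (min(life_table$age) > floor_needed ||
      max(life_table$age) < ceil_needed) {
    abort(sprintf(
      "Life table must cover ages %d..%d for this start age and horizon.",
      floor_needed, ceil_needed), class = "tremorcea_validation_error")
  }

  list(strategies = strategies,
       settings = settings,
       life_table = life_table,
       psa = modifyList(list(n_iterations = 1000L, sd_fraction = 0.2,
                             seed = 42L), raw$psa %||% list()),
       dsa = modifyList(list(spread = 0.2, filter = 0.05),
                        raw$dsa %||% list()))
}

#' Write a model configuration back to YAML
#'
#' Inverse of [load_config()] up to formatting: reloading a written config
#' reproduces identical parameter values.
#'
#' @param cfg A config list as returned by [load_config()].
#' @param path Output path (`.yaml`).
#' @param life_table_entry What to record for the life table: `"bundled"`
#'   or a path. A path is written as given; the table itself is written
#'   next to the config when `write_life_table` is `TRUE`.
#' @param write_life_table Write `cfg$life_table` as CSV alongside.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path, life_table_entry = "bundled",
                         write_life_table = !identical(life_table_entry,
                                                       "bundled")) {
  strat_out <- purrr::map(cfg$strategies, function(s) {
    mon <- as.list(setNames(s$monitoring_annual$amount,
                            s$monitoring_annual$year_from))
    out <- s[c("p_marked", "p_mild", "p_none", "waning_annual",
               "recurrence_annual", "p_reop_given_recurrence",
               "onset_delay_fraction", "procedure_cost", "bundle_years",
               "medication_annual", "u_bt", "u_tr", "u_mt_y1",
               "u_mt_y2plus", "u_mmt_y1", "u_mmt_y2plus")]
    out$monitoring_annual <- mon
    if (length(s$ae_costs)) out$ae_costs <- as.list(s$ae_costs)
    out
  })
  st <- cfg$settings
  doc <- list(
    settings = list(discount_rate = st$discount_rate,
                    horizon_years = st$horizon_years,
                    start_age = st$start_age,
                    male_fraction = st$male_fraction,
                    wtp_grid = as.numeric(st$wtp_grid),
                    population_size = st$population_size),
    life_table = life_table_entry,
    strategies = strat_out,
    psa = cfg$psa,
    dsa = cfg$dsa
  )
  yaml::write_yaml(doc, path, precision = 15)
  if (write_life_table) {
    write.csv(as.data.frame(cfg$life_table),
              file.path(dirname(path), life_table_entry),
              row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Path to the bundled base-case config
#'
#' @return File path of the base-case YAML shipped with the package.
#' @export
base_case_config <- function() {
  system.file("extdata", "base_case.yaml", package = "tremorcea",
              mustWork = TRUE)
}
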