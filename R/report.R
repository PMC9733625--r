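# Report writers and the command-line front end. Machine CSVs carry full
# precision with dot decimals regardless of locale; a manifest records
# enough to reproduce every number.

write_csv_plain <- function(df, path) {
  old <- options(OutDec = ".", scipen = 15)
  on.exit(options(old))
  write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  path
}

#' Write a run manifest
#'
#' Records the config hash, seed, package version, timestamp, scenario
#' spec and output paths of a report run as JSON. Re-running with the same
#' config and seed reproduces the numeric outputs byte for byte; only the
#' timestamp differs.
#'
#' @param out_dir Output directory.
#' @param config_path Config file the run used.
#' @param seed Seed used (NA for deterministic runs).
#' @param scenario Free-form scenario descriptor list.
#' @param outputs Character vector of files the run wrote.
#' @return Path of the manifest file, invisibly.
#' @export
write_manifest <- function(out_dir, config_path, seed = NA,
                           scenario = list(), outputs = character()) {
  manifest <- list(
    config = config_path,
    config_md5 = unname(tools::md5sum(config_path)),
    seed = seed,
    package_version = as.character(utils::packageVersion("tremorcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    scenario = scenario,
    outputs = outputs
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Base-case report: results table, traces, manifest
#'
#' @param config_path Path to a model config ([load_config()] schema).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the named vector of files written.
#' @export
#' @examples
#' \donttest{
#' run_base_case_report(base_case_config(), tempfile())
#' }
run_base_case_report <- function(config_path, out_dir) {
  cfg <- load_config(config_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(results = file.path(out_dir, "results.csv"))
  write_csv_plain(base_case_table(cfg$strategies, cfg$settings,
                                  cfg$life_table), files["results"])
  for (nm in names(cfg$strategies)) {
    f <- file.path(out_dir, sprintf("trace_%s.csv", nm))
    write_csv_plain(run_cohort(cfg$strategies[[nm]], cfg$settings,
                               cfg$life_table), f)
    files[paste0("trace_", nm)] <- f
  }
  write_manifest(out_dir, config_path, scenario = list(kind = "base_case"),
                 outputs = unname(files))
  invisible(files)
}

#' One-way sensitivity report (tornado CSV)
#'
#' @inheritParams run_base_case_report
#' @param filter Minimum relative ICER change to report.
#' @return Invisibly, the files written.
#' @export
run_dsa_report <- function(config_path, out_dir, filter = NULL) {
  cfg <- load_config(config_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dsa <- run_dsa(cfg$strategies, cfg$settings, cfg$life_table,
                 ranges = build_ranges(cfg$strategies,
                                       spread = cfg$dsa$spread),
                 filter = filter %||% cfg$dsa$filter)
  f <- file.path(out_dir, "dsa.csv")
  write_csv_plain(dsa, f)
  write_manifest(out_dir, config_path, scenario = list(kind = "dsa"),
                 outputs = f)
  invisible(c(dsa = f))
}

#' Probabilistic sensitivity report (draws + acceptability curve)
#'
#' @inheritParams run_base_case_report
#' @param iterations,seed Override the config's `psa` section.
#' @return Invisibly, the files written.
#' @export
run_psa_report <- function(config_path, out_dir, iterations = NULL,
                           seed = NULL) {
  cfg <- load_config(config_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- iterations %||% cfg$psa$n_iterations
  sd <- seed %||% cfg$psa$seed
  psa <- run_psa(cfg$strategies, cfg$settings, cfg$life_table,
                 spec = build_psa_spec(cfg$strategies,
                                       sd_fraction = cfg$psa$sd_fraction),
                 n = n, seed = sd)
  files <- c(psa = file.path(out_dir, "psa_draws.csv"),
             ceac = file.path(out_dir, "ceac.csv"))
  write_csv_plain(psa$draws, files["psa"])
  write_csv_plain(ceac(psa, cfg$settings$wtp_grid), files["ceac"])
  write_manifest(out_dir, config_path, seed = sd,
                 scenario = list(kind = "psa", iterations = n),
                 outputs = unname(files))
  invisible(files)
}

#' Scenario report
#'
#' @inheritParams run_base_case_report
#' @param name One of `"start_age"`, `"horizon"`, `"current_care"`,
#'   `"no_discount"`, `"alternative_inputs"`.
#' @param value Scenario value: ages, horizons, eligibility fractions, or
#'   (for `alternative_inputs`) a config path. `NULL` uses the scenario's
#'   standard grid.
#' @return Invisibly, the files written.
#' @export
run_scenario_report <- function(config_path, out_dir, name, value = NULL) {
  valid <- c("start_age", "horizon", "current_care", "no_discount",
             "alternative_inputs")
  if (!(name %in% valid)) {
    abort(sprintf("Unknown scenario `%s`; valid names: %s", name,
                  paste(valid, collapse = ", ")),
          class = "tremorcea_config_error")
  }
  cfg <- load_config(config_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- switch(
    name,
    start_age = run_age_scenario(value %||% c(40, 50, 60, 70),
                                 cfg$strategies, cfg$settings,
                                 cfg$life_table),
    horizon = run_horizon_scenario(value %||% c(1, 5, 10),
                                   cfg$strategies, cfg$settings,
                                   cfg$life_table),
    current_care = run_current_care_blend(value %||% seq(0, 1, by = 0.1),
                                          cfg$strategies, cfg$settings,
                                          cfg$life_table),
    no_discount = run_no_discount_scenario(cfg$strategies, cfg$settings,
                                           cfg$life_table),
    alternative_inputs = run_alternative_inputs(value, psa_n = 0)$base_table
  )
  f <- file.path(out_dir, sprintf("scenario_%s.csv", name))
  write_csv_plain(tab, f)
  write_manifest(out_dir, config_path,
                 scenario = list(kind = name, value = value), outputs = f)
  invisible(c(scenario = f))
}

#' Synthetic-input report: emit generated inputs in loadable formats
#'
#' Writes a random valid strategy set as YAML and a Gompertz life table as
#' CSV, in exactly the formats [load_config()] and [read_life_table()]
#' consume.
#'
#' @param out_dir Output directory.
#' @param seed RNG seed.
#' @return Invisibly, the files written.
#' @export
run_synth_report <- function(out_dir, seed = 42) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  strategies <- random_strategy_set()
  lt <- gompertz_life_table(1.5e-5, 0.1, 40, 100,
                            a_female = 0.7e-5, b_female = 0.105)
  cfg <- list(strategies = strategies, settings = econ_settings(),
              life_table = lt,
              psa = list(n_iterations = 1000L, sd_fraction = 0.2,
                         seed = seed),
              dsa = list(spread = 0.2, filter = 0.05))
  f_cfg <- file.path(out_dir, "synthetic_config.yaml")
  write_config(cfg, f_cfg, life_table_entry = "synthetic_life_table.csv")
  files <- c(config = f_cfg,
             life_table = file.path(out_dir, "synthetic_life_table.csv"))
  invisible(files)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `run`, `dsa`, `psa`, `scenario`, `synth`; the
#' shipped shim (`system.file("cli", "tremorcea", package = "tremorcea")`)
#' forwards `commandArgs(TRUE)` here.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
tremorcea_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: tremorcea <command> [options]",
    "  run      --config P --out DIR",
    "  dsa      --config P --out DIR [--filter F]",
    "  psa      --config P --out DIR [--iterations N] [--seed S]",
    "  scenario --config P --out DIR --name X [--value V[,V...]]",
    "  synth    --out DIR [--seed S]",
    sep = "\n")
  opt <- function(flag, default = NULL) {
    i <- match(flag, args)
    if (is.na(i) || i == length(args)) default else args[i + 1]
  }
  num <- function(x) if (is.null(x)) NULL else as.numeric(strsplit(x, ",")[[1]])
  cmd <- if (length(args)) args[1] else ""
  status <- tryCatch({
    switch(cmd,
      run = run_base_case_report(opt("--config", base_case_config()),
                                 opt("--out", ".")),
      dsa = run_dsa_report(opt("--config", base_case_config()),
                           opt("--out", "."), filter = num(opt("--filter"))),
      psa = run_psa_report(opt("--config", base_case_config()),
                           opt("--out", "."),
                           iterations = num(opt("--iterations")),
                           seed = num(opt("--seed"))),
      scenario = {
        name <- opt("--name")
        if (is.null(name)) {
          abort("scenario requires --name", class = "tremorcea_config_error")
        }
        value <- if (identical(name, "alternative_inputs")) {
          opt("--value")
        } else {
          num(opt("--value"))
        }
        run_scenario_report(opt("--config", base_case_config()),
                            opt("--out", "."), name = name, value = value)
      },
      synth = run_synth_report(opt("--out", "."),
                               seed = num(opt("--seed")) %||% 42),
      {
        message(usage)
        return(invisible(if (cmd %in% c("", "--help", "-h")) 0L else 2L))
      })
    0L
  }, error = function(e) {
    message(conditionMessage(e))
    1L
  })
  invisible(status)
}
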