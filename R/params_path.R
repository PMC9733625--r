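# Parameter addressing for sensitivity analyses.
#
# A parameter path is "<scope>.<field>" where scope is a strategy name or
# "shared" (applied to every strategy that carries the field: medication,
# baseline utility, re-operation probability, and the procedure outcome
# proportions). Map-valued fields take a third component:
# "DBS.monitoring_annual.2" is the band starting at year 2,
# "MRGFUS.ae_costs.infection" a named adverse-event cost.

.shared_fields <- c("p_marked", "p_mild", "p_none", "outcome_split",
                    "p_reop_given_recurrence", "medication_annual", "u_bt")

split_path <- function(path) strsplit(path, ".", fixed = TRUE)[[1]]

#' Read one model parameter by path
#'
#' @param strategies Named list of `strategy_inputs`.
#' @param path Parameter path such as `"DBS.recurrence_annual"`,
#'   `"shared.u_bt"`, `"MRGFUS.monitoring_annual.6"`. Shared paths read the
#'   value from the first strategy that carries it.
#' @return The numeric value.
#' @export
get_param <- function(strategies, path) {
  p <- split_path(path)
  scope <- p[1]
  targets <- if (scope == "shared") strategies else strategies[scope]
  if (any(vapply(targets, is.null, logical(1)))) {
    abort(sprintf("Unknown strategy in parameter path: %s", path),
          class = "tremorcea_config_error")
  }
  for (s in targets) {
    v <- read_field(s, p[-1])
    if (!is.null(v)) return(v)
  }
  abort(sprintf("Parameter path not found: %s", path),
        class = "tremorcea_config_error")
}

.procedure_only_fields <- c("p_marked", "p_mild", "p_none", "outcome_split",
                            "waning_annual", "recurrence_annual",
                            "p_reop_given_recurrence",
                            "onset_delay_fraction", "procedure_cost")

read_field <- function(s, fp) {
  f <- fp[1]
  if (s$name == "NONE" && f %in% .procedure_only_fields) return(NULL)
  if (f == "outcome_split") {
    return(s$p_mild / (s$p_mild + s$p_none))
  }
  if (f == "monitoring_annual") {
    i <- match(as.integer(fp[2]), s$monitoring_annual$year_from)
    return(if (is.na(i)) NULL else s$monitoring_annual$amount[i])
  }
  if (f == "ae_costs") {
    v <- s$ae_costs[fp[2]]
    return(if (is.na(v)) NULL else unname(v))
  }
  v <- s[[f]]
  if (is.null(v) || !is.numeric(v)) NULL else v
}

#' Set one model parameter by path
#'
#' Returns a modified copy of the strategy list; inputs are revalidated.
#' Special cases keep the parameter space coherent:
#' * setting an outcome proportion (`p_marked`, `p_mild`, `p_none`)
#'   rescales the other two proportionally so they still sum to 1;
#'   `outcome_split` sets the mild share of the non-marked remainder;
#' * setting `u_bt` also moves `u_tr`, which the model ties to baseline;
#' * `shared.*` paths write to every strategy carrying the field (outcome
#'   proportions only to procedure strategies).
#'
#' @inheritParams get_param
#' @param value New numeric value.
#' @return The modified strategy list.
#' @export
set_param <- function(strategies, path, value) {
  p <- split_path(path)
  scope <- p[1]
  names_to_set <- if (scope == "shared") names(strategies) else scope
  if (!all(names_to_set %in% names(strategies))) {
    abort(sprintf("Unknown strategy in parameter path: %s", path),
          class = "tremorcea_config_error")
  }
  hit <- FALSE
  for (nm in names_to_set) {
    s <- write_field(strategies[[nm]], p[-1], value)
    if (!is.null(s)) {
      strategies[[nm]] <- validate_strategy_inputs(s)
      hit <- TRUE
    }
  }
  if (!hit) {
    abort(sprintf("Parameter path not found: %s", path),
          class = "tremorcea_config_error")
  }
  strategies
}

write_field <- function(s, fp, value) {
  f <- fp[1]
  value <- unname(value)
  if (s$name == "NONE" && f %in% .procedure_only_fields) return(NULL)
  if (f %in% c("p_marked", "p_mild", "p_none")) {
    old <- s[[f]]
    others <- setdiff(c("p_marked", "p_mild", "p_none"), f)
    rest_old <- 1 - old
    if (rest_old <= 0) return(NULL) # degenerate; cannot rescale
    scale <- (1 - value) / rest_old
    s[[f]] <- value
    for (o in others) s[[o]] <- s[[o]] * scale
    return(s)
  }
  if (f == "outcome_split") {
    rest <- 1 - s$p_marked
    s$p_mild <- rest * value
    s$p_none <- rest * (1 - value)
    return(s)
  }
  if (f == "u_bt") {
    s$u_bt <- value
    s$u_tr <- value
    return(s)
  }
  if (f == "monitoring_annual") {
    i <- match(as.integer(fp[2]), s$monitoring_annual$year_from)
    if (is.na(i)) return(NULL)
    s$monitoring_annual$amount[i] <- value
    return(s)
  }
  if (f == "ae_costs") {
    if (!(fp[2] %in% names(s$ae_costs))) return(NULL)
    s$ae_costs[[fp[2]]] <- value
    return(s)
  }
  if (is.null(s[[f]]) || !is.numeric(s[[f]])) return(NULL)
  s[[f]] <- value
  s
}

# every addressable scalar parameter of a strategy set, with its legal
# domain ("prob", "util", "cost"); used by range building and PSA specs
enumerate_params <- function(strategies) {
  rows <- list(
    tibble(parameter = "shared.p_marked", domain = "prob"),
    tibble(parameter = "shared.outcome_split", domain = "prob"),
    tibble(parameter = "shared.p_reop_given_recurrence", domain = "prob"),
    tibble(parameter = "shared.medication_annual", domain = "cost"),
    tibble(parameter = "shared.u_bt", domain = "util")
  )
  for (nm in names(strategies)) {
    s <- strategies[[nm]]
    if (nm != "NONE") {
      rows <- c(rows, list(tibble(
        parameter = paste0(nm, ".", c("waning_annual", "recurrence_annual",
                                      "onset_delay_fraction")),
        domain = "prob"
      ), tibble(
        parameter = paste0(nm, ".procedure_cost"), domain = "cost"
      ), tibble(
        parameter = paste0(nm, ".", c("u_mt_y1", "u_mt_y2plus",
                                      "u_mmt_y1", "u_mmt_y2plus")),
        domain = "util"
      )))
    }
    rows <- c(rows, list(tibble(
      parameter = paste0(nm, ".monitoring_annual.",
                         s$monitoring_annual$year_from),
      domain = "cost"
    )))
    if (length(s$ae_costs)) {
      rows <- c(rows, list(tibble(
        parameter = paste0(nm, ".ae_costs.", names(s$ae_costs)),
        domain = "cost"
      )))
    }
  }
  out <- dplyr::bind_rows(rows)
  out$base <- vapply(out$parameter,
                     function(p) unname(get_param(strategies, p)),
                     numeric(1), USE.NAMES = FALSE)
  out
}
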