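#' Wilson score interval for a binomial proportion
#'
#' Used to augment small-sample trial proportions: centre
#' `(p + z^2/2n) / (1 + z^2/n)`, half-width
#' `z * sqrt(p(1-p)/n + z^2/4n^2) / (1 + z^2/n)`. Unlike the Wald interval
#' it never leaves \[0, 1\] and stays informative at 0 or n successes.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param confidence Confidence level (default 0.95).
#' @return Named numeric vector `c(low, high)`.
#' @export
#' @examples
#' wilson_interval(8, 9)
wilson_interval <- function(successes, n, confidence = 0.95) {
  if (n < 1) abort("`n` must be >= 1.", class = "tremorcea_validation_error")
  if (successes < 0 || successes > n) {
    abort("`successes` must lie in [0, n].",
          class = "tremorcea_validation_error")
  }
  z <- qnorm(1 - (1 - confidence) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

clip_to_domain <- function(x, domain) {
  x <- pmax(0, x)
  ifelse(domain %in% c("prob", "util"), pmin(1, x), x)
}

#' Build one-way sensitivity ranges for every model parameter
#'
#' Every numeric parameter gets a low/high range: a supplied 95% CI when
#' one is available (e.g. a Wilson interval for a trial proportion),
#' otherwise +/- `spread` of the base value, clipped to the parameter's
#' legal domain (probabilities and utilities to \[0, 1\], costs to
#' non-negative).
#'
#' @param strategies Named list of `strategy_inputs`.
#' @param overrides Optional data frame with columns `parameter`, `low`,
#'   `high` giving confidence-interval bounds that replace the default
#'   spread for those parameters.
#' @param spread Relative half-width when no CI is supplied (default 0.2).
#' @return A tibble with columns `parameter`, `domain`, `base`, `low`,
#'   `high`, `source` (`"ci95"` or `"pm20"`).
#' @export
#' @examples
#' build_ranges(base_case_strategies())
build_ranges <- function(strategies, overrides = NULL, spread = 0.2) {
  grid <- enumerate_params(strategies)
  grid$low <- clip_to_domain(grid$base * (1 - spread), grid$domain)
  grid$high <- clip_to_domain(grid$base * (1 + spread), grid$domain)
  grid$source <- "pm20"
  if (!is.null(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      j <- match(overrides$parameter[i], grid$parameter)
      if (is.na(j)) {
        abort(sprintf("Override names unknown parameter: %s",
                      overrides$parameter[i]),
              class = "tremorcea_config_error")
      }
      grid$low[j] <- clip_to_domain(overrides$low[i], grid$domain[j])
      grid$high[j] <- clip_to_domain(overrides$high[i], grid$domain[j])
      grid$source[j] <- "ci95"
    }
  }
  bad <- grid$low > grid$base | grid$high < grid$base
  if (any(bad)) {
    abort(sprintf("Range does not bracket the base value for: %s",
                  paste(grid$parameter[bad], collapse = ", ")),
          class = "tremorcea_validation_error")
  }
  grid
}

# numeric ICER (dC/dQ) even under dominance, for tornado spans
icer_value <- function(cmp) {
  if (cmp$delta_qaly == 0) NA_real_ else cmp$delta_cost / cmp$delta_qaly
}

evaluate_comparison <- function(strategies, settings, lt, pair) {
  compare_strategies(
    evaluate_strategy(strategies[[pair[1]]], settings, lt),
    evaluate_strategy(strategies[[pair[2]]], settings, lt)
  )
}

#' One-way deterministic sensitivity analysis
#'
#' Re-evaluates the full model with each parameter set to its low and high
#' bound in turn, all others held at base. Rows whose ICER moves by more
#' than `filter` (relative to the base ICER) at either bound are reported,
#' ordered by descending bound-to-bound ICER span (ties alphabetically).
#' ICERs are the raw cost-difference / QALY-difference ratio, so dominant
#' comparisons appear as negative values, as on a tornado diagram.
#'
#' @param strategies Named list of `strategy_inputs`.
#' @param settings An [econ_settings()].
#' @param lt A `life_table`.
#' @param ranges Output of [build_ranges()].
#' @param comparisons List of `c(intervention, comparator)` pairs.
#' @param filter Minimum relative ICER change to report (default 0.05);
#'   set to 0 to keep every row.
#' @return A tibble of class `dsa_result` with columns `comparison`,
#'   `parameter`, `low_value`, `high_value`, `icer_low`, `icer_high`,
#'   `icer_base`, `relative_change`, `span`.
#' @export
run_dsa <- function(strategies, settings, lt,
                    ranges = build_ranges(strategies),
                    comparisons = list(c("MRGFUS", "NONE"),
                                       c("MRGFUS", "DBS")),
                    filter = 0.05) {
  out <- purrr::map(comparisons, function(pair) {
    tag <- paste(pair, collapse = "_vs_")
    base_icer <- icer_value(evaluate_comparison(strategies, settings, lt,
                                                pair))
    rows <- purrr::pmap(ranges, function(parameter, base, low, high, ...) {
      at <- function(v) {
        icer_value(evaluate_comparison(set_param(strategies, parameter, v),
                                       settings, lt, pair))
      }
      tibble(comparison = tag, parameter = parameter,
             low_value = low, high_value = high,
             icer_low = at(low), icer_high = at(high),
             icer_base = base_icer)
    })
    dplyr::bind_rows(rows)
  })
  out <- dplyr::bind_rows(out)
  out$relative_change <- pmax(abs(out$icer_low - out$icer_base),
                              abs(out$icer_high - out$icer_base)) /
    abs(out$icer_base)
  out$span <- abs(out$icer_high - out$icer_low)
  out <- dplyr::filter(out, .data$relative_change > filter)
  out <- dplyr::arrange(out, .data$comparison, dplyr::desc(.data$span),
                        .data$parameter)
  class(out) <- c("dsa_result", class(out))
  out
}

#' Tornado plot of a one-way sensitivity analysis
#'
#' @param object A `dsa_result`.
#' @param comparison Which comparison to plot (default: the first).
#' @param top Number of parameters to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dsa_result
#' @export
autoplot.dsa_result <- function(object,
                                comparison = object$comparison[1],
                                top = 10, ...) {
  d <- dplyr::filter(as_tibble(object), .data$comparison == !!comparison)
  d <- utils::head(d, top)
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       y = .data$parameter,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$icer_base[1]),
                        linetype = 2) +
    ggplot2::labs(x = "ICER (GBP/QALY)", y = NULL, title = comparison) +
    ggplot2::theme_minimal()
}

#' Build a probabilistic sampling specification
#'
#' Assigns each model parameter a sampling distribution by the field's
#' convention: beta for probabilities and utilities (bounded), gamma for
#' costs (non-negative, right-skewed), both parameterised by method of
#' moments around the base value. The standard deviation defaults to
#' `sd_fraction` of the mean; a CI override implies
#' `sd = (high - low) / (2 * 1.96)`. Structural quantities (the onset
#' delay) and zero-valued costs are held at their base value.
#'
#' @inheritParams build_ranges
#' @param sd_fraction SD as a fraction of the mean when no CI is supplied.
#' @param overrides Optional data frame `parameter`, `low`, `high` of 95%
#'   CIs used to derive SDs.
#' @return A tibble with columns `parameter`, `dist` (`"beta"`, `"gamma"`
#'   or `"point"`), `mean`, `sd`, `group` (rows sharing a group label draw
#'   from a common quantile each iteration; `NA` rows draw independently).
#' @export
#' @examples
#' build_psa_spec(base_case_strategies())
build_psa_spec <- function(strategies, sd_fraction = 0.2, overrides = NULL) {
  grid <- enumerate_params(strategies)
  # adverse-event costs carry no base-case cash flow: sampling them would
  # only burn random draws
  grid <- dplyr::filter(grid, !grepl("\\.ae_costs\\.", .data$parameter))
  grid$mean <- grid$base
  grid$sd <- sd_fraction * grid$mean
  if (!is.null(overrides)) {
    j <- match(overrides$parameter, grid$parameter)
    if (anyNA(j)) {
      abort("Override names unknown parameter.",
            class = "tremorcea_config_error")
    }
    grid$sd[j] <- (overrides$high - overrides$low) / (2 * qnorm(0.975))
  }
  grid$dist <- dplyr::case_when(
    grepl("onset_delay_fraction$", grid$parameter) ~ "point",
    grid$sd == 0 | grid$mean == 0 ~ "point",
    grid$domain %in% c("prob", "util") ~ "beta",
    TRUE ~ "gamma"
  )
  # The adverse-event-adjusted improvement utilities of the two procedures
  # derive from one underlying state utility apiece (marked 0.91, mild
  # 0.80, single literature source), so they are shared inputs: rows in a
  # group draw from one common quantile per iteration (comonotone), which
  # preserves each marginal while moving the family together.
  grid$group <- dplyr::case_when(
    grepl("\\.u_mt_y", grid$parameter) ~ "marked_utility",
    grepl("\\.u_mmt_y", grid$parameter) ~ "mild_utility",
    TRUE ~ NA_character_
  )
  grid[c("parameter", "dist", "mean", "sd", "group")]
}

#' Degenerate (point-mass) version of a sampling specification
#'
#' Sets every SD to zero so each PSA iteration reproduces the base case
#' exactly; useful for testing that the probabilistic machinery collapses
#' onto the deterministic result.
#'
#' @param spec Output of [build_psa_spec()].
#' @return The spec with `dist = "point"` and `sd = 0` everywhere.
#' @export
degenerate_psa_spec <- function(spec) {
  spec$dist <- "point"
  spec$sd <- 0
  spec
}

# one draw for a spec row at quantile u (inverse-CDF sampling so grouped
# rows can share a quantile)
draw_param <- function(dist, mean, sd, u) {
  if (dist == "point" || sd == 0) return(mean)
  if (dist == "beta") {
    v <- sd^2
    if (mean <= 0 || mean >= 1) {
      abort(sprintf("Beta moment matching needs mean in (0,1); got %g.",
                    mean),
            class = "tremorcea_validation_error")
    }
    if (v >= mean * (1 - mean)) {
      abort(sprintf("Beta moment matching infeasible: sd %g too large for mean %g.",
                    sd, mean),
            class = "tremorcea_validation_error")
    }
    k <- mean * (1 - mean) / v - 1
    return(stats::qbeta(u, mean * k, (1 - mean) * k))
  }
  # gamma by method of moments: shape (mean/sd)^2, scale sd^2/mean
  stats::qgamma(u, shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' Draw one sampled strategy set
#'
#' Applies one Monte Carlo draw of every parameter in `spec` to the base
#' strategy list. Parameters shared between strategies (one `shared.*` row)
#' are drawn once and written to every strategy, which preserves the
#' coupling between the two procedure arms; strategy-specific rows are
#' drawn independently.
#'
#' @param strategies Base strategy list.
#' @param spec A sampling spec from [build_psa_spec()].
#' @return A strategy list with sampled parameter values, revalidated.
#' @export
sample_inputs <- function(strategies, spec) {
  if (is.null(spec$group)) spec$group <- NA_character_
  group_u <- list()
  for (i in seq_len(nrow(spec))) {
    g <- spec$group[i]
    u <- if (is.na(g)) {
      stats::runif(1)
    } else {
      if (is.null(group_u[[g]])) group_u[[g]] <- stats::runif(1)
      group_u[[g]]
    }
    v <- draw_param(spec$dist[i], spec$mean[i], spec$sd[i], u)
    strategies <- set_param(strategies, spec$parameter[i], v)
  }
  strategies
}

#' Monte Carlo probabilistic sensitivity analysis
#'
#' Runs `n` full model evaluations on sampled inputs and records the
#' incremental cost and QALY pair for each comparison. A fixed master seed
#' derives one sub-seed per iteration, so results are bit-reproducible and
#' iteration `i` does not depend on how many iterations surround it.
#'
#' @inheritParams run_dsa
#' @param spec Sampling spec from [build_psa_spec()].
#' @param n Number of iterations.
#' @param seed Integer master seed.
#' @return An object of class `psa_result` holding the per-iteration draws
#'   (`$draws`: `iteration`, `comparison`, `delta_cost`, `delta_qaly`),
#'   `n` and `seed`. `tidy()` returns the draws, `glance()` one summary
#'   row per comparison.
#' @export
#' @examples
#' \donttest{
#' psa <- run_psa(n = 100, seed = 1)
#' glance(psa)
#' }
run_psa <- function(strategies = base_case_strategies(),
                    settings = econ_settings(),
                    lt = england_life_table(),
                    spec = build_psa_spec(strategies),
                    n = 1000, seed = 42,
                    comparisons = list(c("MRGFUS", "NONE"),
                                       c("MRGFUS", "DBS"))) {
  stopifnot(n >= 1)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  draws <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(sub_seeds[i])
    sampled <- sample_inputs(strategies, spec)
    results <- purrr::map(sampled, evaluate_strategy,
                          settings = settings, lt = lt)
    draws[[i]] <- dplyr::bind_rows(purrr::map(comparisons, function(pair) {
      cmp <- compare_strategies(results[[pair[1]]], results[[pair[2]]])
      tibble(iteration = i,
             comparison = paste(pair, collapse = "_vs_"),
             delta_cost = cmp$delta_cost,
             delta_qaly = cmp$delta_qaly)
    }))
  }
  structure(
    list(draws = dplyr::bind_rows(draws), n = n, seed = seed),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result: %d iterations, seed %d>\n", x$n, x$seed))
  print(glance(x))
  invisible(x)
}

#' @rdname run_psa
#' @param x A `psa_result`.
#' @param ... Unused.
#' @method tidy psa_result
#' @export
tidy.psa_result <- function(x, ...) x$draws

#' @rdname run_psa
#' @method glance psa_result
#' @export
glance.psa_result <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$draws, .data$comparison),
    n = dplyr::n(),
    prop_dominant = mean(.data$delta_cost < 0 & .data$delta_qaly > 0),
    prop_qaly_gain = mean(.data$delta_qaly > 0),
    mean_delta_cost = mean(.data$delta_cost),
    mean_delta_qaly = mean(.data$delta_qaly),
    .groups = "drop"
  )
}

#' Scatter of incremental cost against incremental QALYs
#'
#' @param object A `psa_result`.
#' @param ... Unused.
#' @return A ggplot, one facet per comparison.
#' @method autoplot psa_result
#' @export
autoplot.psa_result <- function(object, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(.data$delta_qaly, .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~comparison, scales = "free") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (GBP)") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the fraction of PSA iterations whose
#' incremental net monetary benefit `wtp * dQALY - dCost` is positive.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Willingness-to-pay grid (GBP/QALY); defaults to the
#'   standard 0..100,000 grid.
#' @return A tibble of class `ceac_curve` with columns `comparison`,
#'   `wtp`, `p_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid = econ_settings()$wtp_grid) {
  if (nrow(psa$draws) == 0) {
    abort("Empty PSA result.", class = "tremorcea_validation_error")
  }
  out <- tidyr::crossing(
    dplyr::distinct(psa$draws["comparison"]),
    wtp = wtp_grid
  )
  out <- dplyr::left_join(out, psa$draws, by = "comparison",
                          relationship = "many-to-many")
  out <- dplyr::summarise(
    dplyr::group_by(out, .data$comparison, .data$wtp),
    p_cost_effective = mean(.data$wtp * .data$delta_qaly -
                              .data$delta_cost > 0),
    .groups = "drop"
  )
  class(out) <- c("ceac_curve", class(out))
  out
}

#' @rdname ceac
#' @param object A `ceac_curve`.
#' @param ... Unused.
#' @method autoplot ceac_curve
#' @export
autoplot.ceac_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$wtp, .data$p_cost_effective,
                               colour = .data$comparison)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (GBP/QALY)",
                  y = "Probability cost-effective", colour = NULL) +
    ggplot2::theme_minimal()
}
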