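# Shared fixtures and independent oracles.

base_lt <- england_life_table()
base_settings <- econ_settings()
base_strats <- base_case_strategies()

# a life table with zero mortality over any age span, for closed-form limits
zero_mortality_lt <- function(age_lo = 40, age_hi = 100) {
  validate_life_table(tibble::tibble(age = age_lo:age_hi,
                                     q_male = 0, q_female = 0))
}

certain_death_lt <- function(age_lo = 40, age_hi = 100) {
  validate_life_table(tibble::tibble(age = age_lo:age_hi,
                                     q_male = 1, q_female = 1))
}

# Path-enumeration oracle: expands the full tree of state trajectories,
# multiplying per-step branch probabilities written out from first
# principles (independently of transition_matrix). Returns occupancy at
# each cycle 0..horizon. Exponential in the horizon; use only for <= 3-4.
enumerate_occupancy <- function(s, horizon, q_seq) {
  states <- c("BT", "MMT", "MT", "TR", "DEAD")
  successors <- function(state, q) {
    r <- s$recurrence_annual; w <- s$waning_annual
    k <- s$p_reop_given_recurrence
    surv <- 1 - q
    branches <- switch(state,
      BT = list(BT = 1),
      MMT = list(BT = r * (1 - k), TR = r * k, MMT = 1 - r),
      MT = list(BT = r * (1 - k), TR = r * k, MMT = (1 - r) * w,
                MT = (1 - r) * (1 - w)),
      TR = list(BT = s$p_none, MMT = s$p_mild, MT = s$p_marked),
      DEAD = list(DEAD = 1)
    )
    if (state == "DEAD") return(branches)
    out <- lapply(branches, function(p) p * surv)
    out$DEAD <- (out$DEAD %||% 0) + q
    out
  }
  occ <- matrix(0, horizon + 1, 5, dimnames = list(NULL, states))
  recurse <- function(state, t, prob) {
    occ[t + 1, state] <<- occ[t + 1, state] + prob
    if (t == horizon || prob == 0) return()
    for (nxt in names(successors(state, q_seq[t + 1]))) {
      recurse(nxt, t + 1, prob * successors(state, q_seq[t + 1])[[nxt]])
    }
  }
  init <- c(BT = s$p_none, MMT = s$p_mild, MT = s$p_marked)
  for (st in names(init)) recurse(st, 0, init[[st]])
  occ
}

`%||%` <- function(a, b) if (is.null(a)) b else a
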