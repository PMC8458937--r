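# Shared test fixtures, built in code.

# flat rate tables covering the default age span
flat_rates <- function(incidence = 0.003, mortality = 0.01,
                       ages = 55:75) {
  list(incidence = rate_table(ages, rep(incidence, length(ages))),
       mortality = rate_table(ages, rep(mortality, length(ages))))
}

zero_rates <- function(ages = 55:75) flat_rates(0, 0, ages)

# a small deterministic generated-rate pair for property tests
toy_generated_rates <- function(seed = 7) {
  generate_rate_tables(rate_profile(noise_sd = 0.01), seed = seed)
}

# a reduced parameter set for fast brute-force comparisons:
# 3-cycle horizon, small engine state space
tiny_params <- function(...) {
  cea_parameters(horizon = 3L, advanced_dwell_threshold = 2L,
                 excess_risk_duration = 2L, ...)
}

# independent path-enumeration oracle: expected discounted cost and QALYs by
# exhaustive enumeration of all engine-state paths. Recomputes the per-cycle
# accruals directly from the parameters; transition probabilities are taken
# from the per-cycle matrices (themselves pinned by direct entry tests).
enumerate_expected <- function(modality, params, rates,
                               horizon = params$horizon) {
  es <- mrmcea:::.engine_states(params)
  interval <- params$screening_interval
  screen_cycles <- seq(0L, horizon - interval, by = interval)
  mats <- lapply(seq_len(horizon) - 1L, function(t) {
    ev <- if (t %in% screen_cycles) {
      list(modality = modality, round_index = match(t, screen_cycles))
    }
    build_transition_matrix(params$start_age + t, params, rates,
                            screening_event = ev)
  })
  cost_exam <- switch(modality, XM = params$cost_xm, MRM = params$cost_mrm)
  tx <- c(DS = params$cost_tx_small, DL = params$cost_tx_large,
          DA = params$cost_tx_advanced)

  accrue <- function(state, t) {
    df <- discount_factor(t, params$discount_rate)
    cost <- 0
    qaly <- es$qol[[state]]
    if (state %in% c("DS", "DL", "DA")) cost <- cost + tx[[state]]
    if (t %in% screen_cycles && (state == "H" || state %in% es$u)) {
      r <- match(t, screen_cycles)
      cost <- cost + cost_exam
      if (state == "H") {
        spec <- specificity_for_round(modality, r, params)
        w <- false_positive_workup(modality, r, params)
        cost <- cost + (1 - spec) * w$cost
        qaly <- qaly - (1 - spec) * w$qol_loss
      }
    }
    c(cost = cost * df, qaly = qaly * df)
  }

  total <- c(cost = 0, qaly = 0)
  recurse <- function(state, t, prob) {
    if (prob == 0) return()
    if (t >= horizon) return()
    total <<- total + prob * accrue(state, t)
    row <- mats[[t + 1L]][state, ]
    for (nxt in es$states[row > 0]) {
      recurse(nxt, t + 1L, prob * row[[nxt]])
    }
  }
  start <- c(H = 1 - params$pretest_probability,
             U0 = params$pretest_probability)
  for (s in names(start)) recurse(s, 0L, start[[s]])
  total
}
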