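base <- cea_parameters()

test_that("transition matrices are row-stochastic with absorbing death", {
  rates <- flat_rates()
  for (ev in list(NULL, list(modality = "MRM", round_index = 1),
                  list(modality = "XM", round_index = 4))) {
    M <- build_transition_matrix(60, base, rates, screening_event = ev)
    expect_true(all(abs(rowSums(M) - 1) < 1e-10))
    expect_true(all(M >= 0 & M <= 1))
    dead <- M["DEAD", ]
    expect_identical(unname(dead[names(dead) != "DEAD"]),
                     rep(0, ncol(M) - 1))
    expect_identical(unname(dead["DEAD"]), 1)
  }
})

test_that("healthy-to-undetected entry equals survival times incidence", {
  rates <- default_rates()
  M <- build_transition_matrix(55, base, rates)
  q55 <- rate_lookup(rates$mortality, 55)
  i55 <- rate_lookup(rates$incidence, 55)
  expect_equal(M["H", "U0"], (1 - q55) * i55, tolerance = 1e-15)
  expect_equal(M["H", "DEAD"], q55, tolerance = 1e-15)
  expect_error(build_transition_matrix(100, base, rates), "coverage")
})

test_that("cohort advancement is plain matrix propagation", {
  n <- length(mrmcea:::.engine_states(base)$states)
  v <- rep(1 / n, n)
  expect_equal(advance_cohort(v, diag(n)), v)
  all_dead <- matrix(0, n, n)
  all_dead[, n] <- 1
  expect_equal(advance_cohort(v, all_dead), c(rep(0, n - 1), 1))
  # hand-computed 2-state product
  expect_equal(advance_cohort(c(0.5, 0.5),
                              matrix(c(0.9, 0.1, 0, 1), 2, 2, byrow = TRUE)),
               c(0.45, 0.55))
  expect_error(advance_cohort(c(0.5, 0.5), diag(3)), "dimension")
})

test_that("cohort mass is conserved at every cycle", {
  for (rates in list(default_rates(), flat_rates(), toy_generated_rates())) {
    for (m in c("XM", "MRM")) {
      traj <- run_strategy(m, base, rates)
      occ <- as.matrix(traj$trajectory[, health_states()])
      expect_true(all(abs(rowSums(occ) - 1) < 1e-10))
      expect_true(all(occ >= -1e-15))
      expect_true(all(diff(traj$trajectory$cum_cost) >= 0))
      expect_true(all(diff(traj$trajectory$cum_qaly) >= 0))
    }
  }
})

test_that("with zero excess risks survival equals the life-table product", {
  p <- cea_parameters(death_risk_undetected_cum = 0, death_small_annual = 0,
                      death_large_annual = 0, death_advanced_annual = 0)
  rates <- default_rates()
  traj <- run_strategy("XM", p, rates)
  q <- rate_lookup(rates$mortality, 55:74)
  surv <- cumprod(1 - q)
  alive <- 1 - traj$trajectory$DEAD
  # occupancy is recorded at cycle start: cycle t carries t years of deaths
  expect_equal(alive, c(1, surv[1:19]), tolerance = 1e-12)
})

test_that("riskless cohorts reproduce the closed-form annuities", {
  zr <- zero_rates()
  p <- cea_parameters(pretest_probability = 0, interval_detection = 0,
                      spec_xm = 1, spec_mrm_round1 = 1, spec_mrm_later = 1,
                      cost_xm = 0, cost_mrm = 0)
  traj <- run_strategy("XM", p, zr)
  expect_equal(traj$total_qaly, 15.32380, tolerance = 1e-5)
  expect_equal(traj$total_cost, 0)

  p$cost_xm <- 101.52
  traj2 <- run_strategy("XM", p, zr)
  expect_equal(traj2$total_cost, 789.33, tolerance = 0.01)
})

test_that("three-cycle path enumeration matches matrix propagation", {
  rates <- flat_rates(incidence = 0.05, mortality = 0.02)
  for (m in c("XM", "MRM")) {
    p <- tiny_params()
    oracle <- enumerate_expected(m, p, rates)
    traj <- run_strategy(m, p, rates)
    expect_equal(traj$total_cost, unname(oracle["cost"]), tolerance = 1e-9)
    expect_equal(traj$total_qaly, unname(oracle["qaly"]), tolerance = 1e-9)
  }
  # also under an interval-detection-free structure and zero prevalence
  p2 <- tiny_params(interval_detection = 0, pretest_probability = 0)
  oracle2 <- enumerate_expected("XM", p2, rates)
  traj2 <- run_strategy("XM", p2, rates)
  expect_equal(traj2$total_cost, unname(oracle2["cost"]), tolerance = 1e-9)
  expect_equal(traj2$total_qaly, unname(oracle2["qaly"]), tolerance = 1e-9)
})

test_that("costs and QALYs respond monotonically to their parameters", {
  rates <- flat_rates()
  ref <- run_strategy("MRM", base, rates)
  for (f in c("cost_mrm", "cost_biopsy", "cost_tx_small", "cost_tx_advanced")) {
    p <- base
    p[[f]] <- p[[f]] * 1.5
    expect_gte(run_strategy("MRM", p, rates)$total_cost, ref$total_cost)
  }
  for (f in c("qol_small", "qol_post_intensive", "qol_healthy")) {
    p <- base
    p[[f]] <- p[[f]] * 0.8
    expect_lte(run_strategy("MRM", p, rates)$total_qaly, ref$total_qaly)
  }
})

test_that("the vectorised batch engine agrees with matrix propagation", {
  rates <- default_rates()
  set.seed(21)
  draws <- list(
    pretest_probability = runif(4, 0.005, 0.05),
    sens_xm = runif(4, 0.2, 0.9), sens_mrm = runif(4, 0.7, 1),
    spec_xm = runif(4, 0.8, 1), spec_mrm_later = runif(4, 0.9, 1),
    cost_mrm = runif(4, 100, 600), cost_biopsy = runif(4, 500, 3000),
    cost_tx_large = runif(4, 5e4, 1.5e5),
    qol_post_simple = runif(4, 0.8, 1), qol_large = runif(4, 0.5, 0.9),
    death_advanced_annual = runif(4, 0, 0.05),
    p_r0_large = runif(4, 0.5, 1),
    biopsy_rate_fp_later = runif(4, 0.5, 1)
  )
  for (m in c("XM", "MRM")) {
    batch <- mrmcea:::.run_strategy_batch(m, draws, base, rates)
    for (i in seq_len(4)) {
      p <- base
      for (nm in names(draws)) p[[nm]] <- draws[[nm]][i]
      traj <- run_strategy(m, validate_parameters(p), rates)
      expect_equal(batch$cost[i], traj$total_cost, tolerance = 1e-9)
      expect_equal(batch$qaly[i], traj$total_qaly, tolerance = 1e-9)
    }
  }
})

test_that("trajectory export carries one labelled row per cycle", {
  traj <- run_strategy("MRM", base, default_rates())
  df <- as.data.frame(traj)
  expect_identical(nrow(df), 20L)
  expect_identical(df$cycle, 0:19)
  expect_equal(df$age, 55:74)
  expect_true(all(health_states() %in% names(df)))
  expect_error(run_strategy("MRM", base, default_rates(), horizon = 2.5),
               "horizon")
})
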