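test_that("tornado handles empty and degenerate ranges", {
  p <- cea_parameters()
  rates <- flat_rates()
  empty <- one_way_tornado(p, ranges = list(), rates = rates)
  expect_identical(nrow(empty), 0L)

  degen <- one_way_tornado(p, ranges = list(cost_mrm = c(314, 314)),
                           rates = rates)
  expect_identical(degen$span, 0)

  expect_error(one_way_tornado(p, ranges = list(cost_mrm = c(400, 500)),
                               rates = rates),
               "bracket")
  expect_error(one_way_tornado(p, ranges = list(sens_mrm = c(0.5, 1.5)),
                               rates = rates),
               "invalid")
})

test_that("MRM cost dominates the tornado; MRM sensitivity matters far less", {
  tor <- one_way_tornado(cea_parameters())
  expect_identical(tor$parameter[1], "cost_mrm")
  # the specificities are among the key determinants
  expect_true(all(c("spec_xm", "spec_mrm_later") %in% tor$parameter[1:5]))
  # MRM sensitivity is a several-fold weaker driver than MRM cost
  span_sens <- tor$span[tor$parameter == "sens_mrm"]
  expect_lt(span_sens, tor$span[1] / 4)
  expect_true(all(diff(tor$span) <= 0))
})

test_that("tornado spans do not depend on parameter processing order", {
  p <- cea_parameters()
  rates <- flat_rates()
  r1 <- list(cost_mrm = c(250, 400), sens_xm = c(0.35, 0.45))
  r2 <- rev(r1)
  t1 <- one_way_tornado(p, r1, rates)
  t2 <- one_way_tornado(p, r2, rates)
  expect_identical(t1[order(t1$parameter), ], t2[order(t2$parameter), ])
})

test_that("the cost-specificity surface is consistent and monotone", {
  p <- cea_parameters()
  single <- two_way_cost_specificity(p, p$cost_mrm, p$spec_mrm_later)
  fit <- screen_cea(p)
  expect_equal(single$icer, fit$result$icer, tolerance = 1e-9)

  sweep <- two_way_cost_specificity(p, p$cost_mrm, seq(0.92, 0.99, 0.01))
  expect_true(all(diff(sweep$icer) < 0))
  expect_error(two_way_cost_specificity(p, -5, 0.97), "cost_grid")
  expect_error(two_way_cost_specificity(p, 314, 1.2), "spec_grid")
})

test_that("break-even cost zeroes the incremental cost and rises with specificity", {
  p <- cea_parameters()
  rates <- default_rates()
  be <- break_even_mrm_cost(p, spec_later = 0.97, rates = rates)
  p_be <- p
  p_be$cost_mrm <- be
  fit <- screen_cea(p_be, rates)
  expect_lt(abs(fit$result$incr_cost), 1)  # within a dollar of equality

  bes <- vapply(c(0.92, 0.95, 0.99), function(s) {
    break_even_mrm_cost(p, spec_later = s, rates = rates)
  }, numeric(1))
  expect_true(all(diff(bes) > 0))

  expect_error(break_even_mrm_cost(p, rates = rates, bracket = c(5000, 6000)),
               "sign")
})

test_that("PSA draws are valid, reproducible and degenerate when fixed", {
  p <- cea_parameters()
  rates <- flat_rates()
  fixed_spec <- lapply(default_psa_distributions(p), function(d) {
    list(dist = "fixed", mean = d$mean, cv = 0)
  })
  psa0 <- probabilistic_sa(p, fixed_spec, n_iter = 5, seed = 1, rates = rates)
  fit <- screen_cea(p, rates)
  expect_equal(psa0$incr_cost, rep(fit$result$incr_cost, 5), tolerance = 1e-9)
  expect_equal(psa0$incr_effect, rep(fit$result$incr_effect, 5),
               tolerance = 1e-9)

  a <- probabilistic_sa(p, n_iter = 100, seed = 7, rates = rates)
  b <- probabilistic_sa(p, n_iter = 100, seed = 7, rates = rates)
  expect_identical(a, b)  # bit-reproducible
  c2 <- probabilistic_sa(p, n_iter = 100, seed = 8, rates = rates)
  expect_false(identical(a, c2))

  # drawn probabilities stay in [0, 1], costs non-negative
  for (f in c("sens_xm", "spec_mrm_later", "qol_post_intensive")) {
    expect_true(all(a[[f]] >= 0 & a[[f]] <= 1))
  }
  for (f in c("cost_mrm", "cost_tx_advanced")) {
    expect_true(all(a[[f]] >= 0))
  }

  bad <- default_psa_distributions(p)
  bad$sens_xm$cv <- 3  # variance beyond the feasible beta variance
  expect_error(probabilistic_sa(p, bad, n_iter = 5, seed = 1, rates = rates),
               "beta")
})

test_that("the CEAC steps at the sample ICER and has exact endpoints", {
  one <- data.frame(incr_cost = 271, incr_effect = 0.020)
  grid <- c(13000, 13500, 13549, 13551, 13600, 14000)
  cv <- ceac(one, grid)
  expect_identical(cv$prob_cost_effective, c(0, 0, 0, 1, 1, 1))

  dominant <- data.frame(incr_cost = c(-10, -5), incr_effect = c(0.1, 0.2))
  expect_true(all(ceac(dominant, c(0, 1e5))$prob_cost_effective == 1))

  psa <- probabilistic_sa(cea_parameters(), n_iter = 200, seed = 3,
                          rates = flat_rates())
  cv2 <- ceac(psa, c(0, 1e9))
  expect_identical(cv2$prob_cost_effective[1], mean(psa$incr_cost < 0))
  expect_identical(cv2$prob_cost_effective[2] -
                     mean(psa$incr_effect > 0 |
                            (psa$incr_effect == 0 & psa$incr_cost < 0)) < 1e-9,
                   TRUE)

  expect_error(ceac(psa[0, ]), "empty")
  expect_error(ceac(psa, c(1, 1)), "increasing")
})

test_that("simulate() on a fitted model reproduces probabilistic_sa", {
  fit <- screen_cea(cea_parameters(), flat_rates())
  s1 <- simulate(fit, nsim = 50, seed = 11)
  s2 <- probabilistic_sa(fit$params, n_iter = 50, seed = 11,
                         rates = fit$rates)
  expect_identical(s1, s2)
})
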