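rates <- flat_rates()
base <- cea_parameters()

# targets generated from a known parameter set, for self-consistency and
# recovery checks
targets_from <- function(params) {
  xm <- run_strategy("XM", params, rates)
  mrm <- run_strategy("MRM", params, rates)
  p99 <- params
  p99$spec_mrm_later <- 0.99
  mrm99 <- run_strategy("MRM", p99, rates)
  cmp99 <- compare_strategies(xm, mrm99, params$wtp)
  list(
    calibration_target("xm_cost", "cost", xm$total_cost, strategy = "XM"),
    calibration_target("mrm_cost", "cost", mrm$total_cost, strategy = "MRM"),
    calibration_target("mrm_qaly", "qaly", mrm$total_qaly, strategy = "MRM"),
    calibration_target("icer99", "icer", cmp99$incr_cost / cmp99$incr_effect,
                       spec_later = 0.99)
  )
}

test_that("loss vanishes on self-generated targets and scales with weights", {
  tg <- targets_from(base)
  expect_equal(calibration_loss(base, tg, rates), 0, tolerance = 1e-18)

  perturbed <- base
  perturbed$interval_detection <- 0.5
  l1 <- calibration_loss(perturbed, tg, rates)
  expect_gt(l1, 0)

  doubled <- lapply(tg, function(t) { t$weight <- 2; t })
  expect_equal(calibration_loss(perturbed, doubled, rates), 2 * l1,
               tolerance = 1e-12)
})

test_that("perturbing a free parameter off a known optimum increases loss", {
  tg <- targets_from(base)
  for (delta in c(-0.1, 0.1)) {
    p <- base
    p$interval_detection <- p$interval_detection + delta
    expect_gt(calibration_loss(validate_parameters(p), tg, rates), 0)
  }
})

test_that("grid search recovers known free parameters exactly", {
  truth <- cea_parameters(interval_detection = 0.5,
                          advanced_dwell_threshold = 2L,
                          excess_risk_duration = 5L)
  tg <- targets_from(truth)
  space <- list(
    interval_detection = list(values = c(0.3, 0.5, 0.7)),
    advanced_dwell_threshold = list(values = c(2L, 3L)),
    excess_risk_duration = list(values = c(3L, 5L))
  )
  fit <- fit_free_parameters(tg, space, rates, base_params = base)
  expect_identical(fit$best$interval_detection, 0.5)
  expect_identical(fit$best$advanced_dwell_threshold, 2L)
  expect_identical(fit$best$excess_risk_duration, 5L)
  expect_equal(fit$loss, 0, tolerance = 1e-16)
  expect_equal(unname(fit$residuals), rep(0, 4), tolerance = 1e-9)

  # result invariant to axis enumeration order (unique optimum)
  fit2 <- fit_free_parameters(tg, rev(space), rates, base_params = base)
  expect_identical(fit2$best[names(fit$best)], fit$best)

  calibrated <- apply_calibration(base, fit)
  expect_identical(calibrated$interval_detection, 0.5)
})

test_that("recovery works from every grid point of a small space", {
  space <- list(
    interval_detection = list(values = c(0.2, 0.8)),
    excess_risk_duration = list(values = c(3L, 5L))
  )
  for (s in space$interval_detection$values) {
    for (d in space$excess_risk_duration$values) {
      truth <- cea_parameters(interval_detection = s,
                              excess_risk_duration = d)
      fit <- fit_free_parameters(targets_from(truth), space, rates,
                                 base_params = base)
      expect_identical(fit$best$interval_detection, s)
      expect_identical(fit$best$excess_risk_duration, d)
    }
  }
})

test_that("degenerate spaces and resolutions are handled", {
  tg <- targets_from(base)
  single <- list(interval_detection = list(values = 0.85))
  fit <- fit_free_parameters(tg, single, rates, base_params = base)
  expect_identical(fit$best$interval_detection, 0.85)

  expect_error(fit_free_parameters(list(), rates = rates), "empty")
  expect_error(fit_free_parameters(tg, list(), rates = rates), "empty")
  expect_error(
    fit_free_parameters(tg, list(interval_detection = list(bounds = c(0, 1))),
                        rates = rates, grid_resolution = 1),
    "grid_resolution")
})

test_that("refining a nested grid never increases the achieved loss", {
  truth <- cea_parameters(interval_detection = 0.45)
  tg <- targets_from(truth)
  coarse <- fit_free_parameters(
    tg, list(interval_detection = list(bounds = c(0.3, 0.7))),
    rates, grid_resolution = 3, base_params = base)
  fine <- fit_free_parameters(
    tg, list(interval_detection = list(bounds = c(0.3, 0.7))),
    rates, grid_resolution = 5, base_params = base)
  expect_lte(fine$loss, coarse$loss)
})
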