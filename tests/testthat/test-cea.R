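test_that("the ICER follows the four-quadrant convention", {
  expect_identical(icer(100, 1, 200, 2), 100)
  expect_identical(icer(200, 1, 100, 2), "ALT_DOMINANT")
  expect_identical(icer(100, 2, 200, 1), "REF_DOMINANT")
  expect_identical(icer(100, 1, 50, 0.5), 100)  # cheaper and less effective
  expect_identical(icer(100, 1, 200, 1), "UNDEFINED")
  expect_identical(icer(100, 1, 100, 1), "UNDEFINED")
})

test_that("the ICER value is preserved under strategy swap, flags mirror", {
  set.seed(5)
  for (i in 1:50) {
    c1 <- runif(1, 0, 1e4); c2 <- runif(1, 0, 1e4)
    e1 <- runif(1, 10, 20); e2 <- runif(1, 10, 20)
    a <- icer(c1, e1, c2, e2)
    b <- icer(c2, e2, c1, e1)
    if (is.numeric(a)) {
      expect_equal(a, b, tolerance = 1e-12)
    } else {
      expect_identical(sort(c(a, b)),
                       c("ALT_DOMINANT", "REF_DOMINANT"))
    }
  }
})

test_that("net monetary benefit is the WTP-weighted effect minus cost", {
  expect_identical(net_monetary_benefit(6081, 15.120, 100000),
                   100000 * 15.120 - 6081)
  expect_identical(net_monetary_benefit(123, 4, 0), -123)
  expect_identical(net_monetary_benefit(0, 0, 5e4), 0)
  expect_error(net_monetary_benefit(1, 1, -1), "wtp")
})

test_that("strategy comparison populates incrementals and the decision", {
  rates <- flat_rates()
  p <- cea_parameters()
  xm <- run_strategy("XM", p, rates)
  mrm <- run_strategy("MRM", p, rates)
  cmp <- compare_strategies(xm, mrm, wtp = 1e5)
  expect_equal(cmp$incr_cost, mrm$total_cost - xm$total_cost,
               tolerance = 1e-9)
  expect_equal(cmp$incr_effect, mrm$total_qaly - xm$total_qaly,
               tolerance = 1e-9)
  expect_identical(compare_strategies(xm, xm, 1e5)$icer, "UNDEFINED")
  expect_equal(compare_strategies(xm, xm, 1e5)$nmb_ref,
               compare_strategies(xm, xm, 1e5)$nmb_alt)

  short <- run_strategy("MRM", p, rates, horizon = 10)
  expect_error(compare_strategies(xm, short, 1e5), "horizon")
})

test_that("NMB ranking agrees with the ICER-vs-WTP decision", {
  rates <- flat_rates()
  p <- cea_parameters()
  xm <- run_strategy("XM", p, rates)
  mrm <- run_strategy("MRM", p, rates)
  for (wtp in c(0, 5000, 13000, 5e4, 1e5, 1e6)) {
    cmp <- compare_strategies(xm, mrm, wtp)
    if (is.numeric(cmp$icer) && cmp$incr_effect > 0) {
      expect_identical(cmp$nmb_alt > cmp$nmb_ref, cmp$icer < wtp)
    }
  }
  # the decision is monotone non-decreasing in WTP
  dec <- vapply(seq(0, 2e5, by = 1e4), function(w) {
    compare_strategies(xm, mrm, w)$cost_effective_at_wtp
  }, logical(1))
  expect_true(all(diff(dec) >= 0))
})

test_that("screen_cea wraps the paired comparison with methods", {
  fit <- screen_cea(cea_parameters(), flat_rates())
  expect_s3_class(fit, "screen_cea")
  s <- summary(fit)
  expect_identical(s$strategy, c("XM", "MRM"))
  expect_equal(s$incr_cost[2], fit$result$incr_cost)
  expect_output(print(fit), "incremental")
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf)
  plot(fit)
  grDevices::dev.off()
  expect_true(file.exists(tf))
  unlink(tf)
})
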