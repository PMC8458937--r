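#' Default one-way sensitivity ranges
#'
#' Cost parameters are varied by +/-25% around the base value; the
#' first-round and later-round MRM specificities over the published
#' prevalence-round/incidence-round bounds (92%-97%); the XM specificity by
#' +/-2.5 percentage points (the order of the uncertainty reported for
#' screening mammography -- a 10% relative drop would double the
#' false-positive rate, outside anything observed); the remaining diagnostic
#' probabilities by +/-10% relative, truncated to `[0, 1]`.
#'
#' @param params A [cea_parameters()] object supplying the base values.
#' @return Named list of `c(low, high)` ranges, each bracketing the base.
#' @export
default_tornado_ranges <- function(params = cea_parameters()) {
  rel <- function(x, f) c(x * (1 - f), min(1, x * (1 + f)))
  out <- list()
  for (f in .cost_fields) out[[f]] <- params[[f]] * c(0.75, 1.25)
  out$spec_mrm_round1 <- c(0.92, 0.97)
  out$spec_mrm_later <- c(0.92, 0.97)
  out$spec_xm <- c(max(0, params$spec_xm - 0.025),
                   min(1, params$spec_xm + 0.025))
  for (f in c("sens_xm", "sens_mrm", "biopsy_rate_fp_round1",
              "biopsy_rate_fp_later", "pretest_probability")) {
    out[[f]] <- rel(params[[f]], 0.10)
  }
  out
}

# signed CE ratio used for deterministic sweeps: incremental cost over
# incremental effect (negative in the dominance quadrants), NA at equal
# effects
.icer_value <- function(res) {
  if (res$incr_effect == 0) NA_real_ else res$incr_cost / res$incr_effect
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the paired strategy comparison with each parameter set to the low
#' and the high end of its range, all others held at base, and records the
#' resulting ICERs. Entries are sorted by descending span, the layout of a
#' tornado diagram.
#'
#' @param base_params A [cea_parameters()] object.
#' @param ranges Named list of `c(low, high)` ranges; each must bracket the
#'   base value and lie in the parameter's domain. Defaults to
#'   [default_tornado_ranges()].
#' @param rates Rate tables, as for [run_strategy()].
#' @param wtp Willingness-to-pay used in the underlying comparisons.
#' @return An object of classes `tornado`/`data.frame`: one row per
#'   parameter with `low`, `high`, `icer_low`, `icer_high` (signed
#'   incremental cost-effectiveness ratios; negative values indicate a
#'   dominance quadrant) and `span = |icer_high - icer_low|`, sorted by
#'   descending span.
#' @export
one_way_tornado <- function(base_params, ranges = default_tornado_ranges(base_params),
                            rates = default_rates(), wtp = base_params$wtp) {
  base_params <- validate_parameters(base_params)
  if (length(ranges) == 0) {
    out <- data.frame(parameter = character(0), low = numeric(0),
                      high = numeric(0), icer_low = numeric(0),
                      icer_high = numeric(0), span = numeric(0))
    class(out) <- c("tornado", "data.frame")
    return(out)
  }
  bad <- character(0)
  for (nm in names(ranges)) {
    rg <- ranges[[nm]]
    base <- base_params[[nm]]
    if (is.null(base)) bad <- c(bad, paste0(nm, ": unknown parameter"))
    else if (rg[1] > base || rg[2] < base) {
      bad <- c(bad, sprintf("%s: range [%g, %g] does not bracket base %g",
                            nm, rg[1], rg[2], base))
    } else {
      probe <- base_params
      probe[[nm]] <- rg[1]
      tryCatch(validate_parameters(probe),
               error = function(e) bad <<- c(bad, paste0(nm, ": ",
                                                         conditionMessage(e))))
      probe[[nm]] <- rg[2]
      tryCatch(validate_parameters(probe),
               error = function(e) bad <<- c(bad, paste0(nm, ": ",
                                                         conditionMessage(e))))
    }
  }
  if (length(bad)) stop("invalid tornado ranges:\n  ",
                        paste(bad, collapse = "\n  "), call. = FALSE)

  run_at <- function(nm, value) {
    p <- base_params
    p[[nm]] <- value
    fit <- screen_cea(p, rates, wtp = wtp)
    .icer_value(fit$result)
  }
  rows <- lapply(names(ranges), function(nm) {
    rg <- ranges[[nm]]
    il <- run_at(nm, rg[1])
    ih <- run_at(nm, rg[2])
    data.frame(parameter = nm, low = rg[1], high = rg[2],
               icer_low = il, icer_high = ih, span = abs(ih - il))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  out
}

#' @export
plot.tornado <- function(x, ...) {
  y <- x[nrow(x):1, ]
  mid <- (y$icer_low + y$icer_high) / 2
  graphics::barplot(
    height = rbind(y$icer_high - mid, mid - y$icer_low),
    beside = FALSE, horiz = TRUE, names.arg = y$parameter, las = 1,
    offset = pmin(y$icer_low, y$icer_high),
    xlab = "ICER (US-$/QALY)", ...)
  invisible(x)
}

#' Two-way sensitivity: MRM examination cost x later-round specificity
#'
#' Evaluates the signed incremental cost-effectiveness ratio on the grid of
#' MRM per-examination costs and later-round MRM specificities, all other
#' parameters at base (first-round specificity stays at its base value).
#'
#' @param base_params A [cea_parameters()] object.
#' @param cost_grid Numeric vector of `cost_mrm` values (>= 0).
#' @param spec_grid Numeric vector of `spec_mrm_later` values in `[0, 1]`.
#' @param rates Rate tables.
#' @return An object of classes `icer_surface`/`data.frame` with columns
#'   `cost_mrm`, `spec_mrm_later`, `icer` (signed ratio, `NA` when effects
#'   are equal) and `flag` (`"ICER"`, `"ALT_DOMINANT"`, `"REF_DOMINANT"` or
#'   `"UNDEFINED"`).
#' @export
two_way_cost_specificity <- function(base_params, cost_grid, spec_grid,
                                     rates = default_rates()) {
  base_params <- validate_parameters(base_params)
  if (any(cost_grid < 0)) stop("cost_grid must be >= 0")
  if (any(spec_grid < 0 | spec_grid > 1)) {
    stop("spec_grid must lie in [0, 1]")
  }
  xm <- run_strategy("XM", base_params, rates)
  grid <- expand.grid(cost_mrm = cost_grid, spec_mrm_later = spec_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- base_params
    p$cost_mrm <- grid$cost_mrm[i]
    p$spec_mrm_later <- grid$spec_mrm_later[i]
    mrm <- run_strategy("MRM", p, rates)
    cmp <- compare_strategies(xm, mrm, base_params$wtp)
    data.frame(icer = .icer_value(cmp),
               flag = if (is.numeric(cmp$icer)) "ICER" else cmp$icer)
  })
  out <- cbind(grid, do.call(rbind, res))
  class(out) <- c("icer_surface", "data.frame")
  out
}

#' Break-even MRM examination cost
#'
#' Finds, by bisection to $0.01, the MRM per-examination cost at which the
#' cumulative discounted costs of the MRM and XM strategies are equal
#' (incremental cost zero) for a given later-round MRM specificity. All other
#' parameters stay at base.
#'
#' @param base_params A [cea_parameters()] object.
#' @param spec_later Later-round MRM specificity in `[0, 1]`; defaults to the
#'   base value.
#' @param rates Rate tables.
#' @param bracket Search bracket for `cost_mrm`, US-$.
#' @param tol Bisection tolerance on the cost, US-$.
#' @return The break-even cost (US-$).
#' @export
break_even_mrm_cost <- function(base_params,
                                spec_later = base_params$spec_mrm_later,
                                rates = default_rates(),
                                bracket = c(0, 2000), tol = 0.01) {
  base_params <- validate_parameters(base_params)
  if (spec_later < 0 || spec_later > 1) stop("spec_later must lie in [0, 1]")
  xm_cost <- run_strategy("XM", base_params, rates)$total_cost
  f <- function(cost) {
    p <- base_params
    p$spec_mrm_later <- spec_later
    p$cost_mrm <- cost
    run_strategy("MRM", p, rates)$total_cost - xm_cost
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0) {
    stop(sprintf(paste0("incremental cost does not change sign over ",
                        "[%.2f, %.2f]: f(lo) = %.2f, f(hi) = %.2f"),
                 lo, hi, flo, fhi))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (flo * fm <= 0) {
      hi <- mid
    } else {
      lo <- mid; flo <- fm
    }
  }
  (lo + hi) / 2
}

#' Default PSA parameter distributions
#'
#' Beta distributions for probabilities and utilities (moment-matched to the
#' base value with coefficient of variation `cv_prob`) and gamma
#' distributions for costs (mean = base value, coefficient of variation
#' `cv_cost`). Parameters at the boundary of their domain (probability 0 or
#' 1, cost 0) are degenerate and held fixed; the three calibrated structural
#' parameters are likewise held fixed.
#'
#' @param params A [cea_parameters()] object supplying the means.
#' @param cv_prob Coefficient of variation for probability/utility draws.
#' @param cv_cost Coefficient of variation for cost draws.
#' @return Named list of distribution specifications, each a list with
#'   `dist` (`"beta"`, `"gamma"` or `"fixed"`), `mean` and `cv`.
#' @export
default_psa_distributions <- function(params = cea_parameters(),
                                      cv_prob = 0.1, cv_cost = 0.2) {
  spec <- list()
  varied_probs <- setdiff(.prob_fields, "interval_detection")
  for (f in varied_probs) {
    m <- params[[f]]
    spec[[f]] <- if (m <= 0 || m >= 1) {
      list(dist = "fixed", mean = m, cv = 0)
    } else {
      list(dist = "beta", mean = m, cv = cv_prob)
    }
  }
  for (f in .cost_fields) {
    m <- params[[f]]
    spec[[f]] <- if (m <= 0) list(dist = "fixed", mean = m, cv = 0) else
      list(dist = "gamma", mean = m, cv = cv_cost)
  }
  spec
}

.validate_distribution_spec <- function(distribution_spec) {
  for (nm in names(distribution_spec)) {
    d <- distribution_spec[[nm]]
    if (!is.list(d) || is.null(d$dist) ||
        !d$dist %in% c("beta", "gamma", "fixed")) {
      stop("invalid distribution for ", nm,
           ": dist must be 'beta', 'gamma' or 'fixed'")
    }
    if (d$dist == "fixed") next
    if (!is.numeric(d$cv) || d$cv < 0) {
      stop("invalid distribution for ", nm, ": cv must be >= 0")
    }
    if (d$dist == "beta") {
      if (d$mean <= 0 || d$mean >= 1) {
        stop("invalid beta distribution for ", nm,
             ": mean must lie strictly inside (0, 1)")
      }
      if ((d$cv * d$mean)^2 >= d$mean * (1 - d$mean)) {
        stop("invalid beta distribution for ", nm,
             ": variance exceeds the feasible beta variance")
      }
    }
    if (d$dist == "gamma" && d$mean <= 0) {
      stop("invalid gamma distribution for ", nm, ": mean must be > 0")
    }
  }
  invisible(distribution_spec)
}

.draw_psa_parameters <- function(distribution_spec, n_iter) {
  draws <- list()
  for (nm in names(distribution_spec)) {
    d <- distribution_spec[[nm]]
    draws[[nm]] <- switch(
      d$dist,
      fixed = rep(d$mean, n_iter),
      beta = {
        if (d$cv == 0) rep(d$mean, n_iter) else {
          sd2 <- (d$cv * d$mean)^2
          nu <- d$mean * (1 - d$mean) / sd2 - 1
          stats::rbeta(n_iter, d$mean * nu, (1 - d$mean) * nu)
        }
      },
      gamma = {
        if (d$cv == 0) rep(d$mean, n_iter) else {
          shape <- 1 / d$cv^2
          stats::rgamma(n_iter, shape = shape, rate = shape / d$mean)
        }
      })
  }
  draws
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_iter` full parameter sets from `distribution_spec`, runs both
#' screening strategies for every draw and records the incremental cost,
#' incremental effect and the incremental net monetary benefit at the
#' reference willingness-to-pay. Reproducible given `seed`.
#'
#' @param base_params A [cea_parameters()] object (supplies the structural
#'   parameters and the default distribution means).
#' @param distribution_spec As returned by [default_psa_distributions()].
#' @param n_iter Number of Monte Carlo iterations, >= 1.
#' @param seed Integer RNG seed.
#' @param rates Rate tables.
#' @param wtp Reference willingness-to-pay for the recorded NMB difference.
#' @return An object of classes `screen_cea_psa`/`data.frame`: one row per
#'   iteration with the drawn parameter values and columns `incr_cost`,
#'   `incr_effect`, `nmb_diff`. Attribute `wtp` records the reference
#'   threshold.
#' @export
#' @examples
#' psa <- probabilistic_sa(cea_parameters(), n_iter = 50, seed = 1)
#' mean(psa$nmb_diff > 0)
probabilistic_sa <- function(base_params,
                             distribution_spec =
                               default_psa_distributions(base_params),
                             n_iter, seed, rates = default_rates(),
                             wtp = base_params$wtp) {
  base_params <- validate_parameters(base_params)
  if (n_iter < 1) stop("n_iter must be >= 1")
  .validate_distribution_spec(distribution_spec)

  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(as.integer(seed))
  draws <- .draw_psa_parameters(distribution_spec, n_iter)

  xm <- .run_strategy_batch("XM", draws, base_params, rates)
  mrm <- .run_strategy_batch("MRM", draws, base_params, rates)
  incr_cost <- mrm$cost - xm$cost
  incr_effect <- mrm$qaly - xm$qaly
  out <- as.data.frame(draws)
  out$incr_cost <- incr_cost
  out$incr_effect <- incr_effect
  out$nmb_diff <- wtp * incr_effect - incr_cost
  attr(out, "wtp") <- wtp
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("screen_cea_psa", "data.frame")
  out
}

#' Probabilistic sensitivity analysis of a fitted screening model
#'
#' `simulate()` on a [screen_cea()] object runs [probabilistic_sa()] with the
#' object's parameters and rate tables.
#'
#' @param object A [screen_cea()] object.
#' @param nsim Number of Monte Carlo iterations.
#' @param seed Integer RNG seed (required, for reproducibility).
#' @param ... Passed on to [probabilistic_sa()] (e.g. `distribution_spec`).
#' @return A `screen_cea_psa` object; see [probabilistic_sa()].
#' @export
simulate.screen_cea <- function(object, nsim = 30000, seed, ...) {
  probabilistic_sa(object$params, n_iter = nsim, seed = seed,
                   rates = object$rates, wtp = object$result$wtp, ...)
}

#' @export
print.screen_cea_psa <- function(x, ...) {
  wtp <- attr(x, "wtp")
  cat(sprintf("Probabilistic sensitivity analysis: %d iterations\n", nrow(x)))
  cat(sprintf("  cost-effective at WTP $%s/QALY: %.1f%%\n",
              format(wtp, big.mark = ","), 100 * mean(x$nmb_diff > 0)))
  cat(sprintf("  MRM cheaper than XM:            %.1f%%\n",
              100 * mean(x$incr_cost < 0)))
  invisible(x)
}

#' Cost-effectiveness plane of PSA iterations
#'
#' @param x A `screen_cea_psa` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.screen_cea_psa <- function(x, ...) {
  wtp <- attr(x, "wtp")
  graphics::plot(x$incr_effect, x$incr_cost, pch = ".", col = "grey30",
                 xlab = "incremental effect (QALYs)",
                 ylab = "incremental cost (US-$)", ...)
  graphics::abline(0, wtp, col = "firebrick")
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 3)
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the fraction of PSA iterations whose
#' incremental net monetary benefit is positive
#' (`wtp * incr_effect - incr_cost > 0`).
#'
#' @param samples A `screen_cea_psa` object (or data frame with `incr_cost`
#'   and `incr_effect` columns) with at least one row.
#' @param wtp_grid Strictly increasing willingness-to-pay grid.
#' @return An object of classes `ceac_curve`/`data.frame` with columns `wtp`
#'   and `prob_cost_effective`.
#' @export
#' @examples
#' psa <- probabilistic_sa(cea_parameters(), n_iter = 50, seed = 1)
#' ceac(psa, seq(0, 2e5, by = 5e4))
ceac <- function(samples, wtp_grid = seq(0, 200000, by = 5000)) {
  if (NROW(samples) == 0) stop("PSA sample list is empty")
  if (any(diff(wtp_grid) <= 0)) stop("wtp_grid must be strictly increasing")
  frac <- vapply(wtp_grid, function(w) {
    mean(w * samples$incr_effect - samples$incr_cost > 0)
  }, numeric(1))
  out <- data.frame(wtp = wtp_grid, prob_cost_effective = frac)
  class(out) <- c("ceac_curve", "data.frame")
  out
}

#' @export
plot.ceac_curve <- function(x, ...) {
  graphics::plot(x$wtp, x$prob_cost_effective, type = "l", ylim = c(0, 1),
                 xlab = "willingness to pay (US-$/QALY)",
                 ylab = "probability cost-effective", ...)
  invisible(x)
}
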