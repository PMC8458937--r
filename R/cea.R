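#' Incremental cost-effectiveness ratio with dominance handling
#'
#' Follows the four-quadrant cost-effectiveness-plane convention: the ICER is
#' the ratio of incremental cost to incremental effect when the alternative
#' is costlier and more effective (or cheaper and less effective); when the
#' alternative is cheaper *and* more effective it dominates
#' (`"ALT_DOMINANT"`), in the mirror case the reference dominates
#' (`"REF_DOMINANT"`), and with equal effects the ratio is `"UNDEFINED"`.
#'
#' @param cost_ref,effect_ref Cumulative cost and effect of the reference
#'   strategy.
#' @param cost_alt,effect_alt Cumulative cost and effect of the alternative.
#' @return A numeric ICER (currency per QALY), or one of the character flags
#'   `"ALT_DOMINANT"`, `"REF_DOMINANT"`, `"UNDEFINED"`.
#' @export
#' @examples
#' icer(100, 1, 200, 2)  # 100
#' icer(200, 1, 100, 2)  # "ALT_DOMINANT"
icer <- function(cost_ref, effect_ref, cost_alt, effect_alt) {
  dc <- cost_alt - cost_ref
  de <- effect_alt - effect_ref
  if (de == 0) {
    "UNDEFINED"
  } else if (de > 0 && dc <= 0) {
    "ALT_DOMINANT"
  } else if (de < 0 && dc >= 0) {
    "REF_DOMINANT"
  } else {
    dc / de
  }
}

#' Net monetary benefit
#'
#' @param cost Cumulative cost.
#' @param effect Cumulative effect (QALYs).
#' @param wtp Willingness-to-pay threshold (currency per QALY), >= 0.
#' @return `wtp * effect - cost`.
#' @export
#' @examples
#' net_monetary_benefit(6081, 15.120, 1e5)
net_monetary_benefit <- function(cost, effect, wtp) {
  if (any(wtp < 0)) stop("wtp must be >= 0")
  wtp * effect - cost
}

#' Compare two strategy trajectories
#'
#' @param traj_ref,traj_alt [run_strategy()] results over identical horizons
#'   and rate tables (reference first, e.g. XM, then the alternative, e.g.
#'   MRM).
#' @param wtp Willingness-to-pay threshold used for the net-benefit decision.
#' @return An object of class `cea_result`: costs and effects per strategy,
#'   incrementals, the ICER (or dominance flag), net monetary benefits and
#'   the cost-effectiveness decision at `wtp`.
#' @export
compare_strategies <- function(traj_ref, traj_alt, wtp) {
  stopifnot(inherits(traj_ref, "cohort_trajectory"),
            inherits(traj_alt, "cohort_trajectory"))
  if (traj_ref$horizon != traj_alt$horizon) {
    stop("strategies were run over different horizons")
  }
  ic <- icer(traj_ref$total_cost, traj_ref$total_qaly,
             traj_alt$total_cost, traj_alt$total_qaly)
  incr_effect <- traj_alt$total_qaly - traj_ref$total_qaly
  out <- list(
    strategy_ref = traj_ref$modality,
    strategy_alt = traj_alt$modality,
    cost_ref = traj_ref$total_cost,
    cost_alt = traj_alt$total_cost,
    effect_ref = traj_ref$total_qaly,
    effect_alt = traj_alt$total_qaly,
    incr_cost = traj_alt$total_cost - traj_ref$total_cost,
    incr_effect = incr_effect,
    icer = ic,
    nmb_ref = net_monetary_benefit(traj_ref$total_cost, traj_ref$total_qaly,
                                   wtp),
    nmb_alt = net_monetary_benefit(traj_alt$total_cost, traj_alt$total_qaly,
                                   wtp),
    wtp = wtp,
    cost_effective_at_wtp =
      identical(ic, "ALT_DOMINANT") || (is.numeric(ic) && incr_effect > 0 &&
                                          ic <= wtp)
  )
  class(out) <- "cea_result"
  out
}

#' @export
print.cea_result <- function(x, ...) {
  icer_str <- if (is.numeric(x$icer)) {
    sprintf("%s US-$/QALY", format(round(x$icer), big.mark = ","))
  } else {
    x$icer
  }
  cat("Cost-effectiveness comparison\n")
  cat(sprintf("  %-4s $%s  %.3f QALYs\n", x$strategy_ref,
              format(round(x$cost_ref), big.mark = ","), x$effect_ref))
  cat(sprintf("  %-4s $%s  %.3f QALYs\n", x$strategy_alt,
              format(round(x$cost_alt), big.mark = ","), x$effect_alt))
  cat(sprintf("  incremental: $%s, %.4f QALYs; ICER %s\n",
              format(round(x$incr_cost), big.mark = ","), x$incr_effect,
              icer_str))
  cat(sprintf("  cost-effective at WTP $%s/QALY: %s\n",
              format(x$wtp, big.mark = ","),
              ifelse(x$cost_effective_at_wtp, "yes", "no")))
  invisible(x)
}

#' Fit the screening cost-effectiveness model
#'
#' The central entry point of the package: runs the cohort model for the
#' reference (x-ray mammography) and alternative (MR-mammography) screening
#' strategies under one parameter set and rate-table pair and pairs them into
#' a cost-effectiveness comparison. The returned object supports `print()`,
#' `summary()` (a base-case results table), `plot()` (cumulative discounted
#' cost and QALY curves) and `simulate()` (probabilistic sensitivity
#' analysis, see [simulate.screen_cea()]).
#'
#' @param params A [cea_parameters()] object.
#' @param rates A list with `incidence` and `mortality` [rate_table()]s;
#'   defaults to the packaged fixtures.
#' @param wtp Willingness-to-pay threshold; defaults to `params$wtp`.
#' @param horizon Model runtime in years; defaults to `params$horizon`.
#' @return An object of class `screen_cea` with elements `params`, `rates`,
#'   `trajectories` (named list of [run_strategy()] results) and `result`
#'   (a `cea_result`).
#' @export
#' @examples
#' fit <- screen_cea()
#' fit
#' summary(fit)
screen_cea <- function(params = cea_parameters(), rates = default_rates(),
                       wtp = params$wtp, horizon = params$horizon) {
  params <- validate_parameters(params)
  trajs <- list(XM = run_strategy("XM", params, rates, horizon),
                MRM = run_strategy("MRM", params, rates, horizon))
  out <- list(params = params, rates = rates,
              trajectories = trajs,
              result = compare_strategies(trajs$XM, trajs$MRM, wtp))
  class(out) <- "screen_cea"
  out
}

#' @export
print.screen_cea <- function(x, ...) {
  cat("Biennial breast-cancer screening: MR-mammography vs x-ray mammography\n")
  print(x$result)
  invisible(x)
}

#' Base-case results table of a fitted screening model
#'
#' @param object A [screen_cea()] object.
#' @param ... Unused.
#' @return A data frame with one row per strategy: cumulative discounted
#'   costs, incremental costs, cumulative discounted effects, incremental
#'   effects and the ICER of the alternative vs the reference.
#' @export
summary.screen_cea <- function(object, ...) {
  r <- object$result
  out <- data.frame(
    strategy = c(r$strategy_ref, r$strategy_alt),
    cum_cost = c(r$cost_ref, r$cost_alt),
    incr_cost = c(NA_real_, r$incr_cost),
    cum_effect = c(r$effect_ref, r$effect_alt),
    incr_effect = c(NA_real_, r$incr_effect),
    icer = c(NA_real_, if (is.numeric(r$icer)) r$icer else NA_real_),
    stringsAsFactors = FALSE
  )
  if (!is.numeric(r$icer)) attr(out, "icer_flag") <- r$icer
  class(out) <- c("summary.screen_cea", "data.frame")
  out
}

#' @export
print.summary.screen_cea <- function(x, ...) {
  y <- x
  class(y) <- "data.frame"
  y$cum_cost <- round(y$cum_cost)
  y$incr_cost <- round(y$incr_cost)
  y$cum_effect <- round(y$cum_effect, 3)
  y$incr_effect <- round(y$incr_effect, 3)
  y$icer <- round(y$icer)
  print(y, row.names = FALSE)
  if (!is.null(attr(x, "icer_flag"))) {
    cat("ICER flag:", attr(x, "icer_flag"), "\n")
  }
  invisible(x)
}

#' Plot cumulative discounted cost and QALY curves of both strategies
#'
#' @param x A [screen_cea()] object.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.screen_cea <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  tx <- x$trajectories$XM$trajectory
  tm <- x$trajectories$MRM$trajectory
  graphics::matplot(tx$cycle, cbind(tx$cum_cost, tm$cum_cost), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "cycle (years)",
                    ylab = "cumulative discounted cost (US-$)", ...)
  graphics::legend("topleft", legend = c("XM", "MRM"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  graphics::matplot(tx$cycle, cbind(tx$cum_qaly, tm$cum_qaly), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "cycle (years)",
                    ylab = "cumulative discounted QALYs", ...)
  invisible(x)
}
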