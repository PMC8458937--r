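#' Define a calibration target
#'
#' A target is a named model output with the value it should reproduce and a
#' relative weight. Supported outputs: the cumulative discounted cost or
#' QALYs of one strategy, or the ICER at a given later-round MRM specificity.
#'
#' @param name Short label for reporting.
#' @param type `"cost"`, `"qaly"` (both need `strategy`) or `"icer"`.
#' @param target The target value.
#' @param weight Positive relative weight.
#' @param strategy `"XM"` or `"MRM"` for cost/QALY targets.
#' @param spec_later Optional later-round MRM specificity the output is
#'   evaluated at (default: the candidate's own value).
#' @return A `calibration_target` object.
#' @export
calibration_target <- function(name, type = c("cost", "qaly", "icer"),
                               target, weight = 1, strategy = NULL,
                               spec_later = NULL) {
  type <- match.arg(type)
  if (weight <= 0) stop("weight must be > 0")
  if (type %in% c("cost", "qaly")) {
    strategy <- match.arg(strategy, c("XM", "MRM"))
  }
  out <- list(name = name, type = type, target = target, weight = weight,
              strategy = strategy, spec_later = spec_later)
  class(out) <- "calibration_target"
  out
}

#' Default calibration target set
#'
#' The four cumulative base-case values (costs and QALYs of both strategies)
#' plus the ICERs at later-round MRM specificities of 92% and 99% (the two
#' ends of the published specificity sweep), equally weighted. This spans
#' both specificity regimes so the fitted structure cannot trade one round's
#' false-positive burden against the other.
#'
#' @return List of [calibration_target()]s.
#' @export
default_calibration_targets <- function() {
  list(
    calibration_target("xm_cost", "cost", 5810, strategy = "XM"),
    calibration_target("xm_qaly", "qaly", 15.099, strategy = "XM"),
    calibration_target("mrm_cost", "cost", 6081, strategy = "MRM"),
    calibration_target("mrm_qaly", "qaly", 15.120, strategy = "MRM"),
    calibration_target("icer_spec92", "icer", 38849, spec_later = 0.92),
    calibration_target("icer_spec99", "icer", 5062, spec_later = 0.99)
  )
}

# evaluate every target for one parameter set, reusing strategy runs
.calibration_outputs <- function(params, targets, rates) {
  xm <- NULL
  mrm_cache <- list()
  get_xm <- function() {
    if (is.null(xm)) xm <<- run_strategy("XM", params, rates)
    xm
  }
  get_mrm <- function(spec_later) {
    key <- sprintf("%.12g", spec_later)
    if (is.null(mrm_cache[[key]])) {
      p <- params
      p$spec_mrm_later <- spec_later
      mrm_cache[[key]] <<- run_strategy("MRM", p, rates)
    }
    mrm_cache[[key]]
  }
  vapply(targets, function(tg) {
    sl <- tg$spec_later %||% params$spec_mrm_later
    if (tg$type == "icer") {
      cmp <- compare_strategies(get_xm(), get_mrm(sl), params$wtp)
      if (cmp$incr_effect == 0) return(NA_real_)
      cmp$incr_cost / cmp$incr_effect
    } else {
      traj <- if (tg$strategy == "XM") get_xm() else get_mrm(sl)
      if (tg$type == "cost") traj$total_cost else traj$total_qaly
    }
  }, numeric(1))
}

#' Calibration loss
#'
#' Weighted sum of squared relative errors between the model outputs of a
#' candidate parameter set and the calibration targets.
#'
#' @param params A full [cea_parameters()] object with the candidate's free
#'   parameter values filled in.
#' @param targets List of [calibration_target()]s.
#' @param rates Rate tables.
#' @return Non-negative loss.
#' @export
calibration_loss <- function(params, targets, rates = default_rates()) {
  outputs <- .calibration_outputs(params, targets, rates)
  w <- vapply(targets, `[[`, numeric(1), "weight")
  tv <- vapply(targets, `[[`, numeric(1), "target")
  sum(w * ((outputs - tv) / tv)^2)
}

#' Default free-parameter space
#'
#' The three transition-structure quantities the published model description
#' leaves implicit: the per-cycle symptomatic (interval) detection
#' probability of an undetected tumor (continuous, bounded), the dwell
#' threshold in missed screening rounds beyond which detection is
#' advanced-stage, and the duration of the stage-specific excess death risk
#' after detection.
#'
#' @return Named list; each axis has either explicit `values` (enumerated
#'   grid) or `bounds` (continuous range discretised at the requested grid
#'   resolution).
#' @export
default_free_parameter_space <- function() {
  list(
    interval_detection = list(bounds = c(0, 0.95)),
    advanced_dwell_threshold = list(values = c(2L, 3L)),
    excess_risk_duration = list(values = c(3L, 5L, 10L, 15L, 20L))
  )
}

#' Fit the free parameters by exhaustive grid search
#'
#' Deterministically evaluates [calibration_loss()] on the full Cartesian
#' grid of the free-parameter space and returns the argmin; ties break toward
#' the lexicographically smallest candidate (in the axis order of `space`).
#'
#' @param targets List of [calibration_target()]s (non-empty).
#' @param space Free-parameter space, as [default_free_parameter_space()].
#' @param rates Rate tables.
#' @param grid_resolution Number of grid points per continuous axis (>= 2).
#' @param base_params Parameter set the candidates are embedded in.
#' @return An object of class `cea_calibration`: `best` (named list of
#'   fitted values), `loss`, `residuals` (per-target relative errors at the
#'   optimum), `outputs`, `targets` and the evaluated `grid` with losses.
#' @export
fit_free_parameters <- function(targets, space = default_free_parameter_space(),
                                rates = default_rates(), grid_resolution = 20,
                                base_params = cea_parameters()) {
  if (length(targets) == 0) stop("calibration target set is empty")
  if (length(space) == 0) stop("free-parameter space is empty")
  axes <- lapply(space, function(ax) {
    if (!is.null(ax$values)) {
      sort(ax$values)
    } else if (!is.null(ax$bounds)) {
      if (grid_resolution < 2) {
        stop("grid_resolution must be >= 2 for continuous axes")
      }
      seq(ax$bounds[1], ax$bounds[2], length.out = grid_resolution)
    } else {
      stop("each axis needs 'values' or 'bounds'")
    }
  })
  grid <- expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(axes)), drop = FALSE]  # lexicographic order
  names(grid) <- names(space)

  losses <- vapply(seq_len(nrow(grid)), function(i) {
    p <- base_params
    for (nm in names(space)) p[[nm]] <- grid[[nm]][i]
    calibration_loss(validate_parameters(p), targets, rates)
  }, numeric(1))
  best_i <- which(losses == min(losses))[1]

  best <- as.list(grid[best_i, , drop = FALSE])
  p_best <- base_params
  for (nm in names(best)) p_best[[nm]] <- best[[nm]]
  p_best <- validate_parameters(p_best)
  outputs <- .calibration_outputs(p_best, targets, rates)
  tv <- vapply(targets, `[[`, numeric(1), "target")
  out <- list(best = best,
              loss = losses[best_i],
              residuals = stats::setNames((outputs - tv) / tv,
                                          vapply(targets, `[[`, character(1),
                                                 "name")),
              outputs = stats::setNames(outputs,
                                        vapply(targets, `[[`, character(1),
                                               "name")),
              targets = targets,
              grid = cbind(grid, loss = losses))
  class(out) <- "cea_calibration"
  out
}

#' Apply calibrated free-parameter values to a parameter set
#'
#' @param params A [cea_parameters()] object.
#' @param fit A `cea_calibration` object from [fit_free_parameters()].
#' @return The updated, validated parameter set.
#' @export
apply_calibration <- function(params, fit) {
  stopifnot(inherits(fit, "cea_calibration"))
  for (nm in names(fit$best)) params[[nm]] <- fit$best[[nm]]
  validate_parameters(params)
}

#' @export
print.cea_calibration <- function(x, ...) {
  cat("Deterministic grid-search calibration\n")
  for (nm in names(x$best)) {
    cat(sprintf("  %s = %g\n", nm, x$best[[nm]]))
  }
  cat(sprintf("  loss: %.6g\n", x$loss))
  cat("  per-target relative residuals:\n")
  for (nm in names(x$residuals)) {
    cat(sprintf("    %-12s %+.3f%%  (model %.6g)\n", nm,
                100 * x$residuals[[nm]], x$outputs[[nm]]))
  }
  invisible(x)
}
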