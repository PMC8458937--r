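#' Model parameter set for the screening cost-effectiveness model
#'
#' Constructs the full parameter set of the decision-analytic model: per-round
#' diagnostic test performance, unit costs (US-$), health-state utilities,
#' transition probabilities, discounting and the willingness-to-pay threshold.
#' Defaults are the base-case inputs of the model (Medicare tariffs, published
#' test accuracies of x-ray mammography and breast MRI in dense breasts, NHS
#' Predict-derived annual disease-specific death risks), plus the three
#' transition-structure parameters that published evidence leaves implicit and
#' that the package pins down by deterministic calibration
#' (see [fit_free_parameters()]): the per-cycle symptomatic (interval)
#' detection probability, the dwell threshold (missed screening rounds) beyond
#' which a tumor is detected in an advanced stage, and the duration in years of
#' stage-specific excess mortality after detection.
#'
#' @param pretest_probability Probability of a prevalent malignant lesion at
#'   the first screening round.
#' @param start_age Age (years) at model entry.
#' @param screening_interval Years between screening rounds.
#' @param horizon Model runtime in years (annual cycles).
#' @param discount_rate Annual discount rate applied to costs and effects.
#' @param wtp Willingness-to-pay threshold, US-$ per QALY gained.
#' @param sens_xm,spec_xm Sensitivity and specificity of x-ray mammography.
#' @param sens_mrm Sensitivity of MR-mammography.
#' @param spec_mrm_round1,spec_mrm_later Specificity of MR-mammography in the
#'   first and in subsequent screening rounds.
#' @param biopsy_rate_fp_round1,biopsy_rate_fp_later Fraction of false-positive
#'   MRM findings worked up by biopsy (rest: follow-up examination), by round.
#' @param cost_xm,cost_mrm,cost_biopsy Per-examination costs, US-$.
#' @param cost_tx_small,cost_tx_large,cost_tx_advanced Per-treatment costs for
#'   tumors < 1 cm, > 1 cm, and advanced-stage disease, US-$.
#' @param qol_healthy,qol_small,qol_large,qol_advanced,qol_post_simple,qol_post_intensive
#'   Health-state utility weights in `[0, 1]`.
#' @param qol_fp_decrement Utility decrement applied for one cycle after a
#'   false-positive finding.
#' @param death_risk_undetected_cum Cumulative probability of death with an
#'   undetected tumor over `undetected_risk_span` years.
#' @param undetected_risk_span Span (years) over which
#'   `death_risk_undetected_cum` accumulates.
#' @param death_small_annual,death_large_annual,death_advanced_annual Annual
#'   disease-specific death probabilities after detection, by stage.
#' @param p_r0_small,p_r0_large Probability of an initial R0 resection by stage.
#' @param p_nplus_small,p_nplus_large Proportion node-positive by stage.
#' @param p_small_if_detected_within_interval Proportion of tumors detected
#'   within one screening interval of onset that are < 1 cm (successfully
#'   treated small).
#' @param interval_detection Per-cycle probability that an undetected tumor
#'   presents symptomatically in a non-screening cycle (calibrated).
#' @param advanced_dwell_threshold Number of missed screening rounds at or
#'   beyond which detection occurs in the advanced stage (calibrated).
#' @param excess_risk_duration Years after detection during which the
#'   stage-specific annual excess death risk applies (calibrated).
#'
#' @return An object of class `cea_parameters`: a named list of all fields,
#'   already validated by [validate_parameters()].
#' @seealso [validate_parameters()], [read_cea_config()], [screen_cea()]
#' @export
#' @examples
#' p <- cea_parameters()
#' p$cost_mrm
#' cea_parameters(spec_mrm_later = 0.99)$spec_mrm_later
cea_parameters <- function(pretest_probability = 0.0165,
                           start_age = 55,
                           screening_interval = 2L,
                           horizon = 20L,
                           discount_rate = 0.03,
                           wtp = 100000,
                           sens_xm = 0.412,
                           spec_xm = 0.90,
                           sens_mrm = 0.952,
                           spec_mrm_round1 = 0.92,
                           spec_mrm_later = 0.97,
                           biopsy_rate_fp_round1 = 0.672,
                           biopsy_rate_fp_later = 0.802,
                           cost_xm = 101.52,
                           cost_mrm = 314.00,
                           cost_biopsy = 1536.00,
                           cost_tx_small = 60637,
                           cost_tx_large = 82121,
                           cost_tx_advanced = 129387,
                           qol_healthy = 1.00,
                           qol_small = 0.87,
                           qol_large = 0.74,
                           qol_advanced = 0.62,
                           qol_post_simple = 0.99,
                           qol_post_intensive = 0.95,
                           qol_fp_decrement = 0.01,
                           death_risk_undetected_cum = 0.10,
                           undetected_risk_span = 10,
                           death_small_annual = 0.0011,
                           death_large_annual = 0.0078,
                           death_advanced_annual = 0.0181,
                           p_r0_small = 1.00,
                           p_r0_large = 0.90,
                           p_nplus_small = 0.00,
                           p_nplus_large = 0.40,
                           p_small_if_detected_within_interval = 1.00,
                           interval_detection = 0.85,
                           advanced_dwell_threshold = 3L,
                           excess_risk_duration = 5L) {
  params <- as.list(environment())
  params$screening_interval <- as.integer(params$screening_interval)
  params$horizon <- as.integer(params$horizon)
  params$advanced_dwell_threshold <- as.integer(params$advanced_dwell_threshold)
  params$excess_risk_duration <- as.integer(params$excess_risk_duration)
  class(params) <- "cea_parameters"
  validate_parameters(params)
}

# field groups used by validation, the PSA and the config reader
.prob_fields <- c(
  "pretest_probability", "sens_xm", "spec_xm", "sens_mrm", "spec_mrm_round1",
  "spec_mrm_later", "biopsy_rate_fp_round1", "biopsy_rate_fp_later",
  "qol_healthy", "qol_small", "qol_large", "qol_advanced", "qol_post_simple",
  "qol_post_intensive", "qol_fp_decrement", "death_risk_undetected_cum",
  "death_small_annual", "death_large_annual", "death_advanced_annual",
  "p_r0_small", "p_r0_large", "p_nplus_small", "p_nplus_large",
  "p_small_if_detected_within_interval", "interval_detection"
)

.cost_fields <- c(
  "cost_xm", "cost_mrm", "cost_biopsy",
  "cost_tx_small", "cost_tx_large", "cost_tx_advanced"
)

#' Validate a parameter set
#'
#' Checks every invariant of the parameter set (probabilities and utilities in
#' `[0, 1]`, non-negative costs and discount rate, positive integer horizon and
#' screening interval with interval <= horizon, positive structural
#' parameters) and reports *all* violations at once.
#'
#' @param params A `cea_parameters` object or a named list with the same fields.
#' @return `params`, invisibly unchanged, with class `cea_parameters`.
#' @export
validate_parameters <- function(params) {
  stopifnot(is.list(params))
  missing_fields <- setdiff(
    c(.prob_fields, .cost_fields,
      c("start_age", "screening_interval", "horizon", "discount_rate", "wtp",
        "undetected_risk_span", "advanced_dwell_threshold",
        "excess_risk_duration")),
    names(params)
  )
  if (length(missing_fields)) {
    stop("missing parameter fields: ", paste(missing_fields, collapse = ", "))
  }

  bad <- character(0)
  for (f in .prob_fields) {
    v <- params[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      bad <- c(bad, sprintf("%s must lie in [0, 1] (got %s)", f,
                            format(params[[f]])))
    }
  }
  for (f in .cost_fields) {
    v <- params[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      bad <- c(bad, sprintf("%s must be >= 0 (got %s)", f, format(params[[f]])))
    }
  }
  if (params$discount_rate < 0) {
    bad <- c(bad, "discount_rate must be >= 0")
  }
  if (params$wtp < 0) bad <- c(bad, "wtp must be >= 0")
  if (params$horizon < 1 || params$horizon != round(params$horizon)) {
    bad <- c(bad, "horizon must be a positive integer")
  }
  if (params$screening_interval < 1 ||
      params$screening_interval != round(params$screening_interval)) {
    bad <- c(bad, "screening_interval must be a positive integer")
  }
  if (params$screening_interval > params$horizon) {
    bad <- c(bad, "screening_interval must not exceed horizon")
  }
  if (params$start_age < 0) bad <- c(bad, "start_age must be >= 0")
  if (params$undetected_risk_span < 1) {
    bad <- c(bad, "undetected_risk_span must be >= 1")
  }
  if (params$advanced_dwell_threshold < 1) {
    bad <- c(bad, "advanced_dwell_threshold must be >= 1")
  }
  if (params$excess_risk_duration < 1) {
    bad <- c(bad, "excess_risk_duration must be >= 1")
  }
  if (length(bad)) {
    stop("invalid parameter set:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }
  class(params) <- "cea_parameters"
  invisible(params)
}

#' Convert a cumulative risk over a span to a constant annual probability
#'
#' Inverts constant-probability compounding: returns the annual probability
#' `p_a` with `(1 - p_a)^span = 1 - p_cum`. Used to annualise risks quoted
#' over a multi-year window, e.g. a 10% risk of death over 10 years with an
#' undetected tumor.
#'
#' @param p_cum Cumulative probability over `span` years, in `[0, 1)`.
#' @param span Number of years, >= 1.
#' @return The constant annual probability.
#' @export
#' @examples
#' annual_probability_from_cumulative(0.10, 10) # ~0.0104807
annual_probability_from_cumulative <- function(p_cum, span) {
  if (any(span <= 0)) stop("span must be >= 1")
  if (any(p_cum < 0) || any(p_cum >= 1)) stop("p_cum must lie in [0, 1)")
  1 - (1 - p_cum)^(1 / span)
}

#' Discount factor for an annual cycle
#'
#' Cycle 0 is undiscounted; cycle `k` is discounted by `(1 + rate)^-k`.
#'
#' @param cycle_index Non-negative integer cycle index (0 = first model year).
#' @param rate Annual discount rate, >= 0.
#' @return The discount factor.
#' @export
#' @examples
#' discount_factor(1, 0.03) # 1/1.03
discount_factor <- function(cycle_index, rate) {
  if (any(cycle_index < 0)) stop("cycle_index must be >= 0")
  if (any(rate < 0)) stop("rate must be >= 0")
  (1 + rate)^(-cycle_index)
}

#' Read / write a model configuration file
#'
#' The configuration is a flat key-value YAML file whose keys exactly match
#' the field names of [cea_parameters()]. `write_cea_config()` serialises with
#' full double precision so a parameter set round-trips bit-identically.
#'
#' @param path Path to the configuration file.
#' @return `read_cea_config()` returns a validated `cea_parameters` object;
#'   `write_cea_config()` returns `path` invisibly.
#' @export
#' @examples
#' path <- tempfile(fileext = ".yaml")
#' write_cea_config(cea_parameters(), path)
#' identical(unclass(read_cea_config(path)), unclass(cea_parameters()))
read_cea_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(cea_parameters))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  do.call(cea_parameters, raw)
}

#' @rdname read_cea_config
#' @param params A `cea_parameters` object to serialise.
#' @export
write_cea_config <- function(params, path) {
  params <- validate_parameters(params)
  fields <- unclass(params)
  lines <- vapply(names(fields), function(nm) {
    v <- fields[[nm]]
    if (is.integer(v)) {
      sprintf("%s: %d", nm, v)
    } else {
      s <- sprintf("%.17g", v)
      if (!grepl("[.e]", s)) s <- paste0(s, ".0")  # keep double typing
      sprintf("%s: %s", nm, s)
    }
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.cea_parameters <- function(x, ...) {
  cat("Screening cost-effectiveness model parameters\n")
  cat(sprintf("  cohort: start age %d, %d-yearly screening over %d years\n",
              as.integer(x$start_age), x$screening_interval, x$horizon))
  cat(sprintf("  discounting: %.1f%%/year; WTP: $%s/QALY\n",
              100 * x$discount_rate, format(x$wtp, big.mark = ",")))
  cat(sprintf("  XM:  sens %.1f%%, spec %.1f%%, $%.2f/exam\n",
              100 * x$sens_xm, 100 * x$spec_xm, x$cost_xm))
  cat(sprintf("  MRM: sens %.1f%%, spec %.1f%% (round 1) / %.1f%% (later), $%.2f/exam\n",
              100 * x$sens_mrm, 100 * x$spec_mrm_round1,
              100 * x$spec_mrm_later, x$cost_mrm))
  cat(sprintf("  calibrated structure: interval detection %.2f/cycle, advanced after %d missed rounds, %d-year excess-risk window\n",
              x$interval_detection, x$advanced_dwell_threshold,
              x$excess_risk_duration))
  invisible(x)
}
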