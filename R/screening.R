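#' Specificity of a screening modality at a given round
#'
#' X-ray mammography has round-independent specificity. MR-mammography's
#' specificity rises from the first (prevalence) screening round to the second
#' and is held constant thereafter: prior images from preceding rounds allow
#' benign findings to be dismissed.
#'
#' @param modality `"XM"` or `"MRM"`.
#' @param round_index Attended screening round, integer >= 1.
#' @param params A [cea_parameters()] object.
#' @return The specificity (probability).
#' @export
#' @examples
#' specificity_for_round("MRM", 1, cea_parameters()) # 0.92
#' specificity_for_round("MRM", 2, cea_parameters()) # 0.97
specificity_for_round <- function(modality, round_index, params) {
  modality <- match.arg(modality, c("XM", "MRM"))
  if (any(round_index < 1) || any(round_index != round(round_index))) {
    stop("round_index must be an integer >= 1")
  }
  if (modality == "XM") {
    rep(params$spec_xm, length(round_index))
  } else {
    ifelse(round_index == 1, params$spec_mrm_round1, params$spec_mrm_later)
  }
}

.sensitivity_for <- function(modality, params) {
  switch(match.arg(modality, c("XM", "MRM")),
         XM = params$sens_xm, MRM = params$sens_mrm)
}

#' Expected cost and utility loss of a false-positive workup
#'
#' A false-positive x-ray mammogram is worked up by biopsy. A false-positive
#' MR-mammogram leads to a biopsy with the round-dependent biopsy rate and
#' otherwise to a follow-up examination, costed at one MRM examination. In
#' both modalities a false positive carries the one-cycle utility decrement
#' `qol_fp_decrement`.
#'
#' @inheritParams specificity_for_round
#' @return A list with elements `cost` (expected workup cost, US-$) and
#'   `qol_loss` (one-cycle QALY decrement).
#' @export
#' @examples
#' false_positive_workup("MRM", 1, cea_parameters())$cost # 1135.184
false_positive_workup <- function(modality, round_index, params) {
  modality <- match.arg(modality, c("XM", "MRM"))
  if (any(round_index < 1)) stop("round_index must be >= 1")
  cost <- if (modality == "XM") {
    rep(params$cost_biopsy, length(round_index))
  } else {
    b <- ifelse(round_index == 1,
                params$biopsy_rate_fp_round1, params$biopsy_rate_fp_later)
    b * params$cost_biopsy + (1 - b) * params$cost_mrm
  }
  list(cost = cost, qol_loss = rep(params$qol_fp_decrement,
                                   length(round_index)))
}

#' Diagnostic outcome split of one screening round
#'
#' Splits a screened population with the given disease prevalence into true
#' positive, false negative, true negative and false positive fractions, and
#' attaches the expected immediate economic consequences: the per-examination
#' screening cost, and the expected workup cost and one-cycle utility loss
#' per false positive.
#'
#' @param prevalence Probability of a (so far undetected) malignant lesion in
#'   the screened population at this round.
#' @inheritParams specificity_for_round
#' @return An object of class `round_outcome`: a list with fields `p_tp`,
#'   `p_fp`, `p_tn`, `p_fn` (summing to 1), `expected_screen_cost`,
#'   `expected_fp_workup_cost` and `expected_fp_qol_loss`.
#' @export
#' @examples
#' ro <- round_outcome(0.0165, "MRM", 1, cea_parameters())
#' ro$p_tp # 0.0165 * 0.952
round_outcome <- function(prevalence, modality, round_index, params) {
  if (prevalence < 0 || prevalence > 1) stop("prevalence must lie in [0, 1]")
  modality <- match.arg(modality, c("XM", "MRM"))
  sens <- .sensitivity_for(modality, params)
  spec <- specificity_for_round(modality, round_index, params)
  workup <- false_positive_workup(modality, round_index, params)
  out <- list(
    p_tp = prevalence * sens,
    p_fn = prevalence * (1 - sens),
    p_fp = (1 - prevalence) * (1 - spec),
    p_tn = (1 - prevalence) * spec,
    expected_screen_cost = switch(modality, XM = params$cost_xm,
                                  MRM = params$cost_mrm),
    expected_fp_workup_cost = workup$cost,
    expected_fp_qol_loss = workup$qol_loss
  )
  class(out) <- "round_outcome"
  out
}

#' @export
print.round_outcome <- function(x, ...) {
  cat("Screening round outcome fractions\n")
  cat(sprintf("  TP %.5f  FN %.5f  FP %.5f  TN %.5f\n",
              x$p_tp, x$p_fn, x$p_fp, x$p_tn))
  cat(sprintf("  screen cost $%.2f; E[workup cost | FP] $%.2f; QOL loss | FP %.3f\n",
              x$expected_screen_cost, x$expected_fp_workup_cost,
              x$expected_fp_qol_loss))
  invisible(x)
}
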