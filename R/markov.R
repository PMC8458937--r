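#' Public health states of the cohort model
#'
#' The model reports occupancy over eight health states: healthy,
#' undetected tumor, three detected stages (tumor < 1 cm, tumor > 1 cm,
#' advanced disease), two post-treatment states (after simple and after
#' intensive treatment) and death (absorbing).
#'
#' @return Character vector of the eight state names, in canonical order.
#' @export
health_states <- function() {
  c("HEALTHY", "UNDETECTED_TUMOR", "DETECTED_SMALL", "DETECTED_LARGE",
    "DETECTED_ADVANCED", "POST_SIMPLE_TX", "POST_INTENSIVE_TX", "DEAD")
}

# Internal engine state space. Dwell-time staging and the finite
# excess-mortality window are not Markov on the 8 public states, so the
# engine expands: undetected-tumor compartments U0..U<thr> track the number
# of missed screening rounds (the last compartment absorbs d >= thr), and
# each post-treatment state is a tunnel P<X>_k over years since detection
# k = 2..K (K = excess_risk_duration) followed by a P<X>_done state without
# excess risk. Public trajectories aggregate these back to 8 states.
.engine_states <- function(params) {
  thr <- params$advanced_dwell_threshold
  K <- params$excess_risk_duration
  u <- paste0("U", 0:thr)
  tunnels <- function(x) {
    k <- if (K >= 2) paste0("P", x, "_", 2:K) else character(0)
    c(k, paste0("P", x, "_done"))
  }
  states <- c("H", u, "DS", "DL", "DA",
              tunnels("S"), tunnels("L"), tunnels("A"), "DEAD")
  qol <- c(params$qol_healthy,
           rep(params$qol_healthy, length(u)),  # undetected: no detected tumor
           params$qol_small, params$qol_large, params$qol_advanced,
           rep(params$qol_post_simple, K),
           rep(params$qol_post_intensive, K),
           rep(params$qol_post_intensive, K),
           0)
  names(qol) <- states
  map <- c(HEALTHY = "H")
  public <- c("HEALTHY", rep("UNDETECTED_TUMOR", length(u)),
              "DETECTED_SMALL", "DETECTED_LARGE", "DETECTED_ADVANCED",
              rep("POST_SIMPLE_TX", K), rep("POST_INTENSIVE_TX", 2 * K),
              "DEAD")
  names(public) <- states
  list(states = states, n = length(states), u = u, thr = thr, K = K,
       qol = qol, public = public)
}

# stage split of a detection event at dwell d (missed rounds so far):
# returns c(small, large, advanced) fractions
.stage_split <- function(d, params) {
  thr <- params$advanced_dwell_threshold
  if (d == 0) {
    ps <- params$p_small_if_detected_within_interval
    c(ps, 1 - ps, 0)
  } else if (d < thr) {
    c(0, 1, 0)
  } else {
    c(0, 0, 1)
  }
}

#' Build the one-cycle transition matrix at a given age
#'
#' Encodes one annual cycle of the cohort model: breast-cancer onset at the
#' age-specific incidence probability, all-cause death at the age-specific
#' life-table probability combined with state-specific excess risks as
#' competing risks (`1 - (1 - q)(1 - e)`), screening detection of undetected
#' tumors (when `screening_event` is given) with stage assigned by dwell time,
#' symptomatic interval detection in non-screening cycles, and the treatment
#' pathway: small tumors to post-simple-treatment, large tumors to
#' post-intensive-treatment with probability `p_r0_large` and otherwise to the
#' advanced stage, advanced disease to post-intensive-treatment.
#'
#' @param age Age (years) of the cohort at the start of the cycle.
#' @param params A [cea_parameters()] object.
#' @param rates A list with `incidence` and `mortality` [rate_table()]s.
#' @param screening_event `NULL` for a non-screening cycle, else a list with
#'   elements `modality` (`"XM"`/`"MRM"`) and `round_index` (>= 1).
#' @return A row-stochastic square matrix over the engine states (dimnames
#'   give the state names); rows sum to 1 and `DEAD` is absorbing.
#' @export
build_transition_matrix <- function(age, params, rates,
                                    screening_event = NULL) {
  es <- .engine_states(params)
  q <- rate_lookup(rates$mortality, age)
  inc <- rate_lookup(rates$incidence, age)
  e_u <- annual_probability_from_cumulative(params$death_risk_undetected_cum,
                                            params$undetected_risk_span)
  e_stage <- c(S = params$death_small_annual, L = params$death_large_annual,
               A = params$death_advanced_annual)
  comp <- function(e) 1 - (1 - q) * (1 - e)

  M <- matrix(0, es$n, es$n, dimnames = list(es$states, es$states))

  # healthy: onset as competing event after surviving the cycle
  M["H", "DEAD"] <- q
  M["H", "U0"] <- (1 - q) * inc
  M["H", "H"] <- (1 - q) * (1 - inc)

  det_targets <- c("DS", "DL", "DA")
  thr <- es$thr
  for (d in 0:thr) {
    st <- paste0("U", d)
    die <- comp(e_u)
    surv <- 1 - die
    M[st, "DEAD"] <- die
    split <- .stage_split(d, params)
    if (!is.null(screening_event)) {
      sens <- .sensitivity_for(screening_event$modality, params)
      M[st, det_targets] <- M[st, det_targets] + surv * sens * split
      miss <- paste0("U", min(d + 1, thr))
      M[st, miss] <- M[st, miss] + surv * (1 - sens)
    } else {
      s <- params$interval_detection
      M[st, det_targets] <- M[st, det_targets] + surv * s * split
      M[st, st] <- M[st, st] + surv * (1 - s)
    }
  }

  first_post <- function(x) {
    if (es$K >= 2) paste0("P", x, "_2") else paste0("P", x, "_done")
  }
  # treatment-year states: one cycle, then on to post-treatment
  M["DS", "DEAD"] <- comp(e_stage["S"])
  M["DS", first_post("S")] <- (1 - M["DS", "DEAD"]) * params$p_r0_small
  M["DS", "DA"] <- (1 - M["DS", "DEAD"]) * (1 - params$p_r0_small)
  M["DL", "DEAD"] <- comp(e_stage["L"])
  M["DL", first_post("L")] <- (1 - M["DL", "DEAD"]) * params$p_r0_large
  M["DL", "DA"] <- (1 - M["DL", "DEAD"]) * (1 - params$p_r0_large)
  M["DA", "DEAD"] <- comp(e_stage["A"])
  M["DA", first_post("A")] <- 1 - M["DA", "DEAD"]

  for (x in c("S", "L", "A")) {
    if (es$K >= 2) {
      for (k in 2:es$K) {
        st <- paste0("P", x, "_", k)
        nxt <- if (k < es$K) paste0("P", x, "_", k + 1) else
          paste0("P", x, "_done")
        M[st, "DEAD"] <- comp(e_stage[x])
        M[st, nxt] <- 1 - M[st, "DEAD"]
      }
    }
    st <- paste0("P", x, "_done")
    M[st, "DEAD"] <- q
    M[st, st] <- 1 - q
  }

  M["DEAD", "DEAD"] <- 1
  M
}

#' Propagate a cohort occupancy vector one cycle
#'
#' @param occupancy Non-negative state-occupancy vector summing to 1, ordered
#'   as the matrix rows.
#' @param matrix A transition matrix from [build_transition_matrix()].
#' @return The next cycle's occupancy vector.
#' @export
advance_cohort <- function(occupancy, matrix) {
  if (length(occupancy) != nrow(matrix)) {
    stop("occupancy length does not match the transition matrix dimension")
  }
  as.numeric(occupancy %*% matrix)
}

#' Run one screening strategy through the cohort model
#'
#' Propagates the cohort over `horizon` annual cycles starting at
#' `params$start_age`. Screening rounds occur at cycles 0, `interval`,
#' `2 * interval`, ... up to the last cycle that leaves a full interval inside
#' the horizon (with the base-case 20-year horizon and 2-year interval: 10
#' rounds at cycles 0-18). Each cycle accrues discounted state utilities,
#' screening examination costs for women in the healthy and undetected states,
#' false-positive workup costs and one-cycle utility decrements for screened
#' disease-free women, and one-time treatment costs during the cycle spent in
#' a detected state. No half-cycle correction is applied.
#'
#' @param modality `"XM"` or `"MRM"`.
#' @param params A [cea_parameters()] object.
#' @param rates A list with `incidence` and `mortality` [rate_table()]s
#'   covering `[start_age, start_age + horizon]`.
#' @param horizon Model runtime in years; defaults to `params$horizon`.
#' @return An object of class `cohort_trajectory`: a list with `modality`,
#'   `total_cost` and `total_qaly` (cumulative discounted), and `trajectory`,
#'   a data frame with one row per cycle (cycle, age, occupancy of the eight
#'   public health states at cycle start, discounted cost and QALY increments,
#'   cumulative totals).
#' @export
#' @examples
#' traj <- run_strategy("XM", cea_parameters(), default_rates())
#' traj$total_cost
run_strategy <- function(modality, params, rates, horizon = params$horizon) {
  modality <- match.arg(modality, c("XM", "MRM"))
  params <- validate_parameters(params)
  if (horizon < 1 || horizon != round(horizon) ||
      horizon %% 1 != 0) {
    stop("horizon must be a positive whole number of annual cycles")
  }
  .check_coverage(rates$mortality, params$start_age, horizon, "mortality")
  .check_coverage(rates$incidence, params$start_age, horizon, "incidence")

  es <- .engine_states(params)
  interval <- params$screening_interval
  screen_cycles <- seq(0L, horizon - interval, by = interval)
  cost_exam <- switch(modality, XM = params$cost_xm, MRM = params$cost_mrm)
  tx_cost <- c(DS = params$cost_tx_small, DL = params$cost_tx_large,
               DA = params$cost_tx_advanced)

  v <- stats::setNames(numeric(es$n), es$states)
  v["H"] <- 1 - params$pretest_probability
  v["U0"] <- params$pretest_probability

  n_cycles <- horizon
  occ_pub <- matrix(0, n_cycles, 8,
                    dimnames = list(NULL, health_states()))
  cost_inc <- qaly_inc <- numeric(n_cycles)

  for (t in seq_len(n_cycles) - 1L) {
    df <- discount_factor(t, params$discount_rate)
    age <- params$start_age + t
    screening <- t %in% screen_cycles
    ev <- NULL
    ci <- sum(v[c("DS", "DL", "DA")] * tx_cost)
    qi <- sum(v * es$qol)
    if (screening) {
      round_index <- match(t, screen_cycles)
      ev <- list(modality = modality, round_index = round_index)
      spec <- specificity_for_round(modality, round_index, params)
      workup <- false_positive_workup(modality, round_index, params)
      fp_mass <- v["H"] * (1 - spec)
      screened <- v["H"] + sum(v[es$u])
      ci <- ci + screened * cost_exam + fp_mass * workup$cost
      qi <- qi - fp_mass * workup$qol_loss
    }
    cost_inc[t + 1L] <- ci * df
    qaly_inc[t + 1L] <- qi * df
    occ_pub[t + 1L, ] <- vapply(
      health_states(), function(s) sum(v[es$public == s]), numeric(1))

    M <- build_transition_matrix(age, params, rates, screening_event = ev)
    v <- stats::setNames(advance_cohort(v, M), es$states)
  }

  traj <- data.frame(cycle = seq_len(n_cycles) - 1L,
                     age = params$start_age + seq_len(n_cycles) - 1L,
                     occ_pub,
                     cost_inc = cost_inc, qaly_inc = qaly_inc,
                     cum_cost = cumsum(cost_inc), cum_qaly = cumsum(qaly_inc))
  out <- list(modality = modality,
              total_cost = sum(cost_inc),
              total_qaly = sum(qaly_inc),
              horizon = horizon,
              trajectory = traj)
  class(out) <- "cohort_trajectory"
  out
}

#' @export
print.cohort_trajectory <- function(x, ...) {
  cat(sprintf("Cohort trajectory: %s strategy, %d annual cycles\n",
              x$modality, x$horizon))
  cat(sprintf("  cumulative discounted cost:  $%.2f\n", x$total_cost))
  cat(sprintf("  cumulative discounted QALYs: %.4f\n", x$total_qaly))
  final <- x$trajectory[nrow(x$trajectory), ]
  cat(sprintf("  final-cycle occupancy: healthy %.3f, post-tx %.3f, dead %.3f\n",
              final$HEALTHY, final$POST_SIMPLE_TX + final$POST_INTENSIVE_TX,
              final$DEAD))
  invisible(x)
}

#' @export
as.data.frame.cohort_trajectory <- function(x, ...) x$trajectory
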