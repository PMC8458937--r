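# Vectorised cohort engine: propagates many parameter draws at once.
#
# The probabilistic sensitivity analysis runs the cohort model 2 x n_iter
# times. Rebuilding a transition matrix per cycle per draw would dominate the
# runtime, so this engine re-expresses the one-cycle update of
# build_transition_matrix() as direct vector arithmetic across draws: the
# occupancy of each engine state is a length-n vector and every transition is
# an element-wise operation. Structural parameters (state space, schedule,
# discounting) are fixed at their base values; a unit test pins this engine
# to the matrix-based run_strategy() on individual draws.

.run_strategy_batch <- function(modality, draws, base_params, rates,
                                horizon = base_params$horizon) {
  modality <- match.arg(modality, c("XM", "MRM"))
  p <- unclass(base_params)
  p[names(draws)] <- draws
  n <- max(vapply(p, length, integer(1)))

  thr <- base_params$advanced_dwell_threshold
  K <- base_params$excess_risk_duration
  interval <- base_params$screening_interval
  screen_cycles <- seq(0L, horizon - interval, by = interval)

  sens <- if (modality == "XM") p$sens_xm else p$sens_mrm
  cost_exam <- if (modality == "XM") p$cost_xm else p$cost_mrm
  e_u <- annual_probability_from_cumulative(p$death_risk_undetected_cum,
                                            base_params$undetected_risk_span)
  zero <- numeric(n)

  # occupancy, one vector per engine state
  U <- lapply(0:thr, function(d) zero)
  H <- 1 - p$pretest_probability + zero
  U[[1]] <- p$pretest_probability + zero
  DS <- DL <- DA <- zero
  PS <- PL <- PA <- lapply(seq_len(max(K - 1, 0)), function(k) zero)
  PSd <- PLd <- PAd <- zero  # post-excess-window states
  DEAD <- zero

  cost <- qaly <- zero
  ps_small <- p$p_small_if_detected_within_interval

  for (t in seq_len(horizon) - 1L) {
    dfac <- discount_factor(t, base_params$discount_rate)
    age <- base_params$start_age + t
    q <- rate_lookup(rates$mortality, age)
    inc <- rate_lookup(rates$incidence, age)
    surv_u <- (1 - q) * (1 - e_u)
    surv_S <- (1 - q) * (1 - p$death_small_annual)
    surv_L <- (1 - q) * (1 - p$death_large_annual)
    surv_A <- (1 - q) * (1 - p$death_advanced_annual)

    screening <- t %in% screen_cycles
    usum <- Reduce(`+`, U)

    # --- accrual on start-of-cycle occupancy
    ci <- DS * p$cost_tx_small + DL * p$cost_tx_large + DA * p$cost_tx_advanced
    qi <- (H + usum) * p$qol_healthy + DS * p$qol_small + DL * p$qol_large +
      DA * p$qol_advanced +
      (Reduce(`+`, PS, accumulate = FALSE) %||% 0 + PSd) * p$qol_post_simple +
      ((Reduce(`+`, PL) %||% 0) + PLd + (Reduce(`+`, PA) %||% 0) + PAd) *
        p$qol_post_intensive
    if (screening) {
      r <- match(t, screen_cycles)
      spec <- if (modality == "XM") p$spec_xm else
        if (r == 1) p$spec_mrm_round1 else p$spec_mrm_later
      brate <- if (r == 1) p$biopsy_rate_fp_round1 else p$biopsy_rate_fp_later
      workup <- if (modality == "XM") p$cost_biopsy else
        brate * p$cost_biopsy + (1 - brate) * p$cost_mrm
      fp <- H * (1 - spec)
      ci <- ci + (H + usum) * cost_exam + fp * workup
      qi <- qi - fp * p$qol_fp_decrement
    }
    cost <- cost + ci * dfac
    qaly <- qaly + qi * dfac

    # --- transition
    small_in <- large_in <- adv_in <- zero
    U_next <- lapply(0:thr, function(d) zero)
    if (screening) {
      for (d in 0:thr) {
        det <- U[[d + 1]] * surv_u * sens
        if (d == 0) {
          small_in <- small_in + det * ps_small
          large_in <- large_in + det * (1 - ps_small)
        } else if (d < thr) {
          large_in <- large_in + det
        } else {
          adv_in <- adv_in + det
        }
        tgt <- min(d + 1, thr) + 1
        U_next[[tgt]] <- U_next[[tgt]] + U[[d + 1]] * surv_u * (1 - sens)
      }
    } else {
      s <- p$interval_detection
      for (d in 0:thr) {
        det <- U[[d + 1]] * surv_u * s
        if (d == 0) {
          small_in <- small_in + det * ps_small
          large_in <- large_in + det * (1 - ps_small)
        } else if (d < thr) {
          large_in <- large_in + det
        } else {
          adv_in <- adv_in + det
        }
        U_next[[d + 1]] <- U_next[[d + 1]] + U[[d + 1]] * surv_u * (1 - s)
      }
    }
    died <- H * q + usum - Reduce(`+`, lapply(U, function(u) u * surv_u)) +
      DS * (1 - surv_S) + DL * (1 - surv_L) + DA * (1 - surv_A)

    DA_next <- adv_in + DL * surv_L * (1 - p$p_r0_large) +
      DS * surv_S * (1 - p$p_r0_small)
    ps_in <- DS * surv_S * p$p_r0_small
    pl_in <- DL * surv_L * p$p_r0_large
    pa_in <- DA * surv_A

    step_tunnel <- function(tun, done, inflow, surv) {
      died_t <- 0
      if (length(tun)) {
        died_t <- Reduce(`+`, lapply(tun, function(v) v * (1 - surv)))
        last <- tun[[length(tun)]] * surv
        if (length(tun) > 1) {
          for (k in seq(length(tun), 2)) tun[[k]] <- tun[[k - 1]] * surv
        }
        tun[[1]] <- inflow
        done_next <- done * (1 - q) + last
      } else {
        done_next <- done * (1 - q) + inflow
      }
      list(tun = tun, done = done_next, died = died_t + done * q)
    }
    sS <- step_tunnel(PS, PSd, ps_in, surv_S)
    sL <- step_tunnel(PL, PLd, pl_in, surv_L)
    sA <- step_tunnel(PA, PAd, pa_in, surv_A)

    onset <- H * (1 - q) * inc
    H <- H * (1 - q) * (1 - inc)
    U_next[[1]] <- U_next[[1]] + onset
    DEAD <- DEAD + died + sS$died + sL$died + sA$died
    U <- U_next
    DS <- small_in; DL <- large_in; DA <- DA_next
    PS <- sS$tun; PSd <- sS$done
    PL <- sL$tun; PLd <- sL$done
    PA <- sA$tun; PAd <- sA$done
  }
  list(cost = cost, qaly = qaly)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
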