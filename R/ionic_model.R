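#' Slow delayed rectifier current
#'
#' `I_Ks = g_Ks_base * g_Ks_scale * x_s^2 * (V_m - E_Ks)`, positive outward.
#' `E_Ks` is the reversal potential with Na+ permeation
#' (`p_KNa = 0.03`).
#'
#' @param state myocyte state vector (see [cell_state_init]).
#' @param params a [cell_params] object.
#' @return current density, uA/uF.
#' @examples
#' s <- cell_state_init()
#' p <- cell_params("epi")
#' compute_iks(s, p)
#' @export
compute_iks <- function(state, params) {
  .check_state(state)
  RTF <- params$R_gas * params$Temp / params$F
  eks <- RTF * log((params$K_o + params$p_KNa * params$Na_o) /
                   (state[["K_i"]] + params$p_KNa * state[["Na_i"]]))
  unname(.gks_total(params) * state[["xs"]]^2 * (state[["V_m"]] - eks))
}

# all 12 membrane currents, written independently of the compiled stepper
# so the two routes can cross-check each other
.currents_r <- function(state, p) {
  V <- state[["V_m"]]; Ki <- state[["K_i"]]; Nai <- state[["Na_i"]]
  Cai <- state[["Ca_i"]]; Cass <- state[["Ca_ss"]]
  RTF <- p$R_gas * p$Temp / p$F
  Ek <- RTF * log(p$K_o / Ki)
  Ena <- RTF * log(p$Na_o / Nai)
  Eca <- 0.5 * RTF * log(p$Ca_o / Cai)

  INa <- p$g_Na * state[["m"]]^3 * state[["h"]] * state[["j"]] * (V - Ena)

  ak1 <- 0.1 / (1 + exp(0.06 * (V - Ek - 200)))
  bk1 <- (3 * exp(2e-4 * (V - Ek + 100)) + exp(0.1 * (V - Ek - 10))) /
         (1 + exp(-0.5 * (V - Ek)))
  IK1 <- p$g_K1 * ak1 / (ak1 + bk1) * (V - Ek)

  Ito <- p$g_to * state[["r"]] * state[["s"]] * (V - Ek)
  IKr <- p$g_Kr * sqrt(p$K_o / 5.4) * state[["xr1"]] * state[["xr2"]] *
         (V - Ek)
  IKs <- compute_iks(state, p)

  vf <- (V - 15) * p$F / (p$R_gas * p$Temp)
  drv <- if (abs(vf) < 1e-7) {
    2 * p$F * (0.25 * Cass - p$Ca_o) * (1 - vf)
  } else {
    4 * (V - 15) * p$F^2 / (p$R_gas * p$Temp) *
      (0.25 * Cass * exp(2 * vf) - p$Ca_o) / (exp(2 * vf) - 1)
  }
  ICaL <- p$g_CaL * state[["d"]] * state[["f"]] * state[["f2"]] *
          state[["fCass"]] * drv

  ev <- exp(p$gamma_ncx * V * p$F / (p$R_gas * p$Temp))
  ev1 <- exp((p$gamma_ncx - 1) * V * p$F / (p$R_gas * p$Temp))
  INaCa <- p$k_NaCa *
    (ev * Nai^3 * p$Ca_o - ev1 * p$Na_o^3 * Cai * 2.5) /
    ((p$K_mNai^3 + p$Na_o^3) * (p$K_mCa + p$Ca_o) * (1 + p$k_sat * ev1))

  INaK <- p$P_NaK * p$K_o * Nai /
    ((p$K_o + p$K_mK) * (Nai + p$K_mNa) *
     (1 + 0.1245 * exp(-0.1 * V * p$F / (p$R_gas * p$Temp)) +
      0.0353 * exp(-V * p$F / (p$R_gas * p$Temp))))

  IpCa <- p$g_pCa * Cai / (Cai + p$K_pCa)
  IpK <- p$g_pK * (V - Ek) / (1 + exp((25 - V) / 5.98))
  IbCa <- p$g_bCa * (V - Eca)
  IbNa <- p$g_bNa * (V - Ena)

  c(I_Na = unname(INa), I_K1 = unname(IK1), I_to = unname(Ito),
    I_Kr = unname(IKr), I_Ks = IKs, I_CaL = unname(ICaL),
    I_NaCa = unname(INaCa), I_NaK = unname(INaK), I_pCa = unname(IpCa),
    I_pK = unname(IpK), I_bCa = unname(IbCa), I_bNa = unname(IbNa))
}

#' Membrane currents
#'
#' Computes the 12 labeled transmembrane current densities and their sum
#' `I_ion = I_Na + I_K1 + I_to + I_Kr + I_Ks + I_CaL + I_NaCa + I_NaK +
#' I_pCa + I_pK + I_bCa + I_bNa`.
#'
#' @inheritParams compute_iks
#' @return named numeric vector of the 12 components plus `I_ion`, uA/uF
#'   (positive outward).
#' @export
compute_ion_currents <- function(state, params) {
  .check_state(state)
  cur <- .currents_r(state, params)
  c(cur, I_ion = sum(cur))
}

#' Sarcoplasmic reticulum calcium fluxes
#'
#' Leak, SERCA uptake and CICR release of the Ca subsystem:
#' `I_leak = V_leak (Ca_sr - Ca_i)`, `I_up = V_maxup / (1 + K_up^2/Ca_i^2)`
#' (half-saturated at `Ca_i = K_up`), and release
#' `I_rel = V_rel * O * (Ca_sr - Ca_ss)` gated by the open fraction `O` of
#' the SR release channel (Ca_ss- and SR-load dependent).
#'
#' @inheritParams compute_iks
#' @return named numeric vector `c(I_leak, I_up, I_rel)` in mM/ms.
#' @export
calcium_fluxes <- function(state, params) {
  .check_state(state)
  Cai <- state[["Ca_i"]]; Casr <- state[["Ca_sr"]]; Cass <- state[["Ca_ss"]]
  if (Cai <= 0 || Casr <= 0 || Cass <= 0)
    stop("calcium concentrations must be positive")
  p <- params
  kcasr <- p$max_sr - (p$max_sr - p$min_sr) / (1 + (p$EC_sr / Casr)^2)
  k1 <- p$k1_rel / kcasr
  O <- k1 * Cass^2 * state[["Rbar"]] / (p$k3_rel + k1 * Cass^2)
  c(I_leak = unname(p$V_leak * (Casr - Cai)),
    I_up = unname(p$V_maxup / (1 + p$K_up^2 / Cai^2)),
    I_rel = unname(p$V_rel * O * (Casr - Cass)))
}

#' Advance the myocyte state
#'
#' One (or `n`) fixed steps of the production integrator: Rush-Larsen
#' exponential updates for the gating variables, forward Euler for membrane
#' potential and concentrations with analytic rapid-buffering updates for
#' the three Ca pools.  `dV_m/dt = -(I_ion + I_stim)/C_m`.
#'
#' @inheritParams compute_iks
#' @param I_stim stimulus current density, uA/uF (negative = depolarizing).
#' @param dt step size, ms; 0.02 ms is the validated default (halving it
#'   moves APD90 by well under 0.5 ms).
#' @param n number of steps.
#' @return the advanced state vector.
#' @export
step_state <- function(state, params, I_stim = 0, dt = 0.02, n = 1L) {
  .check_state(state)
  out <- cpp_cell_step_n(state, .celltype_int(params), .gks_total(params),
                         I_stim, dt, as.integer(n))
  gates <- c("m", "h", "j", "xr1", "xr2", "xs", "r", "s", "d", "f", "f2",
             "fCass", "Rbar")
  g <- out[gates]
  if (any(g < -1e-12 | g > 1 + 1e-12))
    stop("gating variable left [0,1]: ", gates[which(g < 0 | g > 1)[1]])
  out
}

#' Full model right-hand side (deSolve form)
#'
#' Time derivatives of all 19 state variables in the signature
#' `function(t, y, parms)` expected by [deSolve::ode()].  This pure-R route
#' is integrated with an adaptive stiff solver and serves as the
#' independent cross-check of the compiled fixed-step integrator; the two
#' share the published constant set but no code.
#'
#' @param t time, ms (used only for the stimulus window in `parms$stim`).
#' @param y named state vector.
#' @param parms list with elements `params` (a [cell_params]) and
#'   optionally `stim = list(amplitude, duration, offset, BCL)`.
#' @return `list(dy)` as deSolve requires.
#' @export
ttp_derivs <- function(t, y, parms) {
  p <- parms$params
  Istim <- if (is.null(parms$I_stim)) 0 else parms$I_stim
  V <- y[["V_m"]]
  cur <- .currents_r(y, p)
  fl <- calcium_fluxes(y, p)
  Cai <- y[["Ca_i"]]; Cass <- y[["Ca_ss"]]; Casr <- y[["Ca_sr"]]

  ixfer <- p$V_xfer * (Cass - Cai)
  kcasr <- p$max_sr - (p$max_sr - p$min_sr) / (1 + (p$EC_sr / Casr)^2)
  k2 <- p$k2_rel * kcasr
  dRbar <- p$k4_rel * (1 - y[["Rbar"]]) - k2 * Cass * y[["Rbar"]]

  bufc <- 1 / (1 + p$Buf_c * p$K_bufc / (Cai + p$K_bufc)^2)
  bufsr <- 1 / (1 + p$Buf_sr * p$K_bufsr / (Casr + p$K_bufsr)^2)
  bufss <- 1 / (1 + p$Buf_ss * p$K_bufss / (Cass + p$K_bufss)^2)

  dCai <- bufc * (-(cur[["I_bCa"]] + cur[["I_pCa"]] - 2 * cur[["I_NaCa"]]) *
                    p$C_m / (2 * p$V_c * p$F) -
                  (fl[["I_up"]] - fl[["I_leak"]]) * p$V_sr / p$V_c + ixfer)
  dCasr <- bufsr * (fl[["I_up"]] - fl[["I_rel"]] - fl[["I_leak"]])
  dCass <- bufss * (-cur[["I_CaL"]] * p$C_m / (2 * p$V_ss * p$F) +
                    fl[["I_rel"]] * p$V_sr / p$V_ss -
                    ixfer * p$V_c / p$V_ss)
  dNai <- -(cur[["I_Na"]] + cur[["I_bNa"]] + 3 * cur[["I_NaK"]] +
            3 * cur[["I_NaCa"]]) * p$C_m / (p$V_c * p$F)
  dKi <- -(Istim + cur[["I_K1"]] + cur[["I_to"]] + cur[["I_Kr"]] +
           cur[["I_Ks"]] - 2 * cur[["I_NaK"]] + cur[["I_pK"]]) *
         p$C_m / (p$V_c * p$F)

  g <- .gate_kinetics(V, Cass, p$cell_type)
  dgates <- (g$inf - y[g$names]) / g$tau

  dV <- -(sum(cur) + Istim)
  dy <- c(dV, dKi, dNai, dCai, dCass, dCasr, dgates[1:13])
  dy[names(y) == "Rbar"] <- dRbar
  list(dy)
}

# steady states and time constants for the 13 gate-like variables
.gate_kinetics <- function(V, Cass, cell_type) {
  m_inf <- 1 / (1 + exp((-56.86 - V) / 9.03))^2
  tau_m <- (1 / (1 + exp((-60 - V) / 5))) *
           (0.1 / (1 + exp((V + 35) / 5)) + 0.1 / (1 + exp((V - 50) / 200)))
  h_inf <- 1 / (1 + exp((V + 71.55) / 7.43))^2
  if (V >= -40) {
    tau_h <- 0.1688 * (1 + exp(-(V + 10.66) / 11.1))
  } else {
    ah <- 0.057 * exp(-(V + 80) / 6.8)
    bh <- 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V)
    tau_h <- 1 / (ah + bh)
  }
  j_inf <- h_inf
  if (V >= -40) {
    tau_j <- (1 + exp(-0.1 * (V + 32))) / (0.6 * exp(0.057 * V))
  } else {
    aj <- (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
          (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
    bj <- 0.02424 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
    tau_j <- 1 / (aj + bj)
  }
  xr1_inf <- 1 / (1 + exp((-26 - V) / 7))
  tau_xr1 <- 450 / (1 + exp((-45 - V) / 10)) * 6 / (1 + exp((V + 30) / 11.5))
  xr2_inf <- 1 / (1 + exp((V + 88) / 24))
  tau_xr2 <- 3 / (1 + exp((-60 - V) / 20)) * 1.12 / (1 + exp((V - 60) / 20))
  xs_inf <- 1 / (1 + exp((-5 - V) / 14))
  tau_xs <- 1400 / sqrt(1 + exp((5 - V) / 6)) / (1 + exp((V - 35) / 15)) + 80
  r_inf <- 1 / (1 + exp((20 - V) / 6))
  tau_r <- 9.5 * exp(-(V + 40)^2 / 1800) + 0.8
  if (cell_type == "endo") {
    s_inf <- 1 / (1 + exp((V + 28) / 5))
    tau_s <- 1000 * exp(-(V + 67)^2 / 1000) + 8
  } else {
    s_inf <- 1 / (1 + exp((V + 20) / 5))
    tau_s <- 85 * exp(-(V + 45)^2 / 320) + 5 / (1 + exp((V - 20) / 5)) + 3
  }
  d_inf <- 1 / (1 + exp((-8 - V) / 7.5))
  tau_d <- (1.4 / (1 + exp((-35 - V) / 13)) + 0.25) *
           (1.4 / (1 + exp((V + 5) / 5))) + 1 / (1 + exp((50 - V) / 20))
  f_inf <- 1 / (1 + exp((V + 20) / 7))
  tau_f <- 1102.5 * exp(-(V + 27)^2 / 225) + 200 / (1 + exp((13 - V) / 10)) +
           180 / (1 + exp((V + 30) / 10)) + 20
  f2_inf <- 0.67 / (1 + exp((V + 35) / 7)) + 0.33
  tau_f2 <- 562 * exp(-(V + 27)^2 / 240) + 31 / (1 + exp((25 - V) / 10)) +
            80 / (1 + exp((V + 30) / 10))
  fca_inf <- 0.6 / (1 + (Cass / 0.05)^2) + 0.4
  tau_fca <- 80 / (1 + (Cass / 0.05)^2) + 2

  list(names = c("m", "h", "j", "xr1", "xr2", "xs", "r", "s", "d", "f",
                 "f2", "fCass", "Rbar"),
       inf = c(m_inf, h_inf, j_inf, xr1_inf, xr2_inf, xs_inf, r_inf, s_inf,
               d_inf, f_inf, f2_inf, fca_inf, NA),
       tau = c(tau_m, tau_h, tau_j, tau_xr1, tau_xr2, tau_xs, tau_r, tau_s,
               tau_d, tau_f, tau_f2, tau_fca, NA))
}

#' One paced beat via the adaptive stiff reference route
#'
#' Integrates the pure-R right-hand side ([ttp_derivs]) with
#' [deSolve::lsoda()] at tight tolerance.  Used as the in-package reference
#' for the compiled fixed-step integrator (the two trace sets must agree to
#' about a millivolt); far too slow for production pacing.
#'
#' The stimulus window is integrated as its own segment with a constant
#' current so the adaptive solver cannot step over the 1-ms pulse.
#'
#' @param state initial state (named vector).
#' @param params a [cell_params] object.
#' @param protocol a [pacing_protocol]; one cycle is integrated, with the
#'   stimulus delivered at its in-cycle offset.
#' @param rtol,atol solver tolerances.
#' @param record_dt output grid spacing, ms.
#' @return data.frame with `time` and the 19 state columns.
#' @export
simulate_beat_lsoda <- function(state, params, protocol = pacing_protocol(),
                                rtol = 1e-6, atol = 1e-9, record_dt = 0.5) {
  t0 <- protocol$stim_start_offset
  t1 <- t0 + protocol$stim_duration
  segs <- list(
    if (t0 > 0) list(times = seq(0, t0, by = min(record_dt, t0)), I = 0),
    list(times = seq(t0, t1, by = min(record_dt, protocol$stim_duration)),
         I = protocol$stim_amplitude),
    list(times = unique(c(seq(t1, protocol$BCL, by = record_dt),
                          protocol$BCL)), I = 0))
  segs <- segs[!vapply(segs, is.null, logical(1))]
  y <- state
  pieces <- list()
  for (k in seq_along(segs)) {
    parms <- list(params = params, I_stim = segs[[k]]$I)
    out <- deSolve::lsoda(y = y, times = segs[[k]]$times, func = ttp_derivs,
                          parms = parms, rtol = rtol, atol = atol,
                          maxsteps = 100000)
    y <- out[nrow(out), -1]
    y <- stats::setNames(as.numeric(y), colnames(out)[-1])
    df <- as.data.frame(out)
    pieces[[k]] <- if (k < length(segs)) df[-nrow(df), , drop = FALSE] else df
  }
  do.call(rbind, pieces)
}
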