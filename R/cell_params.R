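#' Ventricular cell parameters
#'
#' Builds the parameter set of the ten Tusscher-Panfilov (2006) human
#' ventricular myocyte model for one of the three transmural cell types.
#' The slow delayed rectifier conductance is the protocol dial: the total
#' conductance used in `I_Ks = g_Ks x_s^2 (V - E_Ks)` is
#' `g_Ks_base * g_Ks_scale`, where `g_Ks_base` already carries the 1.3x
#' augmentation of the baseline protocol (0.392 x 1.3 mS/uF for
#' endo/epi, 0.098 x 1.3 mS/uF for the M cell) and `g_Ks_scale` is the
#' fold-increase applied on top (1, 2, 4, 6, 8, 10 in the sweep).
#'
#' All other maximal conductances, fluxes and Ca-subsystem constants are the
#' published constants of the 2006 model and are reported here so that the
#' pure-R right-hand side ([ttp_derivs]) and the compiled integrator share
#' one documented set.  Units: mV, ms, mM, uA/uF.
#'
#' @param cell_type one of `"endo"`, `"M"`, `"epi"`.
#' @param g_Ks_scale dimensionless multiplier on the baseline IKs
#'   conductance; any positive value is accepted (the study protocol uses
#'   1, 2, 4, 6, 8, 10).
#' @param g_Ks_base baseline conductance in mS/uF, default `0.392 * 1.3`
#'   (endo/epi) or `0.098 * 1.3` (M).
#' @return an object of class `cell_params` (a named list).
#' @examples
#' p <- cell_params("endo", g_Ks_scale = 2)
#' p$g_Ks_base * p$g_Ks_scale   # total IKs conductance, mS/uF
#' @export
cell_params <- function(cell_type = c("endo", "M", "epi"),
                        g_Ks_scale = 1,
                        g_Ks_base = NULL) {
  cell_type <- match.arg(cell_type)
  if (!is.numeric(g_Ks_scale) || length(g_Ks_scale) != 1L ||
      !is.finite(g_Ks_scale) || g_Ks_scale <= 0)
    stop("g_Ks_scale must be a single positive number")
  if (is.null(g_Ks_base))
    g_Ks_base <- if (cell_type == "M") 0.098 * 1.3 else 0.392 * 1.3
  if (g_Ks_base <= 0) stop("g_Ks_base must be positive")

  p <- list(
    cell_type = cell_type,
    g_Ks_base = g_Ks_base,
    g_Ks_scale = g_Ks_scale,
    C_m = 0.185,                 # uF (whole-cell capacitance scale)
    # maximal conductances (mS/uF) and pump/exchanger scales
    g_Na = 14.838, g_K1 = 5.405,
    g_to = if (cell_type == "endo") 0.073 else 0.294,
    g_Kr = 0.153, g_CaL = 3.980e-5,
    k_NaCa = 1000, P_NaK = 2.724,
    g_pCa = 0.1238, g_pK = 0.0146, g_bCa = 0.000592, g_bNa = 0.00029,
    # exchanger / pump constants
    K_mNai = 87.5, K_mCa = 1.38, k_sat = 0.1, gamma_ncx = 0.35,
    K_mK = 1.0, K_mNa = 40.0, K_pCa = 0.0005, p_KNa = 0.03,
    # external concentrations (mM)
    K_o = 5.4, Na_o = 140, Ca_o = 2,
    # Ca subsystem (SR release/uptake/leak, subspace transfer)
    V_leak = 0.00036, V_maxup = 0.006375, K_up = 0.00025,
    V_rel = 0.102, k1_rel = 0.15, k2_rel = 0.045, k3_rel = 0.060,
    k4_rel = 0.005, EC_sr = 1.5, max_sr = 2.5, min_sr = 1.0,
    V_xfer = 0.0038,
    # buffering
    Buf_c = 0.2, K_bufc = 0.001, Buf_sr = 10, K_bufsr = 0.3,
    Buf_ss = 0.4, K_bufss = 0.00025,
    # geometry and physical constants
    V_c = 0.016404, V_sr = 0.001094, V_ss = 5.468e-5,
    F = 96485.3415, R_gas = 8314.472, Temp = 310
  )
  num <- vapply(p[-1], function(x) is.numeric(x) && all(x > 0 | is.finite(x)),
                logical(1))
  if (!all(num)) stop("all numeric cell parameters must be finite")
  class(p) <- "cell_params"
  p
}

#' @export
print.cell_params <- function(x, ...) {
  cat("<cell_params> ten Tusscher-Panfilov 2006,", x$cell_type, "cell\n")
  cat(sprintf("  g_Ks = %.4f mS/uF (base %.4f x scale %g)\n",
              x$g_Ks_base * x$g_Ks_scale, x$g_Ks_base, x$g_Ks_scale))
  invisible(x)
}

.celltype_int <- function(p) {
  match(p$cell_type, c("endo", "M", "epi")) - 1L
}

.gks_total <- function(p) p$g_Ks_base * p$g_Ks_scale

#' Pacing protocol
#'
#' Fixed-cycle-length stimulation settings.  Defaults follow the study
#' protocol: basic cycle length 600 ms, 50 conditioning beats, a 1-ms
#' depolarizing stimulus of -52 uA/uF (about twice diastolic threshold)
#' delivered at the start of every cycle.
#'
#' @param BCL basic cycle length, ms.
#' @param n_beats number of paced beats before measurement.
#' @param stim_amplitude stimulus current density, uA/uF (negative =
#'   depolarizing by the `dV/dt = -(I_ion + I_stim)/C_m` sign convention).
#' @param stim_duration stimulus duration, ms.
#' @param stim_start_offset delay of the stimulus within each cycle, ms.
#' @return an object of class `pacing_protocol`.
#' @export
pacing_protocol <- function(BCL = 600, n_beats = 50, stim_amplitude = -52,
                            stim_duration = 1, stim_start_offset = 0) {
  if (!(BCL > stim_duration && stim_duration > 0))
    stop("require BCL > stim_duration > 0")
  if (n_beats < 1) stop("n_beats must be >= 1")
  if (stim_start_offset < 0 || stim_start_offset + stim_duration >= BCL)
    stop("stimulus window must lie inside the cycle")
  structure(list(BCL = BCL, n_beats = as.integer(n_beats),
                 stim_amplitude = stim_amplitude,
                 stim_duration = stim_duration,
                 stim_start_offset = stim_start_offset),
            class = "pacing_protocol")
}

#' Initial (resting) state of the myocyte model
#'
#' Published resting initial conditions; pacing to steady state removes any
#' dependence on these within the conditioning beats.
#'
#' @return named numeric vector of the 19 state variables: `V_m` (mV),
#'   `K_i`, `Na_i`, `Ca_i`, `Ca_ss`, `Ca_sr` (mM), and the 13 dimensionless
#'   gates.
#' @export
cell_state_init <- function() {
  cpp_state_init()
}

.check_state <- function(state) {
  if (length(state) != 19L)
    stop("state must be the 19-component myocyte state vector")
  if (!all(is.finite(state)))
    stop("solver divergence: non-finite state component '",
         names(state)[which(!is.finite(state))[1]], "'")
  invisible(state)
}
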