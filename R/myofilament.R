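#' Sarcomere / crossbridge parameters
#'
#' Constants of the four-state crossbridge scheme (nonpermissive `N_xb`,
#' permissive `P_xb`, prerotated bound `XB_PreR`, post-rotation bound
#' `XB_PostR`) and of the sarcomere-length dynamics
#' `dSL/dt = (Integral_Force + (SL_0 - SL) * viscosity) / mass` with
#' series-elastic afterload `F_afterload = KSE * (SL - SL_0)`.
#'
#' Regulatory (thin-filament) switching follows the steep power law
#' `N -> P` at rate `K_np * TCa_Tot^n_exp` and `P -> N` at
#' `K_pn * TCa_Tot^-n_exp` with `n_exp = 7.5`; `K_np/K_pn = 2^(2 n_exp)`
#' places the permissive/nonpermissive equilibrium switch at
#' `TCa_Tot = 0.5`.  Cycling rates (`f_aapT` attachment, `g_aapT` reverse,
#' `h_fT`/`h_bT` rotation, `g_xbT` ATP-consuming detachment) and the
#' mechanical constants are adapted from the published Rice-model set.
#' Rates are 1/ms; strains and lengths in um; forces normalized so that a
#' fully permissive steady state bears unit active force.
#'
#' @param mode contraction mode: `"isosarcometric"` (fixed SL, the pipeline
#'   default), `"isometric"` (SL moves against the series elastic element),
#'   or `"isotonic"` (afterload fixed at `F_afterload_fixed` after release).
#' @param SL_0 initial/resting sarcomere length, um.
#' @param K_np,K_pn,n_exp regulatory power-law rates (1/ms) and exponent.
#' @param f_aapT,g_aapT,h_fT,h_bT,g_xbT crossbridge cycle rates, 1/ms.
#' @param kon,koff troponin Ca binding on-rate (1/(mM ms)) and off-rate
#'   (1/ms); Kd = koff/kon = 0.6 uM.
#' @param x0 power-stroke strain, um.
#' @param phi strain-kinetic mixing factor.
#' @param viscosity,mass,KSE mechanical constants of the SL equation
#'   (normalized-force ms/um, normalized-force ms^2/um, normalized
#'   force/um).
#' @param SL_rest zero-crossing of the passive force curve, um.
#' @param PCon,PExp passive (titin-like) exponential force constants.
#' @param F_afterload_fixed afterload held after release in isotonic mode.
#' @return an object of class `sarcomere_params`.
#' @export
sarcomere_params <- function(mode = c("isosarcometric", "isometric",
                                      "isotonic"),
                             SL_0 = 1.9,
                             K_np = 1.5, K_pn = 1.5 / 2^15, n_exp = 7.5,
                             f_aapT = 0.5, g_aapT = 0.07, h_fT = 2.0,
                             h_bT = 0.4, g_xbT = 0.07,
                             kon = 40, koff = 0.024,
                             x0 = 0.007, phi = 2,
                             viscosity = 0.003, mass = 5e-5, KSE = 50,
                             SL_rest = 1.9, PCon = 0.002, PExp = 10,
                             F_afterload_fixed = 0) {
  mode <- match.arg(mode)
  vals <- c(SL_0 = SL_0, K_np = K_np, K_pn = K_pn, n_exp = n_exp,
            f_aapT = f_aapT, g_aapT = g_aapT, h_fT = h_fT, h_bT = h_bT,
            g_xbT = g_xbT, kon = kon, koff = koff, x0 = x0, phi = phi,
            viscosity = viscosity, mass = mass, KSE = KSE,
            SL_rest = SL_rest, PCon = PCon, PExp = PExp)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all rate and mechanical constants must be positive")
  p <- as.list(vals)
  p$mode <- mode
  p$F_afterload_fixed <- F_afterload_fixed
  class(p) <- "sarcomere_params"
  p
}

# flat named vector for the compiled stepper
.xb_par_vec <- function(p) {
  c(kon = p$kon, koff = p$koff, K_np = p$K_np, K_pn = p$K_pn,
    n_exp = p$n_exp, f_aapT = p$f_aapT, g_aapT = p$g_aapT, h_fT = p$h_fT,
    h_bT = p$h_bT, g_xbT = p$g_xbT, x0 = p$x0, phi = p$phi,
    viscosity = p$viscosity, mass = p$mass, KSE = p$KSE, SL_0 = p$SL_0,
    SL_rest = p$SL_rest, PCon = p$PCon, PExp = p$PExp,
    mode = match(p$mode, c("isosarcometric", "isometric", "isotonic")) - 1,
    F_afterload_fixed = p$F_afterload_fixed)
}

# steady-state duty fractions of the attached cycle at full permissiveness
.duty_fractions <- function(p) {
  D <- p$g_aapT * p$h_bT + p$g_aapT * p$g_xbT + p$h_fT * p$g_xbT +
       p$f_aapT * (p$h_bT + p$g_xbT) + p$f_aapT * p$h_fT
  c(pre = p$f_aapT * (p$h_bT + p$g_xbT) / D,
    post = p$f_aapT * p$h_fT / D)
}

#' Initial crossbridge state
#'
#' Relaxed state: all regulatory units nonpermissive, no bound bridges,
#' troponin equilibrated with diastolic Ca, strains at their relaxed fixed
#' points, SL at `SL_0`.
#'
#' @param params a [sarcomere_params] object.
#' @param ca_dia diastolic Ca used to equilibrate troponin, mM.
#' @return named numeric state vector of 9 components: `TCa_Tot`, `N_xb`,
#'   `P_xb`, `XB_PreR`, `XB_PostR`, `xXB_PreR`, `xXB_PostR`, `SL`, `F_int`.
#' @export
xb_state_init <- function(params, ca_dia = 7e-5) {
  tca <- params$kon * ca_dia / (params$kon * ca_dia + params$koff)
  c(TCa_Tot = tca, N_xb = 1, P_xb = 0, XB_PreR = 0, XB_PostR = 0,
    xXB_PreR = 0, xXB_PostR = params$x0, SL = params$SL_0, F_int = 0)
}

#' Regulatory and cycling transition rates
#'
#' Evaluates the state-dependent regulatory rates
#' `k_np = K_np * TCa_Tot^n_exp` and `k_pn = K_pn * TCa_Tot^-n_exp`
#' together with the constant cycling rates.
#'
#' @param state crossbridge state vector (see [xb_state_init]).
#' @param params a [sarcomere_params] object.
#' @return named numeric vector of rates, 1/ms.
#' @export
transition_rates <- function(state, params) {
  tca <- state[["TCa_Tot"]]
  if (!is.finite(tca) || tca <= 0)
    stop("TCa_Tot must be positive (the backward power-law rate diverges)")
  c(k_np = unname(params$K_np * tca^params$n_exp),
    k_pn = unname(params$K_pn * tca^-params$n_exp),
    f_aapT = params$f_aapT, g_aapT = params$g_aapT,
    h_fT = params$h_fT, h_bT = params$h_bT, g_xbT = params$g_xbT)
}

#' Advance the crossbridge state one step
#'
#' Occupancies advance by an exact matrix exponential of the four-state
#' chain with rates frozen at the mid-step troponin saturation
#' (unconditionally stable under the steep `TCa^-7.5` backward rate);
#' troponin binding, strains and the SL/force-integral pair use exact
#' exponential updates.  Occupancy is conserved to numerical precision.
#'
#' @inheritParams transition_rates
#' @param ca_i cytosolic Ca during the step, mM.
#' @param dt step, ms.
#' @return the advanced state vector.
#' @export
step_crossbridge <- function(state, ca_i, params, dt = 0.05) {
  if (length(state) != 9L) stop("crossbridge state must have 9 components")
  out <- cpp_xb_step(state, ca_i, .xb_par_vec(params), dt)
  occ <- out[c("N_xb", "P_xb", "XB_PreR", "XB_PostR")]
  if (abs(sum(occ) - 1) > 1e-6 || any(occ < -1e-9))
    stop("crossbridge occupancies left the simplex")
  if (isTRUE(attr(out, "clipped")))
    warning("sarcomere length clipped to [1.4, 2.4] um")
  out
}

#' Forces of the sarcomere
#'
#' Active force is the strain-weighted bound-bridge sum
#' `(XB_PreR * xXB_PreR + XB_PostR * xXB_PostR)` normalized so a fully
#' permissive steady state at the power-stroke strain `x0` bears unit
#' force; passive force is the exponential titin-like curve; preload is
#' `F_passive(SL_0)`; afterload is `KSE * (SL - SL_0)` (isometric), the
#' fixed release value (isotonic), or the same expression evaluated at
#' `SL = SL_0` i.e. 0 (isosarcometric).
#'
#' @inheritParams transition_rates
#' @return named numeric vector `c(F_active, F_passive, F_preload,
#'   F_afterload)`, normalized force units.
#' @export
compute_forces <- function(state, params) {
  duty <- .duty_fractions(params)
  fa <- (state[["XB_PreR"]] * state[["xXB_PreR"]] +
         state[["XB_PostR"]] * state[["xXB_PostR"]]) /
        (params$x0 * duty[["post"]])
  fpass <- function(sl) {
    d <- sl - params$SL_rest
    sign(d) * params$PCon * (exp(params$PExp * abs(d)) - 1)
  }
  fafter <- switch(params$mode,
    isosarcometric = params$KSE * (state[["SL"]] - params$SL_0),
    isometric = params$KSE * (state[["SL"]] - params$SL_0),
    isotonic = params$F_afterload_fixed)
  c(F_active = unname(fa), F_passive = unname(fpass(state[["SL"]])),
    F_preload = unname(fpass(params$SL_0)), F_afterload = unname(fafter))
}

#' Advance sarcomere length
#'
#' Integrates `dSL/dt = (F_int + (SL_0 - SL) * viscosity)/mass` together
#' with the force integral `dF_int/dt = F_active + F_passive - F_preload -
#' F_afterload` one step, holding the crossbridge occupancies fixed.  The
#' pair is a stiff damped oscillator (frequency `sqrt(KSE/mass)`, about
#' 1000/ms at defaults), so the update is the exact matrix exponential of
#' the linearized affine system.  In isosarcometric mode this operation is
#' the identity and SL stays at `SL_0`.
#'
#' @inheritParams step_crossbridge
#' @return state with updated `SL` and `F_int`.
#' @export
step_sarcomere_length <- function(state, params, dt = 0.05) {
  if (params$mode == "isosarcometric") return(state)
  out <- cpp_sl_step(state, .xb_par_vec(params), dt)
  if (isTRUE(attr(out, "clipped")))
    warning("sarcomere length clipped to [1.4, 2.4] um")
  attr(out, "clipped") <- NULL
  out
}

#' Run the myofilament model over a calcium transient
#'
#' Tiles one cycle of a Ca transient `n_beats` times (so the crossbridge
#' pool reaches its cyclic steady state) and integrates the four-state
#' model, returning last-cycle traces and scalars.
#'
#' @param ca either a `beat_record` (its `Cai` trace is used) or a numeric
#'   Ca trace on a uniform grid spanning one cycle, mM.
#' @param params a [sarcomere_params] object.
#' @param ca_dt grid spacing of `ca` when given as a plain vector, ms.
#' @param n_beats cycles to run; the last is reported.
#' @param dt integrator step, ms.
#' @param record_dt output spacing, ms.
#' @return a `mech_record`: list of last-cycle traces (`t`, `Cai`,
#'   occupancies, `TCa_Tot`, `F_active`, `F_passive`, `F_afterload`, `SL`,
#'   `atp_rate` in 1/s) and scalars `peak_tension`, `atp_total` (detachment
#'   flux integral over the cycle), `force_time_integral`.
#' @export
run_myofilament <- function(ca, params = sarcomere_params(), ca_dt = NULL,
                            n_beats = 6, dt = 0.05, record_dt = 0.5) {
  if (inherits(ca, "beat_record")) {
    ca_dt <- mean(diff(ca$t))
    ca <- ca$Cai
  }
  if (is.null(ca_dt)) stop("ca_dt required when ca is a plain vector")
  beat_ms <- (length(ca) - 1) * ca_dt
  # tile beats: drop the duplicate junction sample
  full <- c(rep(ca[-length(ca)], n_beats), ca[length(ca)])
  st0 <- xb_state_init(params, ca_dia = min(ca))
  res <- cpp_xb_run(st0, full, ca_dt, .xb_par_vec(params), dt,
                    max(1L, round(record_dt / dt)))
  last <- res$t >= (n_beats - 1) * beat_ms - 1e-9
  tr <- lapply(res[c("Cai", "N_xb", "P_xb", "XB_PreR", "XB_PostR",
                     "TCa_Tot", "F_active", "F_passive", "F_afterload",
                     "SL", "atp_rate")], function(x) x[last])
  tr$t <- res$t[last] - (n_beats - 1) * beat_ms
  atp <- atp_consumption(tr$t, res$XB_PostR[last], params)
  out <- c(tr[c("t", "Cai")], tr[setdiff(names(tr), c("t", "Cai"))])
  out$peak_tension <- max(tr$F_active)
  out$atp_total <- atp$total
  out$force_time_integral <- sum(diff(tr$t) *
                                 (head(tr$F_active, -1) +
                                  tail(tr$F_active, -1)) / 2)
  out$n_clipped <- res$n_clipped
  out$mode <- params$mode
  class(out) <- "mech_record"
  out
}

#' ATP consumption from the detachment flux
#'
#' The instantaneous ATP consumption rate is the flux through the
#' ATP-consuming detachment transition, `g_xbT * XB_PostR` (reported per
#' second); the cycle total is its time integral.
#'
#' @param t time grid, ms.
#' @param xb_postr post-rotation occupancy trace.
#' @param params a [sarcomere_params] object.
#' @return list with `rate` (1/s, per sample) and `total` (crossbridge
#'   detachment cycles per site over the trace).
#' @export
atp_consumption <- function(t, xb_postr, params) {
  rate <- params$g_xbT * xb_postr * 1000
  total <- sum(diff(t) * (head(rate, -1) + tail(rate, -1)) / 2) / 1000
  list(rate = rate, total = total)
}

#' @export
print.mech_record <- function(x, ...) {
  cat(sprintf("<mech_record> %s, peak tension %.4f (norm), ATP/cycle %.4g\n",
              x$mode, x$peak_tension, x$atp_total))
  invisible(x)
}

#' Export a mechanics record as CSV
#'
#' Columns `t_ms, F_active, F_passive, SL_um, ATP_rate_per_s`.
#'
#' @param record a `mech_record`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mech_csv <- function(record, path) {
  df <- data.frame(t_ms = record$t, F_active = record$F_active,
                   F_passive = record$F_passive, SL_um = record$SL,
                   ATP_rate_per_s = record$atp_rate)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
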