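#' Lumped pump surrogate parameters
#'
#' Desk-scale stand-in for a full circulatory model: a time-varying
#' elastance ventricle driven by the myofilament tension waveform, filling
#' from a constant-pressure venous source through a mitral resistance and
#' ejecting into a 3-element Windkessel (characteristic resistance,
#' peripheral resistance, arterial compliance) through an ideal aortic
#' valve.  `P_lv = (E_min + gain * tension(t)) * (V - V0)`.
#'
#' The default `gain` is the surrogate's single documented calibration: it
#' places the normal-condition ejection fraction near 45% when driven by
#' the baseline tension waveform.  Only orderings and relative drops across
#' the conductance sweep are meaningful; absolute pressures and volumes are
#' not targets of this surrogate.
#'
#' @param V0 unloaded ventricular volume, mL.
#' @param E_min diastolic elastance, mmHg/mL.
#' @param gain tension-to-elastance gain, mmHg/mL per unit normalized
#'   tension.
#' @param R_mv mitral (filling) resistance, mmHg s/mL.
#' @param Z_c aortic characteristic resistance, mmHg s/mL.
#' @param R_p peripheral resistance, mmHg s/mL.
#' @param C_art arterial compliance, mL/mmHg.
#' @param P_ven venous filling pressure, mmHg.
#' @param atp_scale constant representative myocardial mass factor applied
#'   to the single-cell ATP cycle total in the efficiency denominator.
#' @return an object of class `pump_params`.
#' @export
pump_params <- function(V0 = 5, E_min = 0.13, gain = 2.6, R_mv = 0.05,
                        Z_c = 0.05, R_p = 1.2, C_art = 1.5, P_ven = 10,
                        atp_scale = 1) {
  vals <- c(V0 = V0, E_min = E_min, gain = gain, R_mv = R_mv, Z_c = Z_c,
            R_p = R_p, C_art = C_art, P_ven = P_ven, atp_scale = atp_scale)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all pump surrogate elements must be positive")
  structure(as.list(vals), class = "pump_params")
}

#' Run the elastance-Windkessel surrogate to a limit cycle
#'
#' Integrates the two-state (LV volume, arterial pressure) diode-valve
#' model with the periodic tension waveform until the end-diastolic volume
#' changes by less than 0.5% between beats (a warning-flagged record is
#' returned if that does not happen within `n_beats`), then reports
#' last-cycle hemodynamics.
#'
#' @param tension_t time grid of the tension waveform over one cycle, ms.
#' @param tension normalized active tension waveform (periodic at the cycle
#'   length implied by `tension_t`).
#' @param params a [pump_params] object.
#' @param n_beats maximum beats to run.
#' @param dt_ms integration step, ms.
#' @param atp_total optional myofilament ATP cycle total; when given, the
#'   record includes `efficiency = stroke_work / (atp_total * atp_scale)`.
#' @return a `pump_record`: last-cycle traces (`t`, `P_lv`, `P_art`,
#'   `V_lv`) and scalars `EDV`, `ESV`, `SV`, `EF`, `stroke_work`,
#'   `pulse_pressure`, `efficiency` (NA when `atp_total` is missing),
#'   `converged`.
#' @export
run_beat_loop <- function(tension_t, tension, params = pump_params(),
                          n_beats = 60, dt_ms = 0.25, atp_total = NULL) {
  if (length(tension_t) != length(tension))
    stop("tension trace and grid differ in length")
  bcl <- tension_t[length(tension_t)] - tension_t[1]
  if (bcl <= 0) stop("tension grid must span one positive cycle")
  nt <- round(bcl / dt_ms)
  tg <- seq(0, bcl, length.out = nt + 1L)
  Tg <- approx(tension_t - tension_t[1], tension, xout = tg, rule = 2)$y
  E <- params$E_min + params$gain * pmax(Tg, 0)

  dt_s <- dt_ms / 1000
  V <- params$V0 + params$P_ven / params$E_min  # start near passive filling
  Pa <- 70
  edv_prev <- NA_real_
  pa_prev <- NA_real_
  converged <- FALSE

  trace <- NULL
  for (beat in seq_len(n_beats)) {
    pa_start <- Pa
    Vtr <- numeric(nt + 1L); Plvtr <- numeric(nt + 1L); Patr <- numeric(nt + 1L)
    for (k in seq_len(nt + 1L)) {
      Plv <- E[k] * (V - params$V0)
      Qin <- max(0, (params$P_ven - Plv) / params$R_mv)
      Qout <- max(0, (Plv - Pa) / params$Z_c)
      Vtr[k] <- V; Plvtr[k] <- Plv; Patr[k] <- Pa
      if (k <= nt) {
        V <- V + dt_s * (Qin - Qout)
        Pa <- Pa + dt_s * (Qout - Pa / params$R_p) / params$C_art
      }
    }
    edv <- max(Vtr)
    trace <- list(t = tg, V_lv = Vtr, P_lv = Plvtr, P_art = Patr)
    # limit cycle: both end-diastolic volume and beat-start arterial
    # pressure must be beat-to-beat stable
    if (!is.na(edv_prev) &&
        abs(edv - edv_prev) / edv_prev < 0.005 &&
        abs(pa_start - pa_prev) < pmax(0.005 * abs(pa_prev), 0.02)) {
      converged <- TRUE
      break
    }
    edv_prev <- edv
    pa_prev <- pa_start
  }
  if (!converged)
    warning("pump surrogate did not reach a limit cycle within n_beats")

  edv <- max(trace$V_lv); esv <- min(trace$V_lv)
  sv <- edv - esv
  # shoelace area; for degenerate near-zero-excursion loops whose endpoint
  # gap trips the closure contract, fall back to the Green's-theorem
  # integral -int P dV over the beat
  sw <- tryCatch(pv_loop_area(trace$P_lv, trace$V_lv),
                 error = function(e) {
                   p <- trace$P_lv; v <- trace$V_lv; n <- length(v)
                   -sum((p[-1] + p[-n]) / 2 * diff(v))
                 })
  eff <- if (is.null(atp_total)) NA_real_ else
           sw / (atp_total * params$atp_scale)
  structure(c(trace, list(
    EDV = edv, ESV = esv, SV = sv, EF = sv / edv, stroke_work = sw,
    pulse_pressure = max(trace$P_art) - min(trace$P_art),
    efficiency = eff, converged = converged)),
    class = "pump_record")
}

#' @export
print.pump_record <- function(x, ...) {
  cat(sprintf(
    "<pump_record> EDV %.1f mL, ESV %.1f mL, SV %.1f mL, EF %.1f%%\n",
    x$EDV, x$ESV, x$SV, 100 * x$EF))
  cat(sprintf(
    "  stroke work %.0f mmHg*mL, pulse pressure %.1f mmHg, limit cycle: %s\n",
    x$stroke_work, x$pulse_pressure, x$converged))
  invisible(x)
}

#' Pressure-volume loop area
#'
#' Signed shoelace area of one closed (V, P) cycle; positive for the
#' counterclockwise orientation of an ejecting ventricle.  Errors if the
#' trajectory endpoints differ by more than 1% of the cycle's range.
#'
#' @param pressure pressure trace over one cycle, mmHg.
#' @param volume volume trace over one cycle, mL.
#' @return loop area, mmHg mL.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 200)
#' pv_loop_area(50 + 50 * sin(th), 60 + 20 * cos(th))  # ellipse, ~ pi*a*b
#' @export
pv_loop_area <- function(pressure, volume) {
  if (length(pressure) != length(volume) || length(pressure) < 4)
    stop("pressure and volume must be equal-length cycle traces")
  gap_p <- abs(pressure[1] - pressure[length(pressure)])
  gap_v <- abs(volume[1] - volume[length(volume)])
  rng_p <- diff(range(pressure)); rng_v <- diff(range(volume))
  if ((rng_p > 0 && gap_p > 0.01 * rng_p) ||
      (rng_v > 0 && gap_v > 0.01 * rng_v))
    stop("trajectory is not closed (endpoint gap exceeds 1% of range)")
  v <- c(volume, volume[1]); p <- c(pressure, pressure[1])
  n <- length(volume)
  0.5 * sum(v[1:n] * p[2:(n + 1)] - v[2:(n + 1)] * p[1:n])
}
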