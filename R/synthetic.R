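#' Synthetic action potential with closed-form APD90
#'
#' Piecewise template — resting lead-in, linear upstroke, flat plateau,
#' exponential repolarization — whose APD90 is known analytically:
#' measured from the upstroke (maximum dV/dt, i.e. the upstroke onset for
#' this template) the 90% recrossing lies `tau_repol * ln(10)` into the
#' exponential tail, so
#' `APD90 = upstroke_ms + plateau_ms + tau_repol * ln(10)`.
#' Deliberately simple so measurement code can be tested against exact
#' ground truth; morphological realism is the ionic model's job.
#'
#' @param v_rest,v_peak resting and peak potential, mV.
#' @param upstroke_ms linear upstroke duration, ms.
#' @param plateau_ms flat plateau duration, ms.
#' @param tau_repol exponential repolarization time constant, ms.
#' @param lead_ms resting lead-in before the upstroke, ms.
#' @param total_ms trace length; default covers the tail to ~8 tau.
#' @param dt sampling interval, ms.
#' @param noise_sd additive Gaussian noise SD, mV.
#' @param seed RNG seed for the noise (bit-reproducible given a seed).
#' @return list with `t`, `Vm`, and the exact `apd90` implied by the
#'   template parameters.
#' @examples
#' ap <- make_ap(plateau_ms = 200, tau_repol = 30)
#' abs(measure_apd90(ap$t, ap$Vm) - ap$apd90) < 0.5
#' @export
make_ap <- function(v_rest = -85, v_peak = 40, upstroke_ms = 2,
                    plateau_ms = 180, tau_repol = 30, lead_ms = 10,
                    total_ms = NULL, dt = 0.05, noise_sd = 0, seed = NULL) {
  stopifnot(v_peak > v_rest, upstroke_ms > 0, plateau_ms > 0, tau_repol > 0)
  if (is.null(total_ms))
    total_ms <- lead_ms + upstroke_ms + plateau_ms + 8 * tau_repol
  t <- seq(0, total_ms, by = dt)
  t1 <- lead_ms; t2 <- t1 + upstroke_ms; t3 <- t2 + plateau_ms
  v <- ifelse(t < t1, v_rest,
       ifelse(t < t2, v_rest + (v_peak - v_rest) * (t - t1) / upstroke_ms,
       ifelse(t < t3, v_peak,
              v_rest + (v_peak - v_rest) * exp(-(t - t3) / tau_repol))))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + rnorm(length(v), sd = noise_sd)
  }
  list(t = t, Vm = v,
       apd90 = upstroke_ms + plateau_ms + tau_repol * log(10),
       v_rest = v_rest, v_peak = v_peak, t_upstroke = t1)
}

#' Synthetic calcium transient with closed-form integral
#'
#' `Ca(t) = dia + amp * g(t)/g(t_peak)` over one cycle, with
#' `g(t) = (1 - exp(-t/tau_r)) * exp(-t/tau_d)`; the rise constant `tau_r`
#' is solved so the peak falls at `t_peak`.  The exact time integral over
#' the cycle is returned alongside the trace for oracle testing.
#'
#' @param dia diastolic Ca, mM.
#' @param amp transient amplitude (peak minus diastolic), mM; `amp = 0`
#'   gives a constant diastolic trace.
#' @param t_peak time to peak, ms.
#' @param tau_decay decay time constant, ms.
#' @param BCL cycle length, ms.
#' @param dt sampling interval, ms.
#' @param noise_sd additive Gaussian noise SD, mM.
#' @param seed RNG seed for the noise.
#' @return list with `t`, `Cai`, and the exact `integral` (mM ms) of the
#'   noise-free template.
#' @export
make_ca <- function(dia = 7e-5, amp = 9e-4, t_peak = 40, tau_decay = 120,
                    BCL = 600, dt = 0.5, noise_sd = 0, seed = NULL) {
  stopifnot(amp >= 0, dia > 0, t_peak > 0, tau_decay > 0, BCL > t_peak)
  t <- seq(0, BCL, by = dt)
  if (amp == 0) {
    ca <- rep(dia, length(t))
    integral <- dia * BCL
    tau_r <- NA_real_
  } else {
    if (t_peak >= tau_decay)
      stop("template requires t_peak < tau_decay")
    # peak condition: exp(-t*/tau_r) (1 + tau_d/tau_r) = 1
    f <- function(tr) tr * log(1 + tau_decay / tr) - t_peak
    tau_r <- uniroot(f, c(1e-3, 1e7))$root
    g <- function(tt) (1 - exp(-tt / tau_r)) * exp(-tt / tau_decay)
    gmax <- g(t_peak)
    ca <- dia + amp * g(t) / gmax
    ig <- function(TT) {
      tau_rd <- 1 / (1 / tau_r + 1 / tau_decay)
      tau_decay * (1 - exp(-TT / tau_decay)) - tau_rd * (1 - exp(-TT / tau_rd))
    }
    integral <- dia * BCL + amp / gmax * ig(BCL)
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    ca <- pmax(ca + rnorm(length(ca), sd = noise_sd), dia - 3 * noise_sd)
  }
  list(t = t, Cai = ca, integral = integral, dia = dia, amp = amp,
       tau_rise = tau_r)
}
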