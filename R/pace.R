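#' Action potential duration at 90% repolarization
#'
#' APD90 is measured from the point of maximum upstroke velocity (maximum
#' dV/dt) to the first subsequent crossing of
#' `V90 = V_peak - 0.9 * (V_peak - V_rest)`, with linear interpolation
#' between samples.  `V_rest` defaults to the trace minimum; for paced
#' beats pass the membrane potential immediately before the stimulus.
#'
#' @param t time grid, ms.
#' @param vm membrane potential trace, mV (one action potential).
#' @param v_rest resting level used for the 90% threshold, mV.
#' @param smooth_ms optional moving-average window (ms) applied before
#'   measurement; useful on noisy traces, 0 (none) by default.
#' @return APD90 in ms, with attributes `t_up` (upstroke time), `v90`
#'   (threshold) and `t90` (recrossing time).
#' @examples
#' t <- seq(0, 400, by = 0.1)
#' v <- ifelse(t >= 10 & t < 310, 20, -85)
#' measure_apd90(t, v)   # ~300 ms
#' @export
measure_apd90 <- function(t, vm, v_rest = NULL, smooth_ms = 0) {
  if (length(t) != length(vm) || length(t) < 4)
    stop("t and vm must be equal-length traces")
  if (smooth_ms > 0) {
    w <- max(1L, round(smooth_ms / mean(diff(t))))
    if (w %% 2 == 0) w <- w + 1L
    k <- rep(1 / w, w)
    vm <- as.numeric(stats::filter(vm, k, sides = 2))
    keep <- !is.na(vm)
    t <- t[keep]; vm <- vm[keep]
  }
  if (is.null(v_rest)) v_rest <- min(vm)
  v_peak <- max(vm)
  if (v_peak - v_rest < 10)
    stop("no action potential upstroke found (excursion < 10 mV)")

  dv <- diff(vm) / diff(t)
  # earliest interval within tolerance of the maximum slope, so that a
  # piecewise-linear upstroke (constant slope) is marked at its onset
  mx <- max(dv)
  i_up <- which(dv >= mx - abs(mx) * 1e-9 - 1e-12)[1]
  t_up <- t[i_up + 1L]
  # trace may start at the peak (no rising phase recorded)
  if (vm[1] >= v_peak - 1e-9) {
    t_up <- t[1]
    i_up <- 1L
  }
  v90 <- v_peak - 0.9 * (v_peak - v_rest)

  i_peak <- which.max(vm)
  idx <- seq(max(i_peak, i_up), length(vm) - 1L)
  cross <- idx[vm[idx] > v90 & vm[idx + 1L] <= v90]
  if (length(cross) == 0)
    stop("no 90% repolarization crossing before end of trace")
  i <- cross[1]
  frac <- (vm[i] - v90) / (vm[i] - vm[i + 1L])
  t90 <- t[i] + frac * (t[i + 1L] - t[i])
  structure(t90 - t_up, t_up = t_up, v90 = v90, t90 = t90)
}

#' Time integral of the calcium transient
#'
#' Trapezoidal integral of cytosolic Ca over one cycle, the per-beat
#' calcium exposure that tracks APD across the conductance sweep.
#'
#' @param record a `beat_record` from [pace_to_steady_state], or a time
#'   grid (ms) when `cai` is given.
#' @param cai optional Ca trace, mM (when `record` is a time grid).
#' @return integral in mM*ms.
#' @export
integrate_calcium <- function(record, cai = NULL) {
  if (inherits(record, "beat_record")) {
    t <- record$t; cai <- record$Cai
  } else {
    t <- record
  }
  if (length(t) != length(cai)) stop("time and Ca traces differ in length")
  sum(diff(t) * (head(cai, -1) + tail(cai, -1)) / 2)
}

#' Pace a myocyte to steady state
#'
#' Paces the cell for `protocol$n_beats` cycles with the compiled
#' fixed-step integrator and returns the final beat: membrane potential,
#' cytosolic Ca and IKs traces plus derived scalars (APD90, Ca integral,
#' peak/diastolic levels).  Steady state is declared when APD90 changes by
#' less than 1 ms between the last two beats; otherwise a warning is
#' attached to the record (`converged = FALSE`), not raised as an error.
#'
#' @param params a [cell_params] object.
#' @param protocol a [pacing_protocol].
#' @param dt integrator step, ms.
#' @param record_dt trace output spacing, ms.
#' @return a `beat_record`: list with `t`, `Vm`, `Cai`, `IKs`, `apd90`,
#'   `apd90_prev`, `ca_integral`, `v_peak`, `v_rest`, `ca_peak`, `ca_dia`,
#'   `bcl`, `converged`, `cell_type`, `g_Ks_scale` and the final full
#'   `state`.
#' @examples
#' \donttest{
#' rec <- pace_to_steady_state(cell_params("epi"),
#'                             pacing_protocol(n_beats = 5))
#' rec$apd90
#' }
#' @export
pace_to_steady_state <- function(params, protocol = pacing_protocol(),
                                 dt = 0.02, record_dt = 0.1) {
  rec_every <- max(1L, round(record_dt / dt))
  res <- cpp_pace(cell_state_init(), .celltype_int(params),
                  .gks_total(params), protocol$BCL, protocol$n_beats,
                  protocol$stim_amplitude, protocol$stim_duration,
                  protocol$stim_start_offset, dt,
                  rec_beats = min(2L, protocol$n_beats), rec_every)

  bcl <- protocol$BCL
  two_beats <- res$rec_beats == 2L
  last <- res$t >= (res$rec_beats - 1L) * bcl
  t_last <- res$t[last] - (res$rec_beats - 1L) * bcl

  measure_beat <- function(tt, vv) {
    pre <- which(tt <= protocol$stim_start_offset)
    vr <- vv[if (length(pre)) max(pre) else 1L]
    measure_apd90(tt, vv, v_rest = vr)
  }
  apd <- measure_beat(t_last, res$Vm[last])
  apd_prev <- NA_real_
  if (two_beats) {
    prev <- res$t < bcl
    apd_prev <- as.numeric(measure_beat(res$t[prev], res$Vm[prev]))
  }
  converged <- !two_beats || abs(apd - apd_prev) < 1
  if (!converged)
    warning(sprintf(
      "pacing not at steady state: APD90 moved %.2f ms over the last beat",
      abs(apd - apd_prev)))

  out <- list(
    t = t_last, Vm = res$Vm[last], Cai = res$Cai[last], IKs = res$IKs[last],
    apd90 = as.numeric(apd), apd90_prev = apd_prev,
    v_peak = max(res$Vm[last]), v_rest = NA_real_,
    ca_peak = max(res$Cai[last]), ca_dia = min(res$Cai[last]),
    bcl = bcl, converged = converged,
    cell_type = params$cell_type, g_Ks_scale = params$g_Ks_scale,
    state = res$state)
  out$v_rest <- out$Vm[1]
  out$ca_integral <- integrate_calcium(out$t, out$Cai)
  if (out$apd90 >= bcl) stop("measured APD90 exceeds the cycle length")
  class(out) <- "beat_record"
  out
}

#' @export
print.beat_record <- function(x, ...) {
  cat(sprintf(
    "<beat_record> %s cell, g_Ks scale %g, BCL %g ms\n", x$cell_type,
    x$g_Ks_scale, x$bcl))
  cat(sprintf("  APD90 = %.1f ms (prev beat %.1f), Ca integral = %.4g mM*ms\n",
              x$apd90, x$apd90_prev, x$ca_integral))
  cat(sprintf("  Vm [%.1f, %.1f] mV, Cai [%.2e, %.2e] mM, steady: %s\n",
              x$v_rest, x$v_peak, x$ca_dia, x$ca_peak, x$converged))
  invisible(x)
}

#' Export a beat record as CSV
#'
#' Columns `t_ms, Vm_mV, Cai_mM, IKs_uA_per_uF`.
#'
#' @param record a `beat_record`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_beat_csv <- function(record, path) {
  df <- data.frame(t_ms = record$t, Vm_mV = record$Vm, Cai_mM = record$Cai,
                   IKs_uA_per_uF = record$IKs)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
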