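#' 1-D monodomain cable parameters
#'
#' Reaction-diffusion cable
#' `dV/dt = -(I_ion + I_stim)/C_m + D d2V/dx2` with no-flux ends, where the
#' diffusivity combines axial resistivity `rho` (kOhm cm), surface-to-volume
#' ratio `S` (1/cm) and specific capacitance `Cm_sp` (uF/cm^2) as
#' `D = 1/(rho * S * Cm_sp)` in cm^2/ms.  The default diffusivity is the
#' package's one-time conduction calibration: it puts the normal-condition
#' planar conduction velocity near 57 cm/s, the value implied by a 17 cm
#' wavelength at APD90 ~ 0.3 s.  Absolute wavelengths are reported but only
#' their ratios across the conductance sweep are meaningful at cable scale.
#'
#' @param length_cm cable length, cm.
#' @param dx node spacing, cm.
#' @param diffusivity D in cm^2/ms; overrides `rho`/`S`/`Cm_sp` when given.
#' @param rho axial resistivity, kOhm cm.
#' @param S surface-to-volume ratio, 1/cm.
#' @param Cm_sp specific membrane capacitance, uF/cm^2.
#' @param stim_width_cm physical width of the stimulated segment at the
#'   left end, cm (converted to nodes at the chosen resolution).
#' @param act_threshold activation detection threshold on the upstroke, mV.
#' @return an object of class `cable_params`.
#' @export
cable_params <- function(length_cm = 2, dx = 0.00625, diffusivity = NULL,
                         rho = 0.852, S = 1400, Cm_sp = 1,
                         stim_width_cm = 0.075, act_threshold = -20) {
  if (is.null(diffusivity)) diffusivity <- 1 / (rho * S * Cm_sp)
  if (diffusivity < 0) stop("diffusivity must be non-negative")
  n_nodes <- round(length_cm / dx) + 1L
  if (length_cm < 20 * dx) stop("cable must be at least 20 nodes long")
  structure(list(length_cm = length_cm, dx = dx, diffusivity = diffusivity,
                 n_nodes = n_nodes,
                 n_stim_nodes = max(2L, as.integer(round(stim_width_cm / dx))),
                 act_threshold = act_threshold),
            class = "cable_params")
}

#' Simulate a paced 1-D cable
#'
#' Operator-split monodomain solution: the compiled cell stepper advances
#' the reaction term at every node, an explicit three-point Laplacian (with
#' a CFL guard) advances diffusion.  All nodes start from `init_state`
#' (typically the single-cell paced steady state, so that a few cable beats
#' suffice); the left end is stimulated every cycle.  The last beat's
#' space-time voltage field and per-node activation times (linear
#' interpolation of the upstroke crossing of the threshold) are returned.
#'
#' @param cable a [cable_params] object.
#' @param cell a [cell_params] object.
#' @param protocol a [pacing_protocol]; `stim_start_offset` is ignored
#'   (stimulus at cycle start) and `n_beats` counts cable beats.
#' @param init_state initial state for every node; default the resting
#'   state ([cell_state_init]), but passing a paced steady state is both
#'   faster and closer to tissue conditions.
#' @param dt integrator step, ms.
#' @param record_dt output spacing, ms.
#' @return a `cable_field`: list with `t` (ms, from last-beat start),
#'   `Vmat` (time x node voltage matrix), `act_ms` (activation times),
#'   `x_cm` (node coordinates), `cable`, `bcl`.
#' @export
simulate_cable <- function(cable, cell, protocol = pacing_protocol(n_beats = 3),
                           init_state = NULL, dt = 0.005, record_dt = 0.2) {
  if (is.null(init_state)) init_state <- cell_state_init()
  res <- cpp_run_cable(init_state, .celltype_int(cell), .gks_total(cell),
                       cable$n_nodes, cable$dx, cable$diffusivity,
                       protocol$BCL, protocol$n_beats,
                       protocol$stim_amplitude, protocol$stim_duration,
                       cable$n_stim_nodes, dt,
                       max(1L, round(record_dt / dt)),
                       cable$act_threshold)
  structure(list(t = res$t, Vmat = res$Vmat, act_ms = res$act_ms,
                 x_cm = (seq_len(cable$n_nodes) - 1L) * cable$dx,
                 cable = cable, bcl = res$bcl),
            class = "cable_field")
}

#' Conduction velocity between two probes
#'
#' `CV (cm/s) = distance (cm) / (t_down - t_up) (ms) * 1000`, using the
#' interpolated activation times of two probe nodes.  Probes default to 25%
#' and 75% of the cable, at least a quarter of the cable apart and away
#' from the ends.
#'
#' @param field a `cable_field` from [simulate_cable], or a list with
#'   `act_ms` and `x_cm`.
#' @param probes integer node indices `c(up, down)` (up = proximal to the
#'   stimulus).
#' @return CV in cm/s.
#' @export
measure_cv <- function(field, probes = NULL) {
  n <- length(field$act_ms)
  if (is.null(probes)) probes <- round(c(0.25, 0.75) * (n - 1)) + 1L
  a <- field$act_ms[probes]
  if (any(is.na(a)))
    stop("measurement error: probe node never crossed the activation ",
         "threshold (no propagating wavefront)")
  dist <- abs(field$x_cm[probes[2]] - field$x_cm[probes[1]])
  dtr <- a[2] - a[1]
  if (dtr <= 0) stop("probes activated out of order")
  dist / dtr * 1000
}

#' APD90 at a cable node
#'
#' Measures APD90 on the recorded last-beat voltage trace of one node
#' (default the distal probe at 75% of the cable).
#'
#' @param field a `cable_field`.
#' @param node node index.
#' @return APD90, ms.
#' @export
cable_apd90 <- function(field, node = NULL) {
  n <- ncol(field$Vmat)
  if (is.null(node)) node <- round(0.75 * (n - 1)) + 1L
  v <- field$Vmat[, node]
  as.numeric(measure_apd90(field$t, v, v_rest = v[1]))
}

#' Conduction wavelength
#'
#' `wavelength (cm) = CV (cm/s) * APD90 (ms) / 1000`; the spatial extent of
#' excited tissue, the quantity whose shortening favors reentry.
#'
#' @param cv conduction velocity, cm/s.
#' @param apd90 action potential duration, ms.
#' @return wavelength in cm.
#' @examples
#' wavelength(100, 200)  # 20 cm
#' @export
wavelength <- function(cv, apd90) {
  if (any(cv <= 0) || any(apd90 <= 0)) stop("cv and apd90 must be positive")
  cv * apd90 / 1000
}

#' Export an activation map as CSV
#'
#' Columns `node, x_cm, t_act_ms`.
#'
#' @param field a `cable_field`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_activation_csv <- function(field, path) {
  df <- data.frame(node = seq_along(field$act_ms), x_cm = field$x_cm,
                   t_act_ms = field$act_ms)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
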