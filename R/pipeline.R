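#' Default sweep configuration
#'
#' The study protocol as a nested list: three transmural cell types paced
#' at BCL 600 ms across IKs conductance multipliers {1, 2, 4, 6, 8, 10},
#' mechanics driven by the endocardial Ca transients, a 2-cm cable for
#' conduction, and the pump surrogate.  Every run of [run_sweep] is fully
#' described by one such config (writable to YAML with [write_config]).
#'
#' @param cell_types character vector of cell types to sweep.
#' @param scales numeric vector of g_Ks multipliers.
#' @param tissue_cell_type cell type used for the cable and pump stages.
#' @return nested configuration list.
#' @export
default_config <- function(cell_types = c("endo", "M", "epi"),
                           scales = c(1, 2, 4, 6, 8, 10),
                           tissue_cell_type = "endo") {
  list(
    cell_types = cell_types,
    scales = scales,
    tissue_cell_type = tissue_cell_type,
    pacing = list(BCL = 600, n_beats = 50, stim_amplitude = -52,
                  stim_duration = 1, stim_start_offset = 0),
    solver = list(dt = 0.02, record_dt = 0.1),
    mech = list(n_beats = 6, dt = 0.05, record_dt = 0.5),
    cable = list(length_cm = 2, dx = 0.00625, dt = 0.005, n_beats = 3,
                 stim_width_cm = 0.075, act_threshold = -20,
                 diffusivity = 1 / (0.852 * 1400)),
    pump = list(V0 = 5, E_min = 0.13, gain = 2.6, R_mv = 0.05, Z_c = 0.05,
                R_p = 1.2, C_art = 1.5, P_ven = 10, atp_scale = 1,
                n_beats = 60, dt_ms = 0.25)
  )
}

#' Read / write a sweep configuration
#'
#' Configurations round-trip through YAML so that every study run is
#' expressible as one plain-text file.
#'
#' @param path YAML file path.
#' @return for `read_config`, the configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  utils::modifyList(base, cfg)
}

#' @rdname read_config
#' @param config a configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full conductance sweep
#'
#' Executes the whole protocol: for every (cell type, g_Ks scale) pair,
#' paces the myocyte to steady state and drives the myofilament with the
#' resulting Ca transient (18 cell-level rows); for the tissue cell type,
#' additionally runs the cable (CV, wavelength) and the pump surrogate
#' (6 tissue-level rows).  Deterministic given the config: fixed-step
#' solvers, no random input.  A failing stage is recorded in its row's
#' `error` column and the sweep continues.
#'
#' @param config configuration list from [default_config] or [read_config].
#' @param outdir optional directory; when given, per-run trace CSVs, the
#'   two summary tables and a JSON manifest of all parameters are written.
#' @param keep_records keep the full beat/mech/cable/pump records in the
#'   result (memory-heavy for many conditions).
#' @param verbose print per-row progress.
#' @return an object of class `sweep_table`: list with `cells` (one row
#'   per cell type x scale: `apd90_ms`, `ca_integral`, `peak_tension`,
#'   `atp_total`, warnings), `tissue` (one row per scale: `cv_cm_s`,
#'   `wavelength_cm`, `sv_mL`, `ef_frac`, `stroke_work`, `pulse_pressure`,
#'   `efficiency`), and `config`.
#' @export
run_sweep <- function(config = default_config(), outdir = NULL,
                      keep_records = FALSE, verbose = interactive()) {
  pc <- config$pacing
  protocol <- pacing_protocol(pc$BCL, pc$n_beats, pc$stim_amplitude,
                              pc$stim_duration, pc$stim_start_offset)
  sv <- config$solver

  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)

  cells <- expand.grid(cell_type = config$cell_types,
                       g_Ks_scale = config$scales,
                       stringsAsFactors = FALSE)
  cells <- cells[order(match(cells$cell_type, config$cell_types),
                       cells$g_Ks_scale), ]
  rownames(cells) <- NULL
  n <- nrow(cells)
  cells$apd90_ms <- cells$ca_integral <- cells$peak_tension <-
    cells$atp_total <- NA_real_
  cells$converged <- NA
  cells$error <- NA_character_

  records <- list()
  for (i in seq_len(n)) {
    ct <- cells$cell_type[i]; sc <- cells$g_Ks_scale[i]
    key <- paste0(ct, "_x", sc)
    res <- tryCatch({
      rec <- withCallingHandlers(
        pace_to_steady_state(cell_params(ct, g_Ks_scale = sc), protocol,
                             dt = sv$dt, record_dt = sv$record_dt),
        warning = function(w) invokeRestart("muffleWarning"))
      mech <- run_myofilament(rec, sarcomere_params(),
                              n_beats = config$mech$n_beats,
                              dt = config$mech$dt,
                              record_dt = config$mech$record_dt)
      list(rec = rec, mech = mech)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      cells$error[i] <- conditionMessage(res)
    } else {
      cells$apd90_ms[i] <- res$rec$apd90
      cells$ca_integral[i] <- res$rec$ca_integral
      cells$converged[i] <- res$rec$converged
      cells$peak_tension[i] <- res$mech$peak_tension
      cells$atp_total[i] <- res$mech$atp_total
      if (keep_records || ct == config$tissue_cell_type)
        records[[key]] <- res
      if (!is.null(outdir)) {
        write_beat_csv(res$rec, file.path(outdir, paste0("beat_", key,
                                                         ".csv")))
        write_mech_csv(res$mech, file.path(outdir, paste0("mech_", key,
                                                          ".csv")))
      }
    }
    if (verbose)
      message(sprintf("[%2d/%d] %s x%g: APD90 = %.1f ms", i, n, ct, sc,
                      cells$apd90_ms[i]))
  }

  # tissue and pump stages for the designated cell type
  cb <- config$cable
  cable <- cable_params(cb$length_cm, cb$dx, diffusivity = cb$diffusivity,
                        stim_width_cm = cb$stim_width_cm,
                        act_threshold = cb$act_threshold)
  pp <- config$pump
  pumpP <- pump_params(pp$V0, pp$E_min, pp$gain, pp$R_mv, pp$Z_c, pp$R_p,
                       pp$C_art, pp$P_ven, pp$atp_scale)

  tissue <- data.frame(cell_type = config$tissue_cell_type,
                       g_Ks_scale = config$scales,
                       apd90_cable_ms = NA_real_, cv_cm_s = NA_real_,
                       wavelength_cm = NA_real_, sv_mL = NA_real_,
                       ef_frac = NA_real_, stroke_work = NA_real_,
                       pulse_pressure = NA_real_, efficiency = NA_real_,
                       error = NA_character_)
  for (i in seq_len(nrow(tissue))) {
    sc <- tissue$g_Ks_scale[i]
    key <- paste0(config$tissue_cell_type, "_x", sc)
    res <- records[[key]]
    if (is.null(res)) { tissue$error[i] <- "cell stage failed"; next }
    out <- tryCatch({
      field <- simulate_cable(cable,
                              cell_params(config$tissue_cell_type,
                                          g_Ks_scale = sc),
                              pacing_protocol(pc$BCL, cb$n_beats,
                                              pc$stim_amplitude,
                                              pc$stim_duration, 0),
                              init_state = res$rec$state, dt = cb$dt)
      cv <- measure_cv(field)
      apd_c <- cable_apd90(field)
      pump <- withCallingHandlers(
        run_beat_loop(res$mech$t, res$mech$F_active, pumpP,
                      n_beats = pp$n_beats, dt_ms = pp$dt_ms,
                      atp_total = res$mech$atp_total),
        warning = function(w) invokeRestart("muffleWarning"))
      list(field = field, cv = cv, apd_c = apd_c, pump = pump)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      tissue$error[i] <- conditionMessage(out)
      next
    }
    tissue$apd90_cable_ms[i] <- out$apd_c
    tissue$cv_cm_s[i] <- out$cv
    tissue$wavelength_cm[i] <- wavelength(out$cv, out$apd_c)
    tissue$sv_mL[i] <- out$pump$SV
    tissue$ef_frac[i] <- out$pump$EF
    tissue$stroke_work[i] <- out$pump$stroke_work
    tissue$pulse_pressure[i] <- out$pump$pulse_pressure
    tissue$efficiency[i] <- out$pump$efficiency
    if (keep_records) records[[key]]$tissue <- out
    if (!is.null(outdir))
      write_activation_csv(out$field,
                           file.path(outdir, paste0("act_", key, ".csv")))
    if (verbose)
      message(sprintf("tissue x%g: CV = %.1f cm/s, WL = %.1f cm", sc,
                      out$cv, tissue$wavelength_cm[i]))
  }

  result <- structure(list(cells = cells, tissue = tissue, config = config,
                           records = if (keep_records) records else NULL),
                      class = "sweep_table")
  if (!is.null(outdir)) {
    write.csv(cells, file.path(outdir, "summary_cells.csv"),
              row.names = FALSE)
    write.csv(tissue, file.path(outdir, "summary_tissue.csv"),
              row.names = FALSE)
    manifest <- list(config = config,
                     package_version = as.character(
                       utils::packageVersion("cardem")),
                     r_version = R.version.string,
                     timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}

#' @export
print.sweep_table <- function(x, ...) {
  cat("<sweep_table>\n-- cell level --\n")
  print(x$cells[, c("cell_type", "g_Ks_scale", "apd90_ms", "ca_integral",
                    "peak_tension", "atp_total")], digits = 4)
  cat("-- tissue / pump level --\n")
  print(x$tissue[, c("g_Ks_scale", "cv_cm_s", "wavelength_cm", "sv_mL",
                     "ef_frac", "stroke_work", "efficiency")], digits = 4)
  invisible(x)
}

#' APD90 vs calcium-integral correlation
#'
#' Pearson correlation and regression slope of the per-beat Ca integral on
#' APD90, per cell type, across the conductance sweep — the cell-level
#' linearity the sweep is designed to expose.
#'
#' @param table a `sweep_table` from [run_sweep], or its `cells`
#'   data.frame.
#' @return data.frame with one row per cell type: `r`, `slope`
#'   (mM ms per ms), `intercept`, `n`.
#' @export
correlate_apd_ca <- function(table) {
  df <- if (inherits(table, "sweep_table")) table$cells else table
  ok <- is.finite(df$apd90_ms) & is.finite(df$ca_integral)
  df <- df[ok, ]
  out <- lapply(split(df, df$cell_type), function(d) {
    if (nrow(d) < 3)
      stop("need at least 3 completed scales per cell type")
    fit <- lm(ca_integral ~ apd90_ms, data = d)
    data.frame(cell_type = d$cell_type[1],
               r = cor(d$apd90_ms, d$ca_integral),
               slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]), n = nrow(d))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
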