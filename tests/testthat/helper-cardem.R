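# shared fixtures, computed once per test run

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

# full study protocol (3 cell types x 6 scales, cable + pump on endo)
study_sweep <- function() {
  memo("sweep", suppressWarnings(
    run_sweep(default_config(), verbose = FALSE)))
}

# one paced steady-state record per (cell type, scale), shared across files
paced_record <- function(cell_type = "endo", scale = 1, n_beats = 50) {
  key <- sprintf("rec_%s_%g_%d", cell_type, scale, n_beats)
  memo(key, suppressWarnings(
    pace_to_steady_state(cell_params(cell_type, g_Ks_scale = scale),
                         pacing_protocol(n_beats = n_beats))))
}

paper_apd90 <- list(
  endo = c(279, 228, 182, 158, 141, 123),
  M    = c(353, 301, 249, 222, 202, 189),
  epi  = c(280, 230, 185, 162, 147, 135))

sweep_scales <- c(1, 2, 4, 6, 8, 10)

# generator matrix of the four-state crossbridge chain at frozen rates,
# the closed-form oracle for the compiled stepper
xb_rate_matrix <- function(state, params) {
  r <- transition_rates(state, params)
  A <- matrix(0, 4, 4,
              dimnames = list(c("N", "P", "Pre", "Post"), NULL))
  A[1, 1] <- -r[["k_np"]];            A[1, 2] <- r[["k_pn"]]
  A[2, 1] <- r[["k_np"]]
  A[2, 2] <- -(r[["k_pn"]] + r[["f_aapT"]])
  A[2, 3] <- r[["g_aapT"]];           A[2, 4] <- r[["g_xbT"]]
  A[3, 2] <- r[["f_aapT"]]
  A[3, 3] <- -(r[["g_aapT"]] + r[["h_fT"]])
  A[3, 4] <- r[["h_bT"]]
  A[4, 3] <- r[["h_fT"]];             A[4, 4] <- -(r[["h_bT"]] + r[["g_xbT"]])
  A
}
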