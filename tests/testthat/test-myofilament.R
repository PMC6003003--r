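test_that("regulatory power-law rates behave as stated", {
  p <- sarcomere_params()
  s <- xb_state_init(p)

  s[["TCa_Tot"]] <- 1
  r <- transition_rates(s, p)
  expect_equal(r[["k_np"]], p$K_np)
  expect_equal(r[["k_pn"]], p$K_pn)

  s[["TCa_Tot"]] <- 0.4
  r1 <- transition_rates(s, p)
  s[["TCa_Tot"]] <- 0.8
  r2 <- transition_rates(s, p)
  expect_equal(r2[["k_np"]] / r1[["k_np"]], 2^7.5)
  expect_equal(r1[["k_pn"]] / r2[["k_pn"]], 2^7.5)
  # exponents cancel in the product
  expect_equal(r1[["k_np"]] * r1[["k_pn"]], r2[["k_np"]] * r2[["k_pn"]])

  s[["TCa_Tot"]] <- 0
  expect_error(transition_rates(s, p), "positive")
})

test_that("occupancies follow the matrix-exponential solution at clamped troponin saturation", {
  skip_if_not_installed("Matrix")
  p <- sarcomere_params()
  for (tca in c(0.3, 0.6, 0.9)) {
    ca_eq <- p$koff * tca / (p$kon * (1 - tca))  # holds TCa_Tot fixed
    s <- xb_state_init(p)
    s[["TCa_Tot"]] <- tca
    s[c("N_xb", "P_xb", "XB_PreR", "XB_PostR")] <- c(0.7, 0.2, 0.06, 0.04)
    A <- xb_rate_matrix(s, p)

    dt <- 0.05; nstep <- 200  # 10 ms
    st <- s
    for (k in seq_len(nstep)) st <- step_crossbridge(st, ca_eq, p, dt)
    ref <- as.numeric(Matrix::expm(A * dt * nstep) %*%
                        c(0.7, 0.2, 0.06, 0.04))
    expect_lt(max(abs(st[c("N_xb", "P_xb", "XB_PreR", "XB_PostR")] - ref)),
              1e-6)
  }
})

test_that("occupancy stays on the simplex over many randomly driven steps", {
  p <- sarcomere_params()
  set.seed(42)
  # bulk: 1e5 compiled steps over a rough random Ca trace
  ca <- pmax(1e-5, 5e-4 + cumsum(rnorm(10001, sd = 2e-5)))
  res <- cardem:::cpp_xb_run(xb_state_init(p), ca, 1, cardem:::.xb_par_vec(p),
                    dt = 0.1, rec_every = 100)
  occ <- res$state[c("N_xb", "P_xb", "XB_PreR", "XB_PostR")]
  expect_lt(abs(sum(occ) - 1), 1e-8)
  expect_true(all(occ >= -1e-10))

  # step API with per-step random Ca
  st <- xb_state_init(p)
  for (k in 1:500)
    st <- step_crossbridge(st, stats::runif(1, 5e-5, 2e-3), p, dt = 0.1)
  expect_lt(abs(sum(st[c("N_xb", "P_xb", "XB_PreR", "XB_PostR")]) - 1),
            1e-8)
})

test_that("forces: afterload arithmetic and the no-crossbridge limit", {
  p <- sarcomere_params(mode = "isometric")
  s <- xb_state_init(p)

  expect_equal(compute_forces(s, p)[["F_afterload"]], 0)

  s[["SL"]] <- p$SL_0 + 0.1
  expect_equal(compute_forces(s, p)[["F_afterload"]], 5)  # KSE = 50

  s[c("XB_PreR", "XB_PostR")] <- 0
  expect_equal(compute_forces(s, p)[["F_active"]], 0)
  # preload equals passive force at SL_0
  expect_equal(compute_forces(s, p)[["F_preload"]],
               0)  # SL_rest = SL_0 by default
})

test_that("clamped diastolic calcium relaxes the filament to baseline", {
  p <- sarcomere_params()
  s <- xb_state_init(p)
  s[c("N_xb", "P_xb", "XB_PreR", "XB_PostR")] <- c(0.2, 0.4, 0.2, 0.2)
  for (k in 1:4000) s <- step_crossbridge(s, 7e-5, p, dt = 0.1)  # 400 ms
  expect_lt(s[["P_xb"]] + s[["XB_PreR"]] + s[["XB_PostR"]], 1e-3)
  expect_lt(compute_forces(s, p)[["F_active"]], 1e-3)
})

test_that("sarcomere length dynamics: identity in isosarcometric mode, equilibrium at zero net force", {
  iso <- sarcomere_params(mode = "isosarcometric")
  s <- xb_state_init(iso)
  s[["XB_PostR"]] <- 0.5   # nonzero force history
  expect_identical(step_sarcomere_length(s, iso, dt = 0.1), s)

  met <- sarcomere_params(mode = "isometric")
  s2 <- xb_state_init(met)  # zero force, SL = SL_0, F_int = 0
  s3 <- step_sarcomere_length(s2, met, dt = 0.1)
  expect_equal(s3[["SL"]], met$SL_0, tolerance = 1e-12)
})

test_that("tenfold mass slows the sarcomere-length step response", {
  # step response: a suddenly imposed bound-bridge force against the
  # series elastic element; the SL deflection rises on the inertial
  # timescale sqrt(mass/KSE)
  half_peak_time <- function(mass) {
    p <- sarcomere_params(mode = "isometric", mass = mass)
    s <- xb_state_init(p)
    s[c("N_xb", "P_xb", "XB_PreR", "XB_PostR")] <- c(0.3, 0.2, 0, 0.5)
    dt <- 1e-4
    dev <- numeric(2000)
    for (k in seq_along(dev)) {
      s <- step_sarcomere_length(s, p, dt)
      dev[k] <- abs(s[["SL"]] - p$SL_0)
    }
    which(dev >= max(dev) / 2)[1] * dt
  }
  expect_gt(half_peak_time(5e-4), half_peak_time(5e-5))
})

test_that("ATP consumption: zero without bound bridges, monotone in Ca amplitude", {
  p <- sarcomere_params()
  flat <- make_ca(amp = 0, BCL = 600)
  m0 <- run_myofilament(flat$Cai, p, ca_dt = 0.5, n_beats = 2)
  expect_lt(m0$atp_total, 1e-6)   # diastolic permissiveness is ~1e-8
  expect_lt(m0$peak_tension, 1e-6)

  totals <- sapply(c(0.25, 0.5, 0.75, 1) * 1e-3, function(a) {
    ca <- make_ca(amp = a, BCL = 600)
    run_myofilament(ca$Cai, p, ca_dt = 0.5, n_beats = 4)$atp_total
  })
  expect_true(all(diff(totals) > 0))
})

test_that("peak tension rises monotonically with Ca-transient amplitude", {
  p <- sarcomere_params()
  peaks <- sapply(seq(0.1, 1, length.out = 5) * 1e-3, function(a) {
    ca <- make_ca(amp = a, BCL = 600)
    run_myofilament(ca$Cai, p, ca_dt = 0.5, n_beats = 4)$peak_tension
  })
  expect_true(all(diff(peaks) > 0))
})
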