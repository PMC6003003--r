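test_that("CV from constructed activation fields reproduces the defining arithmetic", {
  # imposed activation t(x) = x / 0.05 ms per cm -> 50 cm/s
  x <- seq(0, 2, by = 0.025)
  field <- list(act_ms = x / 0.05, x_cm = x)
  expect_equal(measure_cv(field), 50)

  # distance 3 cm, delta-t 50 ms -> 60 cm/s
  f2 <- list(act_ms = c(0, 50), x_cm = c(0, 3))
  expect_equal(measure_cv(f2, probes = c(1, 2)), 60)

  expect_error(measure_cv(list(act_ms = c(0, NA), x_cm = c(0, 1)),
                          probes = c(1, 2)), "measurement error")
})

test_that("wavelength is CV x APD90 with unit conversion, linear in APD", {
  expect_equal(wavelength(100, 200), 20)
  expect_equal(wavelength(100, 100), wavelength(100, 200) / 2)
  expect_error(wavelength(-1, 100), "positive")
})

test_that("zero diffusivity decouples the cable: distal probes never activate", {
  rec <- paced_record("endo", 1)
  cb <- cable_params(length_cm = 1, diffusivity = 0)
  f <- simulate_cable(cb, cell_params("endo"),
                      pacing_protocol(n_beats = 1), init_state = rec$state)
  expect_error(measure_cv(f), "measurement error")
})

test_that("planar wave: affine activation, probe-position invariance, sqrt-D velocity scaling", {
  rec <- paced_record("endo", 1)
  run_cv <- function(D) {
    cb <- cable_params(length_cm = 1.5, diffusivity = D)
    f <- simulate_cable(cb, cell_params("endo"),
                        pacing_protocol(n_beats = 2),
                        init_state = rec$state)
    f
  }
  f <- run_cv(1 / (0.852 * 1400))
  n <- length(f$act_ms)
  inner <- 10:(n - 10)
  fit <- lm(f$act_ms[inner] ~ f$x_cm[inner])
  expect_gt(summary(fit)$r.squared, 0.999)

  cv0 <- measure_cv(f)
  cv_in <- measure_cv(f, probes = round(c(0.35, 0.65) * (n - 1)) + 1L)
  expect_lt(abs(cv_in - cv0) / cv0, 0.02)

  f4 <- run_cv(4 / (0.852 * 1400))
  expect_lt(abs(measure_cv(f4) / cv0 - 2), 0.3)  # within 15% of doubling
})

test_that("halving dx changes CV by less than 3 percent", {
  rec <- paced_record("endo", 1)
  cv <- sapply(c(0.00625, 0.003125), function(dx) {
    cb <- cable_params(length_cm = 1.5, dx = dx)
    measure_cv(simulate_cable(cb, cell_params("endo"),
                              pacing_protocol(n_beats = 2),
                              init_state = rec$state))
  })
  expect_lt(abs(cv[2] - cv[1]) / cv[1], 0.03)
})

test_that("the CFL guard rejects unstable settings", {
  rec <- paced_record("endo", 1)
  cb <- cable_params(length_cm = 1, diffusivity = 0.02)
  expect_error(simulate_cable(cb, cell_params("endo"),
                              pacing_protocol(n_beats = 1),
                              init_state = rec$state),
               "CFL")
})
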