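test_that("APD90 of constructed square and triangular waveforms matches geometry", {
  t <- seq(0, 400, by = 0.1)
  v <- ifelse(t >= 10 & t < 310, 20, -85)
  expect_equal(as.numeric(measure_apd90(t, v)), 300, tolerance = 0.2)

  # linear repolarization from +40 mV at t=0 to -85 mV at t=250 ms:
  # the 90% level is crossed at t = 225
  t2 <- seq(0, 250, by = 0.1)
  v2 <- 40 - (125 / 250) * t2
  expect_equal(as.numeric(measure_apd90(t2, v2, v_rest = -85)), 225,
               tolerance = 0.2)
})

test_that("APD90 is robust to 2x downsampling of a smooth AP", {
  rec <- paced_record("endo", 1)
  a1 <- as.numeric(measure_apd90(rec$t, rec$Vm, v_rest = rec$Vm[1]))
  half <- seq(1, length(rec$t), by = 2)
  a2 <- as.numeric(measure_apd90(rec$t[half], rec$Vm[half],
                                 v_rest = rec$Vm[1]))
  expect_lt(abs(a1 - a2), 0.5)
})

test_that("APD90 measurement fails loudly without an upstroke or recrossing", {
  t <- seq(0, 100, by = 0.5)
  expect_error(measure_apd90(t, rep(-85, length(t))), "upstroke")
  v <- ifelse(t < 10, -85, 30)  # never repolarizes
  expect_error(measure_apd90(t, v), "crossing")
})

test_that("calcium integral is exact for a constant trace and additive", {
  t <- seq(0, 600, by = 0.5)
  expect_equal(integrate_calcium(t, rep(2e-4, length(t))), 2e-4 * 600)
  ca <- 1e-4 + 1e-4 * sin(pi * t / 600)^2
  expect_equal(integrate_calcium(t, ca),
               1e-4 * 600 + 1e-4 * 300, tolerance = 1e-6)
})
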