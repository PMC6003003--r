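test_that("measured APD90 matches the analytic value over 100 random AP specs", {
  set.seed(7)
  err <- replicate(100, {
    ap <- make_ap(v_rest = runif(1, -90, -80), v_peak = runif(1, 20, 45),
                  upstroke_ms = runif(1, 1, 3),
                  plateau_ms = runif(1, 100, 250),
                  tau_repol = runif(1, 10, 40))
    abs(as.numeric(measure_apd90(ap$t, ap$Vm)) - ap$apd90)
  })
  expect_lt(max(err), 0.5)
})

test_that("pure plateau template reduces to the closed-form geometry", {
  ap <- make_ap(upstroke_ms = 0.1, plateau_ms = 200, tau_repol = 20,
                dt = 0.01)
  expect_equal(ap$apd90, 0.1 + 200 + 20 * log(10))
  expect_equal(as.numeric(measure_apd90(ap$t, ap$Vm)), ap$apd90,
               tolerance = 0.1)
})

test_that("APD90 stays within 2 ms under 1 mV noise in 95 percent of seeds", {
  errs <- sapply(1:400, function(k) {
    ap <- make_ap(plateau_ms = 180, tau_repol = 25, noise_sd = 1, seed = k)
    tryCatch(abs(as.numeric(measure_apd90(ap$t, ap$Vm, v_rest = -85,
                                          smooth_ms = 2)) - ap$apd90),
             error = function(e) Inf)
  })
  expect_gte(mean(errs < 2), 0.95)
})

test_that("seeded generators are bit-reproducible", {
  a <- make_ap(noise_sd = 2, seed = 123)
  b <- make_ap(noise_sd = 2, seed = 123)
  expect_identical(a, b)
  ca1 <- make_ca(noise_sd = 1e-5, seed = 9)
  ca2 <- make_ca(noise_sd = 1e-5, seed = 9)
  expect_identical(ca1, ca2)
})

test_that("calcium template: trapezoid integral matches the closed form; zero amplitude is flat", {
  ca <- make_ca(dia = 8e-5, amp = 7e-4, t_peak = 35, tau_decay = 110,
                BCL = 600, dt = 0.1)
  expect_lt(abs(integrate_calcium(ca$t, ca$Cai) - ca$integral) /
              ca$integral, 1e-3)
  # peak placement
  expect_equal(ca$t[which.max(ca$Cai)], 35, tolerance = 0.5)
  expect_equal(max(ca$Cai), 8e-5 + 7e-4, tolerance = 1e-9)

  flat <- make_ca(amp = 0, BCL = 500)
  expect_true(all(flat$Cai == flat$dia))
  expect_equal(flat$integral, flat$dia * 500)
})
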