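test_that("PV-loop area: rectangle, degenerate loop, orientation and closure contract", {
  # rectangular counterclockwise loop, 40 mL x 100 mmHg
  v <- c(40, 80, 80, 40, 40)
  p <- c(10, 10, 110, 110, 10)
  expect_equal(pv_loop_area(p, v), 4000)

  # zero volume excursion
  expect_equal(pv_loop_area(c(10, 50, 90, 50, 10), rep(60, 5)), 0)

  # open trajectory errors
  expect_error(pv_loop_area(c(10, 10, 110, 110), c(40, 80, 80, 60)),
               "not closed")
})

test_that("loop area equals the -integral P dV oracle on a smooth cycle", {
  th <- seq(0, 2 * pi, length.out = 4000)
  p <- 60 + 45 * sin(th) + 5 * sin(2 * th)
  v <- 60 + 20 * cos(th) + 2 * cos(2 * th)
  a1 <- pv_loop_area(p, v)
  n <- length(v)
  a2 <- -sum((p[-1] + p[-n]) / 2 * diff(v))
  expect_lt(abs(a1 - a2) / a1, 1e-3)
})

test_that("zero active tension ejects nothing", {
  # constant elastance has a fixed point, approached on the Windkessel
  # drainage timescale; volume excursion and loop area are numerically nil
  t <- seq(0, 600, by = 1)
  rec <- suppressWarnings(run_beat_loop(t, rep(0, length(t)),
                                        n_beats = 200))
  expect_lt(rec$SV / rec$EDV, 2e-3)
  expect_lt(abs(rec$stroke_work), 1)
})

test_that("doubling contractile gain increases stroke volume and stroke work", {
  t <- seq(0, 600, by = 1)
  tension <- pmax(0, sin(pi * pmin(t, 300) / 300))^2 * 0.8
  r1 <- suppressWarnings(run_beat_loop(t, tension, pump_params(gain = 2)))
  r2 <- suppressWarnings(run_beat_loop(t, tension, pump_params(gain = 4)))
  expect_gt(r2$SV, r1$SV)
  expect_gt(r2$stroke_work, r1$stroke_work)
  expect_true(r1$EF > 0 && r1$EF < 1)
  expect_lt(r1$ESV, r1$EDV)
})
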