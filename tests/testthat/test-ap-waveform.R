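# tolerance of the render/measure round trip: 2% relative or 0.5 mV /
# 0.05 ms absolute, whichever is larger
expect_roundtrip <- function(est, true, abs_floor) {
  tol <- pmax(0.02 * abs(true), abs_floor)
  expect_lt(abs(est - true), tol)
}

test_that("rendered APs return their parameters under extraction", {
  cases <- list(                      # threshold, amp, hw, rise, decay, ahp
    c(-43.9, 59.5, 2.38, 47.6, -19.6, 14.1),
    c(-40.3, 47.1, 2.99, 24.5, -16.9, 20.1),
    c(-43.9, 62.6, 1.50, 61.5, -44.1, 29.1),
    c(-41.6, 55.5, 1.45, 50.6, -41.1, 28.4),
    c(-45.0, 60.0, 0.95, 60.0, -45.0, 25.0),  # narrow: steepened upper bands
    c(-50.0, 40.0, 4.50, 15.0, -8.0, 10.0))   # slow, wide AP
  for (cs in cases) {
    sh <- ap_shape_params(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6])
    wf <- render_ap(sh, 0.05)
    thr <- measure_ap_threshold(wf)
    f <- measure_ap_features(wf, thr)
    expect_roundtrip(thr, cs[1], 0.5)
    expect_roundtrip(f$amplitude, cs[2], 0.5)
    expect_roundtrip(f$half_width, cs[3], 0.05)
    expect_roundtrip(f$rise_slope, cs[4], 0.5)
    expect_roundtrip(f$decay_slope, cs[5], 0.5)
    expect_roundtrip(f$ahp, cs[6], 0.5)
  }
})

test_that("doubling amplitude with slopes doubled leaves half-width fixed", {
  sh1 <- ap_shape_params(-45, 30, 2.0, 30, -20, 15)
  sh2 <- ap_shape_params(-45, 60, 2.0, 60, -40, 15)
  w1 <- render_ap(sh1, 0.05); w2 <- render_ap(sh2, 0.05)
  f1 <- measure_ap_features(w1, measure_ap_threshold(w1))
  f2 <- measure_ap_features(w2, measure_ap_threshold(w2))
  expect_equal(f1$half_width, f2$half_width, tolerance = 0.01)
})

test_that("zero AHP depth renders and measures as zero", {
  sh <- ap_shape_params(-45, 60, 1.8, 50, -35, 0)
  wf <- render_ap(sh, 0.05)
  f <- measure_ap_features(wf, measure_ap_threshold(wf))
  expect_lt(abs(f$ahp), 0.5)
})

test_that("round-trip error does not grow when the time step halves", {
  sh <- ap_shape_params(-43.9, 62.6, 1.50, 61.5, -44.1, 29.1)
  err <- sapply(c(0.1, 0.05), function(dt) {
    wf <- render_ap(sh, dt)
    f <- measure_ap_features(wf, measure_ap_threshold(wf))
    abs(f$half_width - 1.50)
  })
  expect_lte(err[2], err[1] + 1e-6)
  expect_lt(err[1], 0.05)
})

test_that("threshold criterion has its closed-form value on a quadratic foot", {
  # V(t) = -60 + 50 t^2  =>  dV/dt = 100 t, peak 100 mV/ms at t = 1 ms;
  # the 5% crossing is at t = 0.05 ms where V = -60 + 0.125 mV
  t <- seq(0, 1, by = 0.05)
  wf <- raw_waveform(-60 + 50 * t^2, 0.05)
  expect_equal(measure_ap_threshold(wf), -59.875, tolerance = 1e-3)
})

test_that("a pure linear ramp has no 5% crossing", {
  wf <- raw_waveform(seq(-60, -20, length.out = 200), 0.05)
  expect_error(measure_ap_threshold(wf), class = "shape_error")
})

test_that("triangular APs give their geometric feature values", {
  dt <- 0.01
  up <- seq(-45, 15, by = 60 * dt)          # 1 ms rise at 60 mV/ms
  down <- seq(15 - 60 * dt, -45, by = -60 * dt)
  wf <- raw_waveform(c(up, down), dt)
  f <- measure_ap_features(wf, threshold = -45)
  expect_equal(f$amplitude, 60)
  expect_equal(f$half_width, 1.0, tolerance = 1e-6)
  expect_equal(f$rise_slope, 60, tolerance = 1e-6)
  expect_equal(f$decay_slope, -60, tolerance = 1e-6)
  expect_equal(f$ahp, 0)

  # with a descent to -70 mV after the peak, AHP = threshold - trough
  wf2 <- raw_waveform(c(up, down, seq(-45, -70, by = -10 * dt),
                        rep(-70, 10)), dt)
  f2 <- measure_ap_features(wf2, threshold = -45)
  expect_equal(f2$ahp, 25)
})

test_that("invalid shape parameters are rejected", {
  expect_error(ap_shape_params(-45, -1, 1, 50, -30, 10),
               class = "validation_error")
  expect_error(ap_shape_params(-45, 60, 1, -5, -30, 10),
               class = "validation_error")
  expect_error(ap_shape_params(-45, 60, 1, 50, 30, 10),
               class = "validation_error")
  expect_error(render_ap(ap_shape_params(-45, 60, 1, 50, -30, 10), 0.2),
               class = "validation_error")
})
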