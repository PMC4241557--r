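test_that("the ideal RC pulse has its closed-form plateau and is refit", {
  truth <- list(r_in = 500, c_m = 200, resting = -60)
  p <- gen_passive_pulse(truth, step_pA = -10)
  v <- p$trace$voltage
  t <- trace_times(p$trace)
  plateau <- mean(v[t > p$pulse_end_ms - 20 & t <= p$pulse_end_ms]) - v[1]
  expect_equal(plateau, -5, tolerance = 0.01)      # step * R = -5 mV
  fit <- fit_passive(p)
  expect_equal(fit$tau_m, 100, tolerance = 1)      # 500 MOhm * 200 pF
  expect_equal(fit$r_in, 500, tolerance = 5)
  expect_equal(fit$c_m, 200, tolerance = 2)
  expect_equal(fit$c_m, 1000 * fit$tau_m / fit$r_in)  # identity by construction
})

test_that("noisy passive fits stay within 5%", {
  set.seed(21)
  truth <- list(r_in = 500, c_m = 200, resting = -60)
  p <- gen_passive_pulse(truth, step_pA = -10, noise_sd = 0.3)
  fit <- fit_passive(p)
  expect_equal(fit$tau_m, 100, tolerance = 5)
  expect_equal(fit$r_in, 500, tolerance = 25)
})

test_that("oversized or zero steps are rejected appropriately", {
  truth <- list(r_in = 500, c_m = 200, resting = -60)
  expect_error(gen_passive_pulse(truth, step_pA = -25),
               class = "validation_error")
  p0 <- gen_passive_pulse(truth, step_pA = 0)
  expect_equal(var(p0$trace$voltage), 0)           # flat trace
  expect_error(fit_passive(p0), class = "validation_error")
})

test_that("sag amplitude and rebound delay round-trip", {
  truth <- list(r_in = 500, c_m = 200, sag_amp = 30, sag_tau = 120,
                rebound_delay = 300, resting = -60)
  sh <- ap_shape_params(-44, 60, 1.8, 50, -35, 22)
  sag <- gen_sag_pulse(truth, sh)
  m <- measure_sag_rebound(sag)
  expect_equal(m$sag, 30, tolerance = 0.5)
  expect_equal(m$rebound, 300, tolerance = 0.05 + 1e-9)

  truth$sag_amp <- 0
  m0 <- measure_sag_rebound(gen_sag_pulse(truth, NULL))
  expect_lt(abs(m0$sag), 0.5)
  expect_true(is.na(m0$rebound))
})

test_that("a plain RC response has no sag", {
  truth <- list(r_in = 900, c_m = 150, resting = -60)
  p <- gen_passive_pulse(truth, step_pA = -8)
  m <- measure_sag_rebound(p)
  expect_lt(m$sag, 0.2)
})

test_that("gain regression recovers exact constructed frequencies", {
  # f_start = I/5, f_end = I/10 -> GS 20, GE 10, SFA 2
  mk <- function(I) {
    fs <- I / 5; fe <- I / 10
    times <- c(0, cumsum(c(1 / fs, 1 / fs, rep(1 / fe, ceiling(fe))))) * 1000
    list(spike_times = times[times <= 1000], current_pA = I, pulse_ms = 1000)
  }
  g <- compute_gain(lapply(seq(100, 300, 50), mk))
  expect_equal(g$gain_start, 20, tolerance = 1e-6)
  expect_equal(g$gain_end, 10, tolerance = 1e-6)
  expect_equal(g$sfa_index, 2, tolerance = 1e-6)

  # degenerate flat gain: f = I/10 throughout
  mk2 <- function(I) {
    f <- I / 10
    list(spike_times = seq(0.5 / f, 1, by = 1 / f) * 1000,
         current_pA = I, pulse_ms = 1000)
  }
  g2 <- compute_gain(lapply(seq(100, 300, 50), mk2))
  expect_equal(g2$gain_start, 10, tolerance = 0.01)
  expect_equal(g2$gain_end, 10, tolerance = 0.01)
  expect_equal(g2$sfa_index, 1, tolerance = 0.01)
})

test_that("generated f-I sets round-trip GS/GE within 10%", {
  sh <- ap_shape_params(-43.9, 59.5, 2.0, 47.6, -19.6, 14.1)
  for (gains in list(c(32.1, 20), c(18, 10.4), c(7, 6.8))) {
    truth <- list(gain_start = gains[1], gain_end = gains[2],
                  rheobase = 30, saturation = 400)
    fi <- gen_fi_set(truth, sh)
    resp <- lapply(fi, function(p) {
      st <- detect_spikes(p$trace)
      st <- st[st >= p$pulse_start_ms & st <= p$pulse_end_ms]
      list(spike_times = st - p$pulse_start_ms, current_pA = p$step_pA,
           pulse_ms = 1000)
    })
    g <- compute_gain(resp)
    expect_equal(g$gain_start, gains[1], tolerance = 0.10 * gains[1])
    expect_equal(g$gain_end, gains[2], tolerance = 0.10 * gains[2])
  }
})

test_that("rheobase and depolarization block are honoured", {
  sh <- ap_shape_params(-43.9, 59.5, 2.0, 47.6, -19.6, 14.1)
  truth <- list(gain_start = 20, gain_end = 15, rheobase = 30,
                saturation = 250)
  fi <- gen_fi_set(truth, sh, currents = c(20, 50, 100, 150, 200, 250, 300))
  n_spk <- vapply(fi, function(p) length(detect_spikes(p$trace)), integer(1))
  expect_equal(n_spk[1], 0L)                 # below rheobase
  expect_true(all(n_spk[2:5] > 0))
  # saturating pulses stop early; the gain fit must still use the leading run
  resp <- lapply(fi, function(p) {
    st <- detect_spikes(p$trace)
    st <- st[st >= p$pulse_start_ms & st <= p$pulse_end_ms]
    list(spike_times = st - p$pulse_start_ms, current_pA = p$step_pA,
         pulse_ms = 1000)
  })
  g <- compute_gain(resp)
  expect_lte(g$fit_range[2], 200)
  expect_equal(g$gain_start, 20, tolerance = 2)
  expect_error(gen_fi_set(truth, sh, currents = numeric(0)),
               class = "validation_error")
})

test_that("evenly spaced spikes arise when start and end gain coincide", {
  sh <- ap_shape_params(-43.9, 59.5, 2.0, 47.6, -19.6, 14.1)
  truth <- list(gain_start = 10, gain_end = 10, rheobase = 30,
                saturation = 400)
  fi <- gen_fi_set(truth, sh, currents = 100)
  st <- detect_spikes(fi[[1]]$trace)
  expect_equal(length(st), 10L)
  expect_lt(sd(diff(st)), 0.5)
})
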