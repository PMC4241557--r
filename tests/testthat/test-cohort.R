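test_that("moment-matched truncated sampling reproduces clipped targets", {
  set.seed(61)
  x <- rtnorm_matched(4000, 25.1, 19.2, 12, 150)   # strong left truncation
  expect_true(all(x >= 12))
  expect_equal(mean(x), 25.1, tolerance = 0.7)
  expect_equal(sd(x), 19.2, tolerance = 0.8)
  y <- rtnorm_matched(10, 5, 0, 0, 10)             # sd 0 -> constant
  expect_equal(y, rep(5, 10))
})

test_that("stage draws recover the calibration means within Monte Carlo error", {
  set.seed(62)
  cal <- load_calibration()
  draws <- replicate(300, sample_neuron_params("P21-P23", cal)$truth)
  expect_equal(mean(draws["cv_isi", ]), 7.5, tolerance = 3 * 4.5 / sqrt(300))
  expect_equal(mean(draws["ap_amplitude", ]), 62.6,
               tolerance = 3 * 8.2 / sqrt(300))
  draws2 <- replicate(300, sample_neuron_params("P2-P3", cal)$truth)
  expect_equal(mean(draws2["r_in", ]), 1642, tolerance = 3 * 420 / sqrt(300))
  expect_equal(mean(draws2["ap_rise_slope", ]), 47.6,
               tolerance = 3 * 21.7 / sqrt(300))
  expect_error(sample_neuron_params("P99", cal), class = "lookup_error")
})

test_that("a zero-SD calibration makes every draw equal the mean", {
  cal <- load_calibration()
  cal$sd <- 0
  set.seed(63)
  a <- sample_neuron_params("P14", cal)$truth
  b <- sample_neuron_params("P14", cal)$truth
  expect_equal(a, b)
  expect_equal(unname(a["r_in"]), 460)
  expect_equal(unname(a["ahp"]), 24.1)
})

test_that("cohort generation is deterministic in the seed", {
  plan <- data.frame(stage = "P2-P3", n = 2)
  c1 <- generate_cohort(plan, seed = 3, duration_s = 60, noise_sd = 0.3,
                        protocols = "spontaneous")
  c2 <- generate_cohort(plan, seed = 3, duration_s = 60, noise_sd = 0.3,
                        protocols = "spontaneous")
  expect_identical(c1$recordings[[1]]$spontaneous$voltage,
                   c2$recordings[[1]]$spontaneous$voltage)
  expect_identical(c1$ground_truth, c2$ground_truth)
  c3 <- generate_cohort(plan, seed = 4, duration_s = 60, noise_sd = 0.3,
                        protocols = "spontaneous")
  expect_false(identical(c1$ground_truth$cv_isi, c3$ground_truth$cv_isi))
  expect_error(generate_cohort(data.frame(stage = "P5", n = 0), seed = 1),
               class = "validation_error")
})

test_that("the default plan mirrors the calibration CV_ISI group sizes", {
  plan <- default_stage_plan()
  expect_equal(nrow(plan), 15)
  expect_equal(plan$stage, stage_levels())
  expect_equal(sum(plan$n), 271)
  expect_equal(plan$n[plan$stage == "P7"], 36L)
  half <- default_stage_plan(scale = 0.5)
  expect_true(all(half$n >= plan$n / 2))
})

test_that("extraction reproduces ground truth on a noiseless mini cohort", {
  sim <- simulate_feature_cohort(tiny_plan(2), seed = 64, duration_s = 80,
                                 noise_sd = 0)
  f <- sim$features; g <- sim$ground_truth
  expect_equal(f$neuron_id, g$neuron_id)
  for (nm in c("ap_amplitude", "ap_half_width", "ahp")) {
    expect_equal(f[[nm]], g[[nm]], tolerance = 0.02)
  }
  expect_equal(f$r_in, g$r_in, tolerance = 0.01)
  expect_equal(f$tau_m, g$tau_m, tolerance = 0.01)
  expect_equal(f$isi_avg, g$realized_isi_avg, tolerance = 0.01)
  expect_equal(f$gain_start, g$gain_start, tolerance = 0.05)
  # regimes recovered by classification
  expect_equal(as.character(classify_firing(f$cv_isi)), g$regime)
})

test_that("missing protocols leave their features null, never imputed", {
  set.seed(65)
  p <- sample_neuron_params("P14")
  rec <- generate_recording_set(p, "n1", 14, duration_s = 60, noise_sd = 0,
                                protocols = c("spontaneous", "passive"))
  f <- extract_features(rec)
  expect_true(all(is.na(f[, c("gain_start", "gain_end", "sfa_index",
                              "sag", "rebound")])))
  expect_false(anyNA(f[, c("isi_avg", "cv_isi", "r_in", "tau_m", "c_m",
                           "ap_threshold", "ahp")]))
})
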