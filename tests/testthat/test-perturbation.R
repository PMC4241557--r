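test_that("leak arithmetic is exact and invertible", {
  expect_equal(leak_for_target(1600), 0)
  expect_equal(leak_for_target(576), 1000 / 1600 - 1000 / 576,
               tolerance = 1e-12)
  expect_equal(leak_for_target(576), -1.111, tolerance = 1e-3)
  # applying g and recomputing the apparent R_in returns the target exactly
  for (r in c(100, 576, 2000)) {
    g <- leak_for_target(r)
    expect_equal(apparent_r_in(r, g), 1600, tolerance = 1e-9)
  }
  expect_error(leak_for_target(0), class = "validation_error")
})

make_params <- function() {
  set.seed(51)
  sample_neuron_params("P8-P9")
}

test_that("the identity perturbation changes nothing", {
  p <- make_params()
  q <- apply_perturbation(p, leak = NULL,
                          pharm = pharmacology_spec(0, 1))
  expect_equal(q$truth, p$truth)
  expect_equal(q$ap$ahp_depth, p$ap$ahp_depth)
})

test_that("apamin and TTX scale the targeted parameters arithmetically", {
  p <- make_params()
  p$ap$ahp_depth <- 20.9
  p$truth["ahp"] <- 20.9
  q <- apply_perturbation(p, pharm = pharmacology_spec(0.775, 1))
  expect_equal(q$ap$ahp_depth, 4.70, tolerance = 0.005)

  p$ap$amplitude <- 61.0
  p$truth["ap_amplitude"] <- 61.0
  q2 <- apply_perturbation(p, pharm = pharmacology_spec(0, 0.8))
  expect_equal(q2$ap$amplitude, 48.8, tolerance = 1e-9)
  expect_equal(q2$ap$rise_slope, p$ap$rise_slope * 0.8)
  expect_equal(q2$ap$decay_slope, p$ap$decay_slope * 0.8)
})

test_that("the AHP-CV coupling is monotone in the block fraction", {
  p <- make_params()
  cvs <- vapply(seq(0, 1, by = 0.25), function(b)
    apply_perturbation(p, pharm = pharmacology_spec(b, 1))$train$target_cv,
    numeric(1))
  expect_true(all(diff(cvs) > 0))
  expect_equal(cvs[1], p$train$target_cv)
  # default kappa = 4: a 75% block multiplies CV by 4
  expect_equal(cvs[4] / cvs[1], 1 + 4 * 0.75)
})

test_that("leak injection only affects the passive side", {
  p <- make_params()
  q <- apply_perturbation(p, leak = leak_spec(1600))
  expect_equal(q$passive$r_in, 1600, tolerance = 1e-9)
  expect_equal(q$ap$ahp_depth, p$ap$ahp_depth)
  expect_equal(q$train$target_cv, p$train$target_cv)
  expect_equal(unname(q$truth["tau_m"]), 1600 * p$passive$c_m / 1000)
})

test_that("phenotype shifts are mean score differences, locking translates", {
  set.seed(52)
  d <- data.frame(neuron_id = sprintf("n%02d", 1:12))
  for (nm in spontaneous_feature_names()) d[[nm]] <- rnorm(12, 5)
  d$stage <- "P7"; d$age_days <- 7
  m <- spontaneous_matrix(d)
  pm <- pca_covariance(m)
  s0 <- phenotype_shift(pm, d, d)
  expect_equal(unname(s0$shift), c(0, 0), tolerance = 1e-12)

  after <- d
  after$cv_isi <- d$cv_isi + 3
  s1 <- phenotype_shift(pm, d, after,
                        anchors = rbind(c(1, 1), c(5, 5)))
  expect_equal(s1$shift, s1$after_mean - s1$before_mean)
  expect_equal(unname(s1$locked["end", ] - s1$locked["start", ]),
               unname(s1$shift))
  expect_equal(unname(s1$locked["start", ]), c(1, 1))

  bad <- after[1:10, ]
  expect_error(phenotype_shift(pm, d, bad), class = "validation_error")
  # supplementary projection never alters the reference model
  expect_equal(pm$scores, pca_covariance(m)$scores)
})

test_that("perturbed cohorts shift towards the younger phenotype in PC space", {
  set.seed(53)
  # reference: pooled mature + juvenile cohort (feature level, analytic truth)
  mk <- function(stage, n) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      p <- sample_neuron_params(stage)
      d <- as.data.frame(t(p$truth[spontaneous_feature_names()]))
      d$neuron_id <- paste0(stage, i); d$stage <- stage
      d$age_days <- stage_bins()$age_min[match(stage, stage_bins()$stage)]
      d
    }))
  }
  ref <- rbind(mk("P7", 20), mk("P15-P16", 20))
  m <- spontaneous_matrix(ref)
  pm <- pca_covariance(m)
  cent_young <- colMeans(pm$scores[ref$stage == "P7", 1:2])
  cent_old <- colMeans(pm$scores[ref$stage == "P15-P16", 1:2])

  # apamin + TTX applied to the mature neurons, features recomputed
  before <- ref[ref$stage == "P15-P16", ]
  after <- before
  spec <- pharmacology_spec(0.225, 0.8)
  after$ahp <- before$ahp * (1 - 0.225)
  after$ap_amplitude <- before$ap_amplitude * 0.8
  after$ap_rise_slope <- before$ap_rise_slope * 0.8
  after$ap_decay_slope <- before$ap_decay_slope * 0.8
  after$cv_isi <- before$cv_isi * (1 + 4 * 0.225)
  sh <- phenotype_shift(pm, before, after)
  to_young <- cent_young - cent_old
  cosine <- sum(sh$shift * to_young) /
    sqrt(sum(sh$shift^2) * sum(to_young^2))
  expect_gt(cosine, 0.5)
})
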