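test_that("significance codes bin p values with strict inequalities", {
  expect_equal(as.character(significance_code(c(0.03, 0.005, 0.0005, 0.2))),
               c("p<0.05", "p<0.01", "p<0.001", "ns"))
  expect_equal(as.character(significance_code(c(0.05, 0.01, 0.001))),
               c("ns", "p<0.05", "p<0.01"))
  expect_error(significance_code(1.2), class = "validation_error")
  expect_error(significance_code(-0.1), class = "validation_error")
  # monotone: a smaller p never coarsens the code
  p <- sort(runif(50))
  expect_true(all(diff(as.integer(significance_code(p))) <= 0))
})

test_that("extreme separation is highly significant, degeneracy is not", {
  set.seed(31)
  v <- c(rnorm(20, 0), rnorm(20, 10))
  g <- rep(c("a", "b"), each = 20)
  res <- anova_tukey(v, g)
  expect_lt(res$p_adj, 0.001)

  res0 <- anova_tukey(rep(5, 30), rep(c("a", "b", "c"), 10))
  expect_equal(res0$p_adj, rep(1, 3))
})

test_that("stage names containing hyphens survive the Tukey pair parsing", {
  set.seed(32)
  v <- rnorm(60)
  g <- rep(c("P2-P3", "P8-P9", "P21-P23"), each = 20)
  res <- anova_tukey(v, g)
  expect_setequal(unique(c(res$stage_a, res$stage_b)),
                  c("P2-P3", "P8-P9", "P21-P23"))
  expect_equal(nrow(res), 3)
})

test_that("Tukey adjustment is never anti-conservative vs pairwise t", {
  set.seed(33)
  for (i in 1:10) {
    v <- rnorm(45, rep(c(0, 0.5, 1), each = 15))
    g <- rep(c("a", "b", "c"), each = 15)
    res <- anova_tukey(v, g)
    for (r in seq_len(nrow(res))) {
      ia <- g == res$stage_a[r]; ib <- g == res$stage_b[r]
      p_t <- t.test(v[ia], v[ib], var.equal = TRUE)$p.value
      # small slack: the pairwise t uses its own 2-group error df, so tiny
      # numerical crossings can occur without anti-conservatism in practice
      expect_gte(res$p_adj[r], p_t - 0.005)
    }
  }
})

test_that("Tukey p values agree with a permutation max-statistic oracle", {
  set.seed(34)
  v <- rnorm(45, rep(c(0, 0.8, 1.6), each = 15))
  g <- rep(c("a", "b", "c"), each = 15)
  res <- anova_tukey(v, g)
  orc <- tukey_permutation_oracle(v, g, B = 4000)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  m <- match(key(res$stage_a, res$stage_b), key(orc$stage_a, orc$stage_b))
  expect_lt(max(abs(res$p_adj - orc$p_perm[m])), 0.05)
})

test_that("the stacking table is complete, symmetric and typed", {
  set.seed(35)
  cohort <- data.frame(stage = rep(c("P5", "P7", "P14"), each = 5))
  for (nm in feature_names()) cohort[[nm]] <- rnorm(15)
  cohort$gain_start <- NA_real_                  # an unmeasured parameter
  tab <- build_stacking_table(cohort)
  expect_equal(nrow(tab), 3 * 16)                # S(S-1)/2 pairs x 16
  expect_true(all(tab$code[tab$parameter == "gain_start"] == "not_measured"))
  expect_true(all(tab$code[tab$parameter == "cv_isi"] != "not_measured"))
  key <- paste(tab$stage_a, tab$stage_b)
  expect_equal(length(unique(key)), 3)

  # minimal table: 2 stages, 1 parameter
  small <- data.frame(stage = rep(c("P5", "P7"), each = 4),
                      cv_isi = rnorm(8))
  t2 <- build_stacking_table(small, parameters = "cv_isi")
  expect_equal(nrow(t2), 1)
  expect_error(build_stacking_table(small[small$stage == "P5", ],
                                    parameters = "cv_isi"),
               class = "insufficient_data_error")
})
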