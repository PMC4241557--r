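make_cohort_matrix <- function(x, stage = NULL, age = NULL) {
  d <- as.data.frame(x)
  names(d) <- spontaneous_feature_names()[seq_len(ncol(x))]
  for (nm in setdiff(spontaneous_feature_names(), names(d))) d[[nm]] <- 1
  d$neuron_id <- sprintf("n%03d", seq_len(nrow(d)))
  d$stage <- stage %||% rep("P7", nrow(d))
  d$age_days <- age %||% rep(7, nrow(d))
  d
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("mean-normalization divides by |mean| and inverts exactly", {
  set.seed(41)
  d <- make_cohort_matrix(matrix(rnorm(80, 5), 10))
  d$ap_threshold <- rnorm(10, -43)               # negative-mean column
  m <- spontaneous_matrix(d)
  expect_equal(colMeans(m$x)[["isi_avg"]], 1, tolerance = 1e-12)
  expect_equal(colMeans(m$x)[["ap_threshold"]], -1, tolerance = 1e-12)
  expect_true(all(sign(m$x[, "ap_threshold"]) ==
                  sign(d$ap_threshold)))
  raw <- denormalize(m)
  expect_equal(unname(raw), unname(as.matrix(d[, spontaneous_feature_names()])),
               tolerance = 1e-12)
  dd <- d; dd$cv_isi <- dd$cv_isi - mean(dd$cv_isi)   # zero-mean column
  expect_error(spontaneous_matrix(dd), class = "validation_error")
})

test_that("Ward clustering equals exhaustive-search agglomeration (n <= 6)", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:6, 1)
    x <- matrix(rnorm(n * 3), n)
    d <- ahc_ward(x)
    orc <- ward_oracle(x)
    expect_equal(sort(d$height), sort(orc$heights), tolerance = 1e-8)
    for (k in 2:(n - 1)) {
      expect_equal(canon_partition(cutree(d$hclust, k)),
                   canon_partition(orc$partitions[[k]]))
    }
    expect_true(all(diff(d$height) >= -1e-9))    # Ward monotonicity
  }
})

test_that("collinear points on a line merge nearest first", {
  x <- matrix(c(0, 1, 10), ncol = 1)
  d <- ahc_ward(x)
  orc <- ward_oracle(x)
  expect_equal(d$height, orc$heights, tolerance = 1e-10)
  expect_equal(d$height[1], 0.5)                 # delta-SSE of merging {0,1}
  expect_equal(canon_partition(cutree(d$hclust, 2)), c(1, 1, 2))

  x2 <- matrix(c(1, 1, 5), ncol = 1)             # duplicates merge at 0
  expect_equal(ahc_ward(x2)$height[1], 0)
})

test_that("the automatic cut finds well-separated blobs", {
  set.seed(43)
  blob <- function(center, n) sweep(matrix(rnorm(n * 2, sd = 0.5), n), 2,
                                    center, "+")
  x3 <- rbind(blob(c(0, 0), 15), blob(c(10, 0), 15), blob(c(0, 10), 15))
  d <- make_cohort_matrix(x3, stage = rep(c("P5", "P7", "P14"), each = 15),
                          age = rep(c(5, 7, 14), each = 15))
  m <- spontaneous_matrix(d, normalization = "none")
  cc <- auto_cut(ahc_ward(m), m)
  expect_equal(cc$k, 3)
  truth <- rep(1:3, each = 15)
  expect_equal(length(unique(tapply(cc$membership, truth,
                                    function(z) unique(z)))), 3)
  expect_true(all(tapply(cc$membership, truth,
                         function(z) length(unique(z))) == 1))

  x2 <- rbind(blob(c(0, 0), 20), blob(c(10, 0), 20))
  m2 <- spontaneous_matrix(make_cohort_matrix(x2), normalization = "none")
  expect_equal(auto_cut(ahc_ward(m2), m2)$k, 2)
})

test_that("centroids, central objects and class ages are consistent", {
  set.seed(44)
  x <- rbind(matrix(rnorm(20, 0, 0.3), 10), matrix(rnorm(20, 8, 0.3), 10))
  d <- make_cohort_matrix(x, age = rep(c(3, 17), each = 10))
  m <- spontaneous_matrix(d, normalization = "none")
  cc <- auto_cut(ahc_ward(m), m)
  expect_equal(cc$k, 2)
  for (c in 1:2) {
    i <- which(cc$membership == c)
    expect_equal(unname(cc$centroids[c, 1:2]),
                 unname(colMeans(m$x[i, 1:2, drop = FALSE])))
    ctr <- match(cc$central_objects[c], d$neuron_id)
    dists <- sqrt(rowSums(sweep(m$x[i, , drop = FALSE], 2,
                                cc$centroids[c, ])^2))
    expect_equal(min(dists), dists[match(ctr, i)])
  }
  expect_setequal(round(cc$class_age[, "mean"]), c(3, 17))
  expect_equal(auto_cut(ahc_ward(m), m, k = 4)$k, 4)   # fixed-k override
})

test_that("degenerate dendrograms fall back to two classes with a warning", {
  x <- matrix(rep(c(0, 0), 4), 4, byrow = TRUE)   # four identical points
  m <- spontaneous_matrix(make_cohort_matrix(x), normalization = "none")
  expect_warning(cc <- auto_cut(ahc_ward(m), m), "flat")
  expect_equal(cc$k, 2)
})

test_that("covariance PCA solves the constructed eigenproblem exactly", {
  # data built so the divisor-n covariance is [[2,1],[1,2]]:
  # eigenvalues 3 and 1, PC1 = (1,1)/sqrt(2), fractions 0.75/0.25
  z1 <- sqrt(3) * rep(c(1, -1), 4)
  z2 <- rep(c(1, 1, -1, -1), 2)
  v1 <- c(1, 1) / sqrt(2); v2 <- c(1, -1) / sqrt(2)
  x <- cbind(z1, z2) %*% rbind(v1, v2)
  S <- crossprod(scale(x, scale = FALSE)) / nrow(x)
  expect_equal(unname(S), matrix(c(2, 1, 1, 2), 2), tolerance = 1e-12)
  pm <- pca_covariance(x)
  expect_equal(unname(pm$eigenvalues), c(3, 1), tolerance = 1e-12)
  expect_equal(unname(pm$variance_fraction), c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(abs(unname(pm$components[, 1])), rep(1 / sqrt(2), 2),
               tolerance = 1e-12)
  expect_gt(pm$components[which.max(abs(pm$components[, 1])), 1], 0)
})

test_that("PCA invariants: reconstruction, score covariance, rank", {
  set.seed(45)
  d <- make_cohort_matrix(matrix(rnorm(64, 5), 8))
  m <- spontaneous_matrix(d)
  pm <- pca_covariance(m)
  expect_equal(sum(pm$variance_fraction), 1, tolerance = 1e-12)
  rec <- pm$scores %*% t(pm$components) +
    matrix(pm$means, nrow(m$x), ncol(m$x), byrow = TRUE)
  expect_equal(unname(rec), unname(m$x), tolerance = 1e-10)
  cv <- crossprod(pm$scores) / nrow(m$x)
  expect_equal(unname(diag(cv)), unname(pm$eigenvalues), tolerance = 1e-10)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-10)
  expect_equal(unname(crossprod(pm$components)), diag(8), tolerance = 1e-10)

  coll <- make_cohort_matrix(cbind(1:8, 2 * (1:8) + 3))
  expect_warning(p2 <- pca_covariance(
    spontaneous_matrix(coll[, c(names(coll))], normalization = "none")$x[, 1:2]),
    "rank")
  expect_equal(p2$variance_fraction[1], 1, tolerance = 1e-12)
})

test_that("supplementary projection reproduces training scores, never refits", {
  set.seed(46)
  d <- make_cohort_matrix(matrix(rnorm(80, 5), 10))
  m <- spontaneous_matrix(d)
  pm <- pca_covariance(m)
  s <- project_supplementary(pm, d[3, ])
  expect_equal(unname(s[1, ]), unname(pm$scores[3, ]), tolerance = 1e-10)
  mean_row <- d[1, ]
  raw <- as.matrix(d[, spontaneous_feature_names()])
  mean_row[, spontaneous_feature_names()] <- as.list(colMeans(raw))
  s0 <- project_supplementary(pm, mean_row)
  expect_equal(max(abs(s0)), 0, tolerance = 1e-10)
  sdup <- project_supplementary(pm, rbind(d[3, ], d[3, ]))
  expect_equal(sdup[1, ], sdup[2, ])
  expect_error(project_supplementary(pm, d[, 1:4]),
               class = "validation_error")
})

test_that("stage trajectories, ellipses and the SD-age correlation behave", {
  scores <- cbind(F1 = c(1, 1, 2, 2, 4, 4), F2 = c(0, 0, 1, 1, 3, 3))
  traj <- stage_trajectory(scores, stage = rep(c("P5", "P7", "P14"), each = 2),
                           age_days = rep(c(5, 7, 14), each = 2))
  expect_equal(traj$stage, c("P5", "P7", "P14"))
  expect_equal(traj$f1_sd, rep(0, 3))
  ell <- variability_ellipse(data.frame(stage = c("a", "b", "c"),
                                        f1_sd = c(1, 2, 2), f2_sd = c(1, 0.5, 1),
                                        age_mean = 1:3))
  expect_equal(ell$area, c(pi, pi, 2 * pi))
  # doubling both SDs quadruples the area
  expect_equal(pi * 4 * 2, 4 * (pi * 2 * 1))

  tr <- data.frame(age_mean = 1:10, f1_sd = seq(5, 0.5, length.out = 10))
  r <- sd_age_correlation(tr)
  expect_equal(r$r, -1, tolerance = 1e-12)
  expect_equal(r$n, 10)
  expect_error(sd_age_correlation(data.frame(age_mean = 1:5,
                                             f1_sd = rep(1, 5))),
               class = "degenerate_error")
})
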