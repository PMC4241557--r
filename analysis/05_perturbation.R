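#!/usr/bin/env Rscript
# Emulate the pharmacology / dynamic-clamp phenotype-reversal experiments.
#
# Two manipulations are applied at the generator-parameter level and traced
# in the reference PCA space:
#   (a) P8-like neurons + apamin (75-80% AHP block) + negative leak to an
#       apparent R_in of 1600 MOhm -- the neonatal value;
#   (b) P15-like neurons + low-dose apamin (20-25% AHP block) + 20 nM TTX
#       (sodium_scale 0.8).
# Both shifts should point from the mature toward the younger phenotype.

suppressPackageStartupMessages(library(ephystraj))
set.seed(20260925)

features <- read_feature_table("results/features.csv")
snm <- spontaneous_matrix(features)
pm <- pca_covariance(snm)
k3 <- auto_cut(ahc_ward(snm), snm, k = 3)
ages <- k3$class_age[, "mean"]
cents <- t(vapply(order(ages), function(c)
  colMeans(pm$scores[k3$membership == c, 1:2, drop = FALSE]), numeric(2)))
rownames(cents) <- c("young", "mid", "old")

perturb_cohort <- function(stage, n, leak, pharm, kappa = 4) {
  before <- list(); after <- list()
  for (i in seq_len(n)) {
    p <- sample_neuron_params(stage)
    q <- apply_perturbation(p, leak = leak, pharm = pharm, kappa = kappa)
    mk <- function(z, id) {
      d <- as.data.frame(t(z$truth[spontaneous_feature_names()]))
      d$neuron_id <- id
      d
    }
    before[[i]] <- mk(p, sprintf("%s%02d", stage, i))
    after[[i]] <- mk(q, sprintf("%s%02d", stage, i))
  }
  phenotype_shift(pm, do.call(rbind, before), do.call(rbind, after))
}

shift_a <- perturb_cohort("P8-P9", 10, leak = leak_spec(1600),
                          pharm = pharmacology_spec(0.775, 1,
                                                    "apamin 100 nM - leak"))
shift_b <- perturb_cohort("P15-P16", 12, leak = NULL,
                          pharm = pharmacology_spec(0.225, 0.8,
                                                    "apamin 5 nM + TTX 20 nM"))

cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
cat("Apamin + negative leak on P8-like neurons (n = 10):\n")
cat(sprintf("  shift (F1, F2) = (%.2f, %.2f); cosine with old->young axis:"
            , shift_a$shift[1], shift_a$shift[2]))
cat(sprintf(" %.2f\n", cosine(shift_a$shift, cents["young", ] - cents["mid", ])))
cat("Apamin + TTX on P15-like neurons (n = 12):\n")
cat(sprintf("  shift (F1, F2) = (%.2f, %.2f); cosine with mature->mid axis:",
            shift_b$shift[1], shift_b$shift[2]))
cat(sprintf(" %.2f\n", cosine(shift_b$shift, cents["mid", ] - cents["old", ])))

out <- rbind(
  data.frame(condition = "apamin100nM_minus_leak_P8",
             f1_shift = shift_a$shift[1], f2_shift = shift_a$shift[2],
             n = shift_a$n),
  data.frame(condition = "apamin5nM_TTX20nM_P15",
             f1_shift = shift_b$shift[1], f2_shift = shift_b$shift[2],
             n = shift_b$n))
write.csv(out, "results/phenotype_shifts.csv", row.names = FALSE)
cat("Shift vectors written to results/phenotype_shifts.csv\n")
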