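#!/usr/bin/env Rscript
# Stage 6: discrimination and calibration on the held-out test split.
#
# Compares the twin probability against CHA2DS2-VASc, HAS-BLED and the
# STS-style surrogate: AUC with stratified bootstrap CI, Youden-threshold
# sensitivity/specificity/PPV/NPV, and (for probability scores)
# Hosmer-Lemeshow, calibration slope and Brier score.

library(poaftwin)
seed <- 1L
cohort <- load_cohort_csv("results/cohort.csv")
splits <- split_cohort(cohort, seed = seed + 20L)
panel <- read.csv("results/scores.csv")

idx <- match(splits$test$id, panel$patient_id)
metrics <- compare_scores(panel[idx, ], splits$test$poaf_event,
                          n_boot = 2000, seed = seed + 60L)
write.csv(metrics, "results/metrics.csv", row.names = FALSE)
print(metrics[, c("score", "auc", "auc_lo", "auc_hi", "sensitivity",
                  "specificity", "brier")], digits = 3)
cat(sprintf("\ntwin AUC %.2f vs CHA2DS2-VASc %.2f on %d held-out patients\n",
            metrics$auc[metrics$score == "twin_prob"],
            metrics$auc[metrics$score == "chads_vasc"], nrow(splits$test)))
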