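#!/usr/bin/env Rscript
# Stage 5: the virtual randomized controlled trial.
#
# Calibrates twins for the GAN-sampled virtual cohort, randomizes 1:1, and
# applies the twin-guided policy (electrolyte repletion to K > 4.0 / Mg >
# 2.0 mEq/L plus prophylaxis for twin probability above the 60th
# percentile, delivered 60 h before surgery). Events follow the
# ground-truth daily hazard over the 7-day horizon. Also sweeps the
# intervention lead time to locate the highest-yield window.

library(poaftwin)
seed <- 1L
gt <- gt_config(seed = seed)
virtual <- load_cohort_csv("results/virtual_cohort.csv")

cache <- build_twin_cache()
twins <- calibrate_cohort(virtual, cache = cache)
twin_prob <- twin_risk_probability(twins, virtual)

tc <- trial_config(n_total = nrow(virtual), seed = seed + 40L)
report <- simulate_trial(virtual, twin_prob, gt, tc)
print(report)
write_trial_report(report, "results/trial_report.json", "results/km_curves.csv")

sweep <- window_sweep(virtual, twin_prob, gt, tc)
write.csv(sweep$table, "results/window_sweep.csv", row.names = FALSE)
cat(sprintf("lead-time sweep: lowest incidence at %d h before surgery\n",
            sweep$best_lead_h))
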