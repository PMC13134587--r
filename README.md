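# poaftwin

Digital-twin simulation and virtual randomized trials for postoperative
atrial fibrillation (POAF) after cardiac surgery.

POAF strikes roughly a quarter of cardiac-surgery patients within the
first postoperative week, and static scores (CHA₂DS₂-VASc, HAS-BLED,
operative risk calculators) predict it poorly because they cannot see the
electrophysiological substrate — repolarization prolongation, conduction
slowing, hypokalemia/hypomagnesemia, inflammation. `poaftwin` is a tested
R workbench for the digital-twin alternative, built around a synthetic
registry whose event mechanism is known exactly, so every downstream
stage can be validated against recoverable ground truth:

- **Synthetic cohorts** (`generate_cohort`, `inject_and_impute`,
  `split_cohort`): correlated perioperative covariates and a
  discrete-time daily POAF hazard, logistic-linear in a vulnerability
  composite, electrolyte deficits below the 4.0 / 2.0 mEq/L targets,
  log-CRP and age — calibrated so the untreated 7-day cumulative
  incidence is 27.6%:

  logit h_d = logit(h₀) + log(s_d) + 0.8·z_vuln + 0.35·deficit + 0.3·z_CRP + 0.25·z_age

- **Cell electrophysiology** (`simulate_ap`, `ap_metrics`,
  `scale_conductances`): a six-current Hodgkin-Huxley-formalism atrial
  cell (I_Na, I_CaL, I_Kr, I_Ks, I_K1, leak; RK4, dt = 0.02 ms) with
  APD90 ≈ 285 ms and V_rest ≈ −81 mV at 1 Hz, monotone in the s_Kr,
  s_Ks, s_CaL conductance scales.
- **Tissue propagation** (`simulate_fiber`, `simulate_fiber_bidomain`,
  `conduction_velocity`, `apd_dispersion`): operator-split 1D monodomain
  plus an equivalence-checked bidomain solver (equal anisotropy reduces
  to harmonic-mean monodomain), CV ∝ √D.
- **Twin calibration** (`calibrate_twin`, `vulnerability_index`): bounded
  inversion of APD90(s_Kr) + 60 ms = QTc (Bazett), cohort-scale via a
  monotone spline cache, plus a logistic vulnerability composite.
- **GAN cohorts** (`fit_generator`, `sample_cohort`, `fidelity_report`,
  `copula_baseline`): a compact tabular GAN (two-hidden-layer MLPs,
  non-saturating loss, Adam, moment-matching regularizer) validated by
  per-feature Kolmogorov-Smirnov, categorical total-variation and
  correlation-gap checks against a Gaussian-copula baseline.
- **Virtual RCT** (`simulate_trial`, `window_sweep`, `km_curve`,
  `logrank_test`): 1:1 seeded allocation, twin-guided electrolyte
  repletion + prophylaxis above the 60th twin-probability percentile,
  7-day event simulation, LOS / ICU / stroke secondary outcomes, and a
  preoperative lead-time sweep that recovers the 48–72 h benefit window.
- **Evaluation** (`roc_auc`, `youden_threshold`, `hosmer_lemeshow`,
  `calibration_slope`, `brier_score`, `compare_scores`): the full
  discrimination / calibration suite, implemented in-module and tested
  against pair-counting, `pROC` and `survival` oracles.

## Worked example

The numbered scripts under `analysis/` run the whole study into
`results/`; `Rscript analysis/01_simulate_cohort.R` through
`06_evaluate_scores.R`. The core of it, interactively:

```r
library(poaftwin)

gt     <- gt_config(seed = 1)                      # calibrated mechanism
cohort <- generate_cohort(gt, 10000, seed = 1)
mean(cohort$poaf_event)                            # 0.2727 (target 0.276)

twins  <- calibrate_cohort(cohort)                 # cached s_Kr inversion
prob   <- twin_risk_probability(twins, cohort)
report <- simulate_trial(cohort, prob, gt, trial_config(seed = 41))
print(report)
```

```
Virtual RCT (5000 vs 5000)
  POAF incidence: 18.0% vs 27.1% (RRR 33.7%, p <0.001)
  LOS: 7.5 vs 8.0 d (p <0.001); ICU: 2.3 vs 2.5 d (p <0.001)
  Stroke: 1.5% vs 1.6% (p 0.628); log-rank p <0.001
```

The control arm sits at the mechanism's calibrated 7-day incidence; the
twin-guided arm's relative risk reduction lands in the low 30s because
treated patients get both electrolyte repletion and window-timed
prophylaxis. Sweeping the intervention lead time recovers the built-in
benefit window:

```r
window_sweep(cohort, prob, gt, trial_config(seed = 41))$best_lead_h
#> 48        # lowest incidence across the 48-72 h plateau
```

and on the held-out split the twin probability discriminates far better
than the clinical scores (`analysis/06_evaluate_scores.R` prints
AUC 0.69 vs 0.58 for CHA₂DS₂-VASc at n = 1500).

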