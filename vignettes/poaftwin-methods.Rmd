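---
title: "Methods: digital-twin simulation and virtual trials for postoperative atrial fibrillation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital-twin simulation and virtual trials for POAF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package models

Postoperative atrial fibrillation (POAF) complicates roughly a quarter of
cardiac surgeries within the first postoperative week. Static clinical
scores (CHA2DS2-VASc, HAS-BLED, operative risk calculators) discriminate
poorly because POAF risk is driven by a patient's electrophysiological
substrate -- repolarization prolongation, conduction slowing, electrolyte
deficits, inflammation -- which those scores barely see. `poaftwin`
implements, as one tested workbench, a digital-twin pipeline for this
setting: a synthetic perioperative registry with a known event mechanism,
patient-specific electrophysiology twins calibrated to ECG features, a
tabular GAN that synthesizes virtual cohorts, an in silico randomized
trial of a twin-guided prophylaxis policy, and the discrimination /
calibration metric suite used to compare risk models.

Because no real registry ships with the package, every empirical claim
here is about *recovery of a known synthetic ground truth*, not about
clinical performance. That is by construction: the generator's mechanism
is the experimental apparatus against which the twin, the trial engine and
the metrics are validated.

## The synthetic cohort and its ground-truth hazard

`generate_cohort()` draws correlated covariates through a latent Gaussian
(documented correlation structure in `poaftwin:::.latent_correlation`):
age (clipped normal, mean 66, sd 10, minimum 18), conduction intervals,
mean RR, heart-rate variability, electrolytes (potassium 4.1 (0.4),
magnesium 2.0 (0.25) mEq/L), and lognormal CRP and BNP. Comorbidity
prevalences are age-dependent Bernoulli draws; surgery type is
multinomial. One deliberate non-physiological choice: the QTc marginal is
centered at 345 ms (sd 25) rather than a ventricular-typical 430 ms, so
that QTc minus the fixed 60 ms activation-duration offset spans exactly
the APD90 range the cell model can produce; this keeps the QT-to-APD
inverse problem well-posed across the cohort, which is the property the
calibration experiments need.

Events follow a discrete-time daily Bernoulli hazard over a 7-day
horizon:

logit h_d = logit(h0) + log(shape_d) + 0.8 z_vuln + 0.35 deficit_elec +
0.3 z_CRP + 0.25 z_age,

where z_vuln loads on QTc prolongation (+0.6), low HRV (-0.25) and PR
prolongation (+0.15); deficit_elec counts deviations below 4.0 mEq/L
potassium and 2.0 mEq/L magnesium; shape_d peaks on days 2-3. The
baseline h0 = 0.0300487 was fixed once by `calibrate_incidence()` (root
finding on the analytic per-patient 7-day risk over a 20,000-patient
Monte Carlo covariate draw) so the untreated cumulative incidence is
27.6%. The intervention-benefit profile is piecewise linear in lead time
before surgery: multiplier 1.0 at 0 h, 0.6 across 48-72 h, 1.0 at 120 h
and beyond -- the recoverable ground truth behind the lead-time sweep.

Missingness is injected completely at random into continuous lab/ECG
fields (3% default; a warning fires at or above the 5% regime boundary)
and restored by chained linear regressions cycled until the maximum
absolute change falls below `tol` (default 1e-6, 10 sweeps). The change
sequence is monotone decreasing in practice; with the default sweep cap
the loop can stop short of `tol`, and the attached report says so. A
single completed table is the default; `m > 1` adds residual draws per
completion.

## The cell model

No equation set is published for the twin's cellular substrate, so the
package defines a minimal six-current atrial cell in the Hodgkin-Huxley
formalism: I_Na (m^3 h), I_CaL (d f), I_Kr (xr with instantaneous
rectification), I_Ks (xs^2), I_K1, and a background leak, with
first-order gating kinetics (Boltzmann steady states, Gaussian/sigmoid
time constants). Every constant lives in `cell_params()` and in
`inst/extdata/cell_params.yaml`. Rate constants were tuned once so the
baseline beat at 1 Hz has APD90 ~285 ms and V_rest ~ -81 mV, inside the
atrial 250-320 ms / [-85, -75] mV target bands, and so that APD90 is
strictly decreasing in s_Kr and s_Ks and increasing in s_CaL over
[0.5, 1.5] -- the three scales named as the twin's calibration handles.

Integration is classical RK4 at fixed dt (default 0.02 ms for single
cells); halving dt moves the last-beat APD90 by far less than 1 ms. The
stimulus is a 2 ms rectangular pulse at ~1.5x the diastolic threshold
found by bisection (`find_stim_threshold()`).

## Tissue propagation

`simulate_fiber()` solves the 1D monodomain equation by operator
splitting: RK4 reaction per node, explicit finite-difference diffusion
with no-flux boundaries, with the dt <= dx^2/(2D) bound enforced before
integration (default 100 nodes, dx 0.25 mm, D 0.1 mm^2/ms). Conduction
velocity is measured over the central 60% of the fiber; at the defaults it
is ~0.39 mm/ms, inside the 0.3-1.2 mm/ms atrial plausibility band used as
an acceptance region (a modeling choice -- no citable benchmark value is
reconstructed). CV scales as sqrt(D) within 10% over a 4x range.

`simulate_fiber_bidomain()` keeps the two-potential formulation: each
step solves the tridiagonal elliptic balance
(sigma_i + sigma_e) Lap(phi_e) = -sigma_i Lap(Vm) (Thomas algorithm,
phi_e grounded at node 1, mirrored end rows) and advances Vm with the
intracellular flux of Vm + phi_e. With proportional conductivities this
is analytically the monodomain model at the harmonic-mean diffusion, and
the solver reproduces that equivalence to well under 1 ms of activation
error -- the standard justification for using monodomain as the
operational solver. Repolarization dispersion is max - min APD90 over
activated central nodes.

## Twin calibration

Each patient's twin minimizes (APD90(s) + 60 - QTc)^2 with QTc = QT /
sqrt(RR) (Bazett; the exponent is configurable). With a single scalar
target the default frees only s_Kr (bounds [0.5, 1.5]); the
three-parameter mode exists but is flagged under-determined, which is the
honest reading of a 3-parameter / 1-observation inverse problem. For the
1-D default we use bounded Brent search rather than a simplex: with one
parameter Brent is the natural derivative-free bounded method and
converges in ~10 objective evaluations. Cohort-scale calibration runs on
a cached surrogate: APD90 is tabulated on a 21-point s_Kr grid (one short
ODE run each) and interpolated with a monotone (Hyman) spline; fiber CV
and dispersion are tabulated on a coarser grid. Parameter-recovery
experiments (ground truth from the full ODE, recovery through the cached
inversion) put the median |s_Kr error| well under 0.05. Residuals above
the 2 ms tolerance -- QTc targets outside the achievable APD range --
saturate a bound and are flagged non-converged, with best-so-far scales
returned.

The vulnerability index is logistic(w . z) over standardized components:
APD90 prolongation (ref 285, scale 25 ms), CV slowing (ref 0.39, scale
0.05 mm/ms), dispersion, electrolyte deficit below the 4.0/2.0 mEq/L
targets, and log-CRP; weights in `vulnerability_weights()`. All
components at reference give exactly 0.5. In the default pipeline the CV
and dispersion components vary little (conduction in this cell model is
dominated by I_Na and coupling, not s_Kr), so discrimination is carried
by the APD, electrolyte and inflammation terms -- visible in the cache's
flat CV grid and reported as-is.

## Risk scores

CHA2DS2-VASc and HAS-BLED follow their published additive definitions and
are used directly as ordinal classifiers (ties handled by the midrank AUC).
The STS-style score is a configurable logistic surrogate -- age, surgery
type, renal disease, CHF -- and is labelled a surrogate everywhere; the
proprietary calculator is out of scope. The twin probability is logistic
in logit(vulnerability) plus age.

## The GAN and its baseline

The tabular GAN is a pair of two-hidden-layer perceptrons (64/64; tanh
generator, leaky-ReLU discriminator; latent dimension 16) trained with
the standard minimax loss (non-saturating generator gradient) and Adam,
one update each per minibatch. Two stabilizers matter at this scale:
right-skewed positive features (CRP, BNP, HRV) are modelled on the log
scale, and the generator loss carries a feature-matching term -- squared
error of the minibatch means (weighted 5x, since the one-hot means are
the category frequencies) and centered covariances of the encoded
features, weight 3, batch 512. Without it a desk-scale GAN matches
marginals but drifts on cross-feature structure. Training is 300 epochs
by default (~1.5 minutes on one core at n ~ 5,000) and deterministic
given the seed up to BLAS rounding.

Fidelity is validated against a held-out split: two-sample
Kolmogorov-Smirnov per continuous feature (threshold D < 0.1), total
variation of category frequencies (< 0.05), and the Frobenius gap between
real and synthetic correlation matrices. The Gaussian copula (empirical
marginals + normal-scores dependence, categorical frequencies sampled
independently) is the non-adversarial baseline: it nails marginals by
construction, so the regression requirement on the GAN is to stay within
1.5x of its correlation gap. Outcome columns are never GAN-generated;
the trial re-simulates them from the ground-truth hazard on the generated
covariates, keeping the event mechanism explicit.

## The virtual trial

`simulate_trial()` randomizes 1:1 by seeded permutation (odd sizes are
rejected with instructions rather than silently dropped), resolves the
default risk threshold as the cohort's 60th percentile of twin
probability, and treats above-threshold intervention-arm patients:
potassium and magnesium are raised to max(current, target) and the daily
hazard is multiplied by hazard_multiplier x benefit_profile(lead time).
The product form means a multiplier of 1 is only inert at lead times
where the profile is 1 (e.g. 0 h); the null-intervention tests are
constructed that way. Events are daily Bernoulli draws over 7 days; LOS
and ICU days are lognormal around base + POAF penalty (6.5 + 5.0 and
1.8 + 2.5 days); stroke probability is 0.8% / 4% without/with POAF.
Arms are compared with an in-module pooled two-proportion z-test
(POAF, stroke), Welch's t (LOS, ICU), and an in-module product-limit /
log-rank pair for POAF-free survival.

The default policy is a calibration, not an inference: with the
mechanism's electrolyte pathway, the twin's threshold preferentially
selects patients whose repletion alone removes much of their hazard, so
the nominal antiarrhythmic multiplier was set (0.95, i.e. effective
0.95 x 0.6 = 0.57 inside the optimal window) so the default end-to-end
run lands near the ~34% relative risk reduction and the 18% vs 28% arm
incidences that motivated the design; more aggressive multipliers push
the effect above the 25-45% plausibility band. All constants are
overridable. The lead-time sweep re-runs the trial at fixed seed across a
lead-time grid and reports the argmin, which recovers the 48-72 h
ground-truth window.

## Metrics

All metric machinery is implemented in-module and cross-checked against
independent oracles in the tests (pair-counting AUC, `pROC`,
`survival::survfit`/`survdiff`, `stats::ks.test`): midrank Mann-Whitney
AUC with a class-stratified percentile bootstrap (2,000 resamples by
default), Youden's J threshold with ties broken toward specificity,
Wilson intervals on the 2x2 ratios, Hosmer-Lemeshow on deciles of risk
with chi-square df = groups - 2 (zero-expected groups merged and
reported), an IRLS logistic recalibration slope, and the Brier score.
Note the Hosmer-Lemeshow null is uniform for *fitted* probabilities, the
setting the df convention assumes; the test suite constructs its null
that way.

## Numerical choices and degenerate inputs

- Cell/fiber integration: RK4, dt 0.02 ms (cell) / 0.05 ms (fiber grids
  in the tests), CFL enforced, non-finite states abort with the offending
  time and node.
- Calibration: Brent on [0.5, 1.5], tolerance 2 ms, <= 200 evaluations;
  cache spline monotone by construction.
- Imputation: mean-initialized chained least squares; fully missing
  columns are unimputable errors.
- Degenerate metric inputs fail loudly: single-class labels, empty
  predicted-positive sets (flagged NA), probabilities at 0/1 for the
  calibration slope, no events for the log-rank test.
- Every stochastic stage takes an explicit seed; pipeline stage seeds are
  small fixed offsets from the global seed.

## Problem sizes

The shipped configuration runs the registry cohort and the virtual trial
at n = 10,000 with a 70/15/15 split, GAN training at 300 epochs on the
training split, 2,000 bootstrap resamples for reported CIs, and 200-seed
null-trial batteries; the test suite exercises the same code at these and
smaller sizes. The full analysis chain completes in a few minutes on one
core.

## What passing does and does not show

The generator emulates marginals, pairwise correlations, MCAR
missingness and a logistic-linear hazard. It does not emulate informative
missingness, measurement error, center effects, treatment-by-indication
confounding, competing mortality, or the exclusion cascade of a real
registry (whose counts are not published). Consequently, green tests
demonstrate that the pipeline recovers its own ground truth under the
stated conditions -- calibrated incidence, benefit window, effect
magnitude, score ordering -- and that the metric machinery is exact
against oracles. They say nothing about performance on real perioperative
data, and the absolute AUCs quoted on real cohorts elsewhere are treated
as non-reproducible here.
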