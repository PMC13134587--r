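# Synthetic perioperative cohort generator with a known ground-truth POAF
# mechanism: correlated demographic/ECG/lab covariates, a discrete-time
# daily Bernoulli hazard that is logistic-linear in a vulnerability
# composite, MCAR missingness injection, chained-equation imputation, and
# 70/15/15 cohort splitting.

# run code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.cohort_columns <- c(
  "id", "age", "sex", "hypertension", "diabetes", "chf", "vascular_disease",
  "prior_stroke_tia", "renal_disease", "liver_disease", "bleeding_history",
  "labile_inr", "alcohol_use", "antiplatelet_use", "surgery_type",
  "pr_ms", "qrs_ms", "qt_ms", "rr_s", "hrv_sdnn_ms",
  "potassium_meq_l", "magnesium_meq_l", "crp_mg_l", "bnp_pg_ml",
  "poaf_event", "poaf_day", "censored"
)

.continuous_lab_ecg <- c("pr_ms", "qrs_ms", "qt_ms", "rr_s", "hrv_sdnn_ms",
                         "potassium_meq_l", "magnesium_meq_l", "crp_mg_l",
                         "bnp_pg_ml")

#' Ground-truth configuration for the synthetic POAF mechanism
#'
#' Defines the generative law of the synthetic cohort: feature marginals and
#' correlations, the daily POAF hazard (logistic-linear in a vulnerability
#' composite, electrolyte deficits, inflammation and age, with a day-shape
#' profile peaking on postoperative days 2-3), the MCAR missingness
#' fraction, and the time-varying preoperative intervention-benefit profile
#' whose hazard multiplier is minimal (0.6) for lead times of 48-72 h before
#' surgery, rising linearly to 1.0 at 0 h and at 120 h.
#'
#' The default \code{baseline_daily_hazard} is calibrated so that the
#' untreated 7-day cumulative incidence matches
#' \code{target_7day_incidence} = 27.6\% (see
#' \code{\link{calibrate_incidence}}).
#'
#' @param baseline_daily_hazard per-day event probability at reference
#'   covariates (before day-shape and covariate effects).
#' @param coef_vulnerability,coef_electrolyte,coef_inflammation,coef_age
#'   log-odds weights of the hazard components.
#' @param target_7day_incidence untreated 7-day cumulative incidence the
#'   default baseline is calibrated to.
#' @param missing_fraction MCAR missingness proportion injected into
#'   continuous lab/ECG fields (< 0.05 by design).
#' @param benefit_profile data.frame with columns \code{lead_h},
#'   \code{multiplier}: piecewise-linear hazard multiplier vs intervention
#'   lead time (h before surgery); 1 outside its support.
#' @param day_shape length-7 positive multiplier of the baseline odds per
#'   postoperative day.
#' @param seed integer recorded with the config and used as the default
#'   generation seed.
#' @return A \code{gt_config} list.
#' @export
gt_config <- function(baseline_daily_hazard = 0.0300487,
                      coef_vulnerability = 0.8,
                      coef_electrolyte = 0.35,
                      coef_inflammation = 0.3,
                      coef_age = 0.25,
                      target_7day_incidence = 0.276,
                      missing_fraction = 0.03,
                      benefit_profile = data.frame(
                        lead_h = c(0, 48, 72, 120),
                        multiplier = c(1.0, 0.6, 0.6, 1.0)),
                      day_shape = c(1.2, 1.4, 1.3, 1.0, 0.8, 0.7, 0.6),
                      seed = 1L) {
  stopifnot(baseline_daily_hazard > 0, baseline_daily_hazard < 1,
            target_7day_incidence > 0, target_7day_incidence < 1,
            missing_fraction >= 0,
            is.data.frame(benefit_profile),
            all(c("lead_h", "multiplier") %in% names(benefit_profile)),
            length(day_shape) == 7, all(day_shape > 0))
  if (missing_fraction >= 0.05)
    warning("missing_fraction >= 0.05 exceeds the <5% design regime of the cohort")
  structure(list(baseline_daily_hazard = baseline_daily_hazard,
                 coef_vulnerability = coef_vulnerability,
                 coef_electrolyte = coef_electrolyte,
                 coef_inflammation = coef_inflammation,
                 coef_age = coef_age,
                 target_7day_incidence = target_7day_incidence,
                 missing_fraction = missing_fraction,
                 benefit_profile = benefit_profile,
                 day_shape = day_shape,
                 seed = as.integer(seed)),
            class = "gt_config")
}

#' Read / write a ground-truth config as YAML
#' @param path file path.
#' @param config a \code{gt_config}.
#' @return \code{read_gt_config} returns a \code{gt_config}.
#' @export
read_gt_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$benefit_profile <- as.data.frame(y$benefit_profile)
  y$day_shape <- as.numeric(y$day_shape)
  do.call(gt_config, y)
}

#' @rdname read_gt_config
#' @export
write_gt_config <- function(config, path) {
  y <- unclass(config)
  y$benefit_profile <- as.list(config$benefit_profile)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Intervention-benefit hazard multiplier at a given lead time
#'
#' Linear interpolation of the configured benefit profile; 1 outside its
#' support (no benefit when intervening at 0 h or beyond the last knot).
#'
#' @param config a \code{gt_config}.
#' @param lead_time_h intervention lead time, hours before surgery.
#' @return Hazard multiplier in (0, 1].
#' @export
benefit_multiplier <- function(config, lead_time_h) {
  bp <- config$benefit_profile
  stats::approx(bp$lead_h, bp$multiplier, xout = lead_time_h,
                rule = 2, yleft = 1, yright = 1)$y
}

# standardized hazard components; cohort is a data.frame of PatientRecords
.hazard_components <- function(cohort) {
  z_qtc <- (cohort$qt_ms / sqrt(cohort$rr_s) - 345) / 25
  z_hrv <- (log(cohort$hrv_sdnn_ms) - log(40)) / 0.4
  z_pr <- (cohort$pr_ms - 165) / 25
  list(
    vulnerability = 0.6 * z_qtc - 0.25 * z_hrv + 0.15 * z_pr,
    electrolyte = pmax(0, 4.0 - cohort$potassium_meq_l) / 0.4 +
      pmax(0, 2.0 - cohort$magnesium_meq_l) / 0.25,
    inflammation = (log(cohort$crp_mg_l) - log(5)) / 0.8,
    age = (cohort$age - 66) / 10
  )
}

#' Ground-truth daily POAF hazard
#'
#' The generative hazard of the synthetic mechanism: logistic-linear in the
#' standardized vulnerability composite (QTc prolongation, low HRV, PR
#' prolongation), electrolyte deficits below 4.0 mEq/L potassium / 2.0 mEq/L
#' magnesium, log-CRP inflammation, and age; modulated by the postoperative
#' day shape, then multiplied by \code{intervention_multiplier} and clamped
#' below 1.
#'
#' @param record one or more patient records (data.frame rows).
#' @param day postoperative day, 1-7.
#' @param config a \code{gt_config}.
#' @param intervention_multiplier non-negative hazard ratio (scalar or one
#'   per record).
#' @return Vector of per-record daily event probabilities in [0, 1).
#' @export
true_daily_hazard <- function(record, day, config = gt_config(),
                              intervention_multiplier = 1) {
  if (length(day) != 1 || day < 1 || day > 7 || day != round(day))
    stop("day must be a single integer in 1..7")
  if (any(intervention_multiplier < 0))
    stop("intervention_multiplier must be >= 0")
  comp <- .hazard_components(record)
  lp <- stats::qlogis(config$baseline_daily_hazard) +
    log(config$day_shape[day]) +
    config$coef_vulnerability * comp$vulnerability +
    config$coef_electrolyte * comp$electrolyte +
    config$coef_inflammation * comp$inflammation +
    config$coef_age * comp$age
  pmin(stats::plogis(lp) * intervention_multiplier, 1 - 1e-9)
}

# latent correlation of the continuous features (documented structure):
# order: age, qtc, pr, qrs, rr, hrv, k, mg, crp, bnp
.latent_correlation <- function() {
  nm <- c("age", "qtc", "pr", "qrs", "rr", "hrv", "k", "mg", "crp", "bnp")
  R <- diag(10)
  dimnames(R) <- list(nm, nm)
  set2 <- function(a, b, r) { R[a, b] <<- r; R[b, a] <<- r }
  set2("age", "qtc", 0.20); set2("age", "hrv", -0.30); set2("age", "bnp", 0.30)
  set2("age", "pr", 0.15); set2("k", "mg", 0.30); set2("crp", "bnp", 0.40)
  set2("qtc", "hrv", -0.20); set2("rr", "hrv", 0.20)
  R
}

#' Generate a synthetic perioperative cohort
#'
#' Continuous features are drawn from a latent Gaussian with the documented
#' correlation structure and mapped to clipped normal / lognormal marginals
#' (age mean 66 sd 10 clipped at 18; PR 165(25), QRS 95(15) ms; RR 0.90(0.12)
#' s; QTc 345(25) ms with QT = QTc*sqrt(RR) -- centered so that QTc minus
#' the 60 ms activation-duration offset spans the cell model's achievable
#' APD90 range; HRV SDNN lognormal around 40 ms;
#' potassium 4.1(0.4), magnesium 2.0(0.25) mEq/L; CRP and BNP lognormal).
#' Comorbidity flags are Bernoulli with age-dependent prevalence; surgery
#' type is multinomial (CABG 50\%, valve 25\%, combined 15\%, aortic 10\%).
#' Untreated 7-day POAF outcomes are drawn day by day from
#' \code{\link{true_daily_hazard}}; non-events are administratively censored
#' at day 7.
#'
#' @param config a \code{gt_config}.
#' @param n number of patients (>= 0).
#' @param seed integer seed (defaults to \code{config$seed}).
#' @return A data.frame of patient records (one row per patient) with the
#'   schema in \code{poaftwin:::.cohort_columns}.
#' @export
generate_cohort <- function(config = gt_config(), n, seed = config$seed) {
  if (length(n) != 1 || is.na(n) || n < 0 || n != round(n))
    stop("n must be a single non-negative integer")
  n <- as.integer(n)
  empty <- function() {
    df <- data.frame(id = character(0), age = numeric(0), sex = character(0),
                     stringsAsFactors = FALSE)
    for (cl in .cohort_columns[4:14]) df[[cl]] <- logical(0)
    df$surgery_type <- character(0)
    for (cl in .continuous_lab_ecg) df[[cl]] <- numeric(0)
    df$poaf_event <- logical(0); df$poaf_day <- integer(0); df$censored <- logical(0)
    df[.cohort_columns]
  }
  if (n == 0) return(empty())
  .with_seed(seed, {
    R <- .latent_correlation()
    L <- chol(R)
    Z <- matrix(stats::rnorm(n * 10), n, 10) %*% L
    colnames(Z) <- colnames(R)
    clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

    age <- clip(66 + 10 * Z[, "age"], 18, 95)
    qtc <- clip(345 + 25 * Z[, "qtc"], 300, 420)
    pr <- clip(165 + 25 * Z[, "pr"], 80, 320)
    qrs <- clip(95 + 15 * Z[, "qrs"], 50, 200)
    rr <- clip(0.90 + 0.12 * Z[, "rr"], 0.55, 1.40)
    qt <- pmin(qtc * sqrt(rr), 0.95 * rr * 1000)
    hrv <- clip(exp(log(40) + 0.4 * Z[, "hrv"]), 5, 200)
    k <- clip(4.1 + 0.4 * Z[, "k"], 2.8, 6.0)
    mg <- clip(2.0 + 0.25 * Z[, "mg"], 1.2, 3.2)
    crp <- clip(exp(log(5) + 0.8 * Z[, "crp"]), 0.1, 200)
    bnp <- clip(exp(log(150) + 0.9 * Z[, "bnp"]), 5, 5000)

    sex <- ifelse(stats::runif(n) < 0.7, "male", "female")
    flag <- function(base, slope) {
      stats::runif(n) < stats::plogis(stats::qlogis(base) + slope * (age - 66))
    }
    cohort <- data.frame(
      id = sprintf("P%06d", seq_len(n)), age = age, sex = sex,
      hypertension = flag(0.60, 0.04), diabetes = flag(0.30, 0.02),
      chf = flag(0.18, 0.03), vascular_disease = flag(0.25, 0.03),
      prior_stroke_tia = flag(0.08, 0.03), renal_disease = flag(0.12, 0.03),
      liver_disease = flag(0.04, 0.00), bleeding_history = flag(0.06, 0.01),
      labile_inr = flag(0.05, 0.00), alcohol_use = flag(0.12, -0.01),
      antiplatelet_use = flag(0.45, 0.01),
      surgery_type = sample(c("CABG", "valve", "combined", "aortic"), n,
                            replace = TRUE, prob = c(0.50, 0.25, 0.15, 0.10)),
      pr_ms = pr, qrs_ms = qrs, qt_ms = qt, rr_s = rr, hrv_sdnn_ms = hrv,
      potassium_meq_l = k, magnesium_meq_l = mg, crp_mg_l = crp,
      bnp_pg_ml = bnp, stringsAsFactors = FALSE
    )
    out <- simulate_outcomes(cohort, config, intervention_multiplier = 1)
    cohort$poaf_event <- out$poaf_event
    cohort$poaf_day <- out$poaf_day
    cohort$censored <- out$censored
    cohort[.cohort_columns]
  })
}

#' Draw 7-day POAF outcomes from the ground-truth hazard
#'
#' Daily Bernoulli draws from \code{\link{true_daily_hazard}} until event or
#' day 7; uses the current RNG stream (seed management is the caller's job).
#'
#' @param cohort patient records (outcome columns ignored).
#' @param config a \code{gt_config}.
#' @param intervention_multiplier scalar or per-patient hazard multiplier.
#' @param horizon_days event horizon (default 7).
#' @return data.frame with \code{poaf_event}, \code{poaf_day} (NA when no
#'   event), \code{censored}.
#' @export
simulate_outcomes <- function(cohort, config = gt_config(),
                              intervention_multiplier = 1, horizon_days = 7) {
  n <- nrow(cohort)
  event <- logical(n)
  day <- rep(NA_integer_, n)
  at_risk <- rep(TRUE, n)
  mult <- rep(intervention_multiplier, length.out = n)
  for (d in seq_len(horizon_days)) {
    h <- true_daily_hazard(cohort, d, config, mult)
    hit <- at_risk & (stats::runif(n) < h)
    day[hit] <- d
    event[hit] <- TRUE
    at_risk[hit] <- FALSE
  }
  data.frame(poaf_event = event, poaf_day = day, censored = !event)
}

#' Calibrate the baseline daily hazard to a target 7-day incidence
#'
#' Root-finds the baseline daily hazard at which the mean untreated 7-day
#' cumulative incidence over a Monte Carlo cohort equals
#' \code{config$target_7day_incidence}. The expectation is computed
#' analytically per patient (product of daily survival probabilities), so
#' the only Monte Carlo error is in the covariate draw.
#'
#' @param config a \code{gt_config}.
#' @param n_mc Monte Carlo cohort size.
#' @param seed covariate-draw seed.
#' @return A \code{gt_config} with calibrated \code{baseline_daily_hazard}.
#' @export
calibrate_incidence <- function(config = gt_config(), n_mc = 20000,
                                seed = config$seed) {
  cov_cohort <- generate_cohort(config, n_mc, seed)
  f <- function(h0) {
    cfg <- config
    cfg$baseline_daily_hazard <- h0
    surv <- rep(1, nrow(cov_cohort))
    for (d in 1:7) surv <- surv * (1 - true_daily_hazard(cov_cohort, d, cfg))
    mean(1 - surv) - config$target_7day_incidence
  }
  config$baseline_daily_hazard <- stats::uniroot(f, c(1e-4, 0.5), tol = 1e-7)$root
  config
}

#' Inject MCAR missingness and impute by chained equations
#'
#' Masks \code{config$missing_fraction} of the continuous lab/ECG cells
#' completely at random, then restores them by iterative chained linear
#' regression: each incomplete variable is regressed on all other continuous
#' variables plus age (current completions), cycled until the maximum
#' absolute change of any imputed value is below \code{tol} or
#' \code{max_iter} sweeps. A completeness report is attached as attribute
#' \code{"imputation_report"}.
#'
#' @param cohort a cohort data.frame.
#' @param config a \code{gt_config}.
#' @param max_iter maximum chained sweeps.
#' @param tol convergence tolerance on the largest absolute change.
#' @param seed seed of the missingness mask.
#' @param m number of completed datasets; with \code{m > 1} each completion
#'   adds a residual draw to the regression prediction and a list of
#'   completed cohorts is returned.
#' @return The completed cohort (or a list of \code{m} of them).
#' @export
inject_and_impute <- function(cohort, config = gt_config(), max_iter = 10,
                              tol = 1e-6, seed = config$seed + 1L, m = 1) {
  if (nrow(cohort) == 0) return(cohort)
  masked <- .with_seed(seed, {
    x <- cohort
    if (config$missing_fraction > 0) {
      for (cl in .continuous_lab_ecg) {
        idx <- which(stats::runif(nrow(x)) < config$missing_fraction)
        x[[cl]][idx] <- NA_real_
      }
    }
    x
  })
  if (config$missing_fraction >= 0.05)
    warning("missing fraction >= 0.05: outside the <5% regime the cohort is designed for")
  if (m == 1) return(impute_chained(masked, max_iter, tol))
  lapply(seq_len(m), function(i)
    .with_seed(seed + i, impute_chained(masked, max_iter, tol, noise = TRUE)))
}

#' Chained-equation imputation of continuous lab/ECG fields
#'
#' @param cohort cohort with possible NA cells in continuous lab/ECG fields.
#' @param max_iter,tol iteration controls (see \code{\link{inject_and_impute}}).
#' @param noise add a Gaussian residual draw to each prediction (used for
#'   multiple completions).
#' @return Completed cohort with attribute \code{"imputation_report"}:
#'   per-column missing counts, sweeps used, final max change, convergence
#'   flag, and the per-sweep max-change sequence.
#' @export
impute_chained <- function(cohort, max_iter = 10, tol = 1e-6, noise = FALSE) {
  vars <- .continuous_lab_ecg
  n_missing <- vapply(cohort[vars], function(x) sum(is.na(x)), integer(1))
  fully <- names(n_missing)[n_missing == nrow(cohort)]
  if (length(fully))
    stop("unimputable: column(s) fully missing: ", paste(fully, collapse = ", "))
  if (sum(n_missing) == 0) {
    attr(cohort, "imputation_report") <- list(n_missing = n_missing,
                                              iterations = 0L, max_change = 0,
                                              converged = TRUE,
                                              change_path = numeric(0))
    return(cohort)
  }
  miss <- lapply(cohort[vars], function(x) which(is.na(x)))
  x <- cohort
  for (v in vars) # mean initialization
    x[[v]][miss[[v]]] <- mean(cohort[[v]], na.rm = TRUE)
  preds_of <- function(v) c("age", setdiff(vars, v))
  change_path <- numeric(0)
  it <- 0L
  repeat {
    it <- it + 1L
    max_change <- 0
    for (v in vars) {
      idx <- miss[[v]]
      if (!length(idx)) next
      obs <- setdiff(seq_len(nrow(x)), idx)
      X <- cbind(1, as.matrix(x[preds_of(v)]))
      fit <- stats::lm.fit(X[obs, , drop = FALSE], x[[v]][obs])
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      pred <- drop(X[idx, , drop = FALSE] %*% beta)
      if (noise) {
        sigma <- sqrt(sum(fit$residuals^2) / max(1, fit$df.residual))
        pred <- pred + stats::rnorm(length(idx), 0, sigma)
      }
      max_change <- max(max_change, max(abs(pred - x[[v]][idx])))
      x[[v]][idx] <- pred
    }
    change_path <- c(change_path, max_change)
    if (max_change < tol || it >= max_iter) break
  }
  attr(x, "imputation_report") <- list(n_missing = n_missing, iterations = it,
                                       max_change = max_change,
                                       converged = max_change < tol,
                                       change_path = change_path)
  x
}

#' Split a cohort into training / validation / test sets
#'
#' Sizes are \code{floor(n * f)} per set with the remainder assigned to
#' training; assignment is a seeded permutation, so the three parts are an
#' exhaustive, disjoint partition.
#'
#' @param cohort a cohort data.frame.
#' @param fractions numeric triple summing to 1 (default 0.70/0.15/0.15).
#' @param seed permutation seed.
#' @return Named list \code{train}, \code{validation}, \code{test}.
#' @export
split_cohort <- function(cohort, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three numbers summing to 1")
  n <- nrow(cohort)
  n_val <- floor(n * fractions[2])
  n_test <- floor(n * fractions[3])
  n_train <- n - n_val - n_test
  perm <- .with_seed(seed, sample.int(n))
  list(train = cohort[sort(perm[seq_len(n_train)]), , drop = FALSE],
       validation = cohort[sort(perm[n_train + seq_len(n_val)]), , drop = FALSE],
       test = cohort[sort(perm[n_train + n_val + seq_len(n_test)]), , drop = FALSE])
}
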