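# The in silico randomized controlled trial: seeded 1:1 allocation, a
# twin-guided prophylaxis policy (electrolyte repletion to the 4.0/2.0
# mEq/L targets plus a hazard multiplier scaled by the preoperative
# benefit profile), daily Bernoulli event simulation over the 7-day
# postoperative horizon, secondary outcomes (LOS, ICU days, stroke), and
# the trial statistics (two-proportion z, Welch t, Kaplan-Meier, log-rank).

#' Intervention policy of the twin-guided arm
#'
#' @param risk_threshold twin probability above which prophylaxis is
#'   applied; \code{NULL} means "the cohort's 60th percentile", resolved at
#'   trial time.
#' @param hazard_multiplier ratio applied to the daily POAF hazard of
#'   treated patients (0 < m <= 1), before the benefit-profile scaling.
#' @param k_target,mg_target electrolyte repletion targets (mEq/L).
#' @param lead_time_h intervention start, hours before surgery; the
#'   ground-truth benefit profile is evaluated here.
#' @return An \code{intervention_policy} list.
#' @export
intervention_policy <- function(risk_threshold = NULL, hazard_multiplier = 0.95,
                                k_target = 4.0, mg_target = 2.0,
                                lead_time_h = 60) {
  stopifnot(hazard_multiplier > 0, hazard_multiplier <= 1,
            is.null(risk_threshold) ||
              (risk_threshold >= 0 && risk_threshold <= 1))
  structure(list(risk_threshold = risk_threshold,
                 hazard_multiplier = hazard_multiplier,
                 k_target = k_target, mg_target = mg_target,
                 lead_time_h = lead_time_h),
            class = "intervention_policy")
}

#' Trial configuration
#'
#' Outcome-model constants: length of stay is lognormal around
#' \code{los_base_days} (+\code{los_poaf_days} after POAF), ICU days
#' analogous, stroke probability \code{stroke_p_no_poaf} /
#' \code{stroke_p_poaf}.
#'
#' @param n_total total trial size (even; default 10,000, allocated 1:1).
#' @param horizon_days postoperative event horizon (default 7).
#' @param seed trial seed.
#' @param los_base_days,los_poaf_days,los_sdlog LOS model constants.
#' @param icu_base_days,icu_poaf_days,icu_sdlog ICU model constants.
#' @param stroke_p_no_poaf,stroke_p_poaf stroke probabilities.
#' @return A \code{trial_config} list.
#' @export
trial_config <- function(n_total = 10000, horizon_days = 7, seed = 11L,
                         los_base_days = 6.5, los_poaf_days = 5.0,
                         los_sdlog = 0.18,
                         icu_base_days = 1.8, icu_poaf_days = 2.5,
                         icu_sdlog = 0.25,
                         stroke_p_no_poaf = 0.008, stroke_p_poaf = 0.04) {
  stopifnot(n_total > 0, horizon_days >= 1)
  structure(list(n_total = as.integer(n_total),
                 horizon_days = as.integer(horizon_days),
                 seed = as.integer(seed),
                 los_base_days = los_base_days, los_poaf_days = los_poaf_days,
                 los_sdlog = los_sdlog,
                 icu_base_days = icu_base_days, icu_poaf_days = icu_poaf_days,
                 icu_sdlog = icu_sdlog,
                 stroke_p_no_poaf = stroke_p_no_poaf,
                 stroke_p_poaf = stroke_p_poaf),
            class = "trial_config")
}

#' Randomize a cohort 1:1 into intervention and control arms
#'
#' Exact 1:1 split by a seeded permutation.
#'
#' @param cohort cohort data.frame with even row count.
#' @param seed allocation seed.
#' @return List \code{intervention}, \code{control} (disjoint, exhaustive).
#' @export
randomize_arms <- function(cohort, seed = 1L) {
  n <- nrow(cohort)
  if (n %% 2 != 0)
    stop("1:1 allocation needs an even cohort size; drop one record explicitly")
  perm <- .with_seed(seed, sample.int(n))
  list(intervention = cohort[sort(perm[seq_len(n / 2)]), , drop = FALSE],
       control = cohort[sort(perm[n / 2 + seq_len(n / 2)]), , drop = FALSE])
}

#' Apply the twin-guided policy to (intervention-arm) patients
#'
#' Patients with \code{twin_prob > risk_threshold} have potassium and
#' magnesium raised to \code{max(current, target)} and receive the policy's
#' hazard multiplier additionally scaled by the ground-truth benefit
#' profile at the policy's lead time; everyone else is untreated
#' (multiplier 1, electrolytes unchanged).
#'
#' @param cohort patient records.
#' @param twin_prob per-patient twin risk probability.
#' @param policy an \code{intervention_policy} (its \code{risk_threshold}
#'   must be resolved, i.e. non-NULL).
#' @param gt a \code{gt_config} supplying the benefit profile.
#' @return List: \code{cohort} (electrolytes modified for treated),
#'   \code{multiplier} (per patient), \code{treated} (logical).
#' @export
apply_policy <- function(cohort, twin_prob, policy, gt = gt_config()) {
  if (is.null(policy$risk_threshold))
    stop("risk_threshold is unresolved; set it or use simulate_trial()")
  treated <- twin_prob > policy$risk_threshold
  mult <- rep(1, nrow(cohort))
  mult[treated] <- policy$hazard_multiplier *
    benefit_multiplier(gt, policy$lead_time_h)
  cohort$potassium_meq_l[treated] <-
    pmax(cohort$potassium_meq_l[treated], policy$k_target)
  cohort$magnesium_meq_l[treated] <-
    pmax(cohort$magnesium_meq_l[treated], policy$mg_target)
  list(cohort = cohort, multiplier = mult, treated = treated)
}

# secondary outcomes for one arm, given POAF indicators (uses current RNG)
.secondary_outcomes <- function(poaf, cfg) {
  n <- length(poaf)
  los <- stats::rlnorm(n, log(cfg$los_base_days + cfg$los_poaf_days * poaf),
                       cfg$los_sdlog)
  icu <- stats::rlnorm(n, log(cfg$icu_base_days + cfg$icu_poaf_days * poaf),
                       cfg$icu_sdlog)
  stroke <- stats::runif(n) <
    ifelse(poaf, cfg$stroke_p_poaf, cfg$stroke_p_no_poaf)
  data.frame(los_days = los, icu_days = icu, stroke = stroke)
}

#' Run the virtual randomized controlled trial
#'
#' Randomizes 1:1, applies the twin-guided policy in the intervention arm
#' (threshold \code{NULL} resolves to the cohort's 60th percentile of
#' \code{twin_prob}), then simulates daily POAF events from the
#' ground-truth hazard times the per-patient policy multiplier over the
#' horizon, plus LOS / ICU / stroke secondary outcomes. Fully reproducible
#' under \code{config$seed}.
#'
#' @param cohort patient records (even row count).
#' @param twin_prob per-patient twin risk probability aligned with
#'   \code{cohort}.
#' @param gt a \code{gt_config} (the event mechanism).
#' @param config a \code{trial_config}.
#' @param policy an \code{intervention_policy}.
#' @return A \code{trial_report}: per-arm summaries, relative risk
#'   reduction, test p-values, Kaplan-Meier curves, log-rank test.
#' @export
simulate_trial <- function(cohort, twin_prob, gt = gt_config(),
                           config = trial_config(),
                           policy = intervention_policy()) {
  stopifnot(nrow(cohort) == length(twin_prob))
  if (is.null(policy$risk_threshold))
    policy$risk_threshold <- unname(stats::quantile(twin_prob, 0.60))
  idx <- seq_len(nrow(cohort))
  arms <- randomize_arms(cbind(cohort, .row = idx), seed = config$seed)
  run_arm <- function(arm_df, treated_arm, seed_offset) {
    tp <- twin_prob[arm_df$.row]
    if (treated_arm) {
      ap <- apply_policy(arm_df, tp, policy, gt)
      arm_df <- ap$cohort; mult <- ap$multiplier; treated <- ap$treated
    } else {
      mult <- rep(1, nrow(arm_df)); treated <- rep(FALSE, nrow(arm_df))
    }
    .with_seed(config$seed + seed_offset, {
      out <- simulate_outcomes(arm_df, gt, mult, config$horizon_days)
      sec <- .secondary_outcomes(out$poaf_event, config)
      # drop any pre-existing outcome columns: the trial re-simulates them
      keep <- setdiff(names(arm_df), c(".row", "poaf_event", "poaf_day", "censored"))
      cbind(arm_df[keep], out, sec, treated = treated)
    })
  }
  int_arm <- run_arm(arms$intervention, TRUE, 1000L)
  ctl_arm <- run_arm(arms$control, FALSE, 2000L)

  summarize <- function(a) list(
    n = nrow(a), poaf_events = sum(a$poaf_event),
    poaf_incidence = mean(a$poaf_event),
    mean_los_days = mean(a$los_days), mean_icu_days = mean(a$icu_days),
    stroke_events = sum(a$stroke), stroke_incidence = mean(a$stroke),
    n_treated = sum(a$treated)
  )
  si <- summarize(int_arm); sc <- summarize(ctl_arm)
  tp_poaf <- two_proportion_test(si$poaf_events, si$n, sc$poaf_events, sc$n)
  tp_stroke <- two_proportion_test(si$stroke_events, si$n, sc$stroke_events, sc$n)
  t_los <- stats::t.test(int_arm$los_days, ctl_arm$los_days)
  t_icu <- stats::t.test(int_arm$icu_days, ctl_arm$icu_days)
  ev_day <- function(a) ifelse(a$poaf_event, a$poaf_day, config$horizon_days)
  km_i <- km_curve(ev_day(int_arm), !int_arm$poaf_event, config$horizon_days)
  km_c <- km_curve(ev_day(ctl_arm), !ctl_arm$poaf_event, config$horizon_days)
  lr <- logrank_test(ev_day(int_arm), int_arm$poaf_event,
                     ev_day(ctl_arm), ctl_arm$poaf_event)
  structure(list(
    intervention = si, control = sc,
    rrr_percent = relative_risk_reduction(sc$poaf_incidence, si$poaf_incidence),
    p_poaf = tp_poaf$p, p_stroke = tp_stroke$p,
    p_los = t_los$p.value, p_icu = t_icu$p.value,
    los_reduction_days = sc$mean_los_days - si$mean_los_days,
    icu_reduction_days = sc$mean_icu_days - si$mean_icu_days,
    km_intervention = km_i, km_control = km_c, logrank_p = lr$p,
    logrank_chi2 = lr$chi2,
    policy = policy, seed = config$seed,
    arms = list(intervention = int_arm, control = ctl_arm)
  ), class = "trial_report")
}

#' Relative risk reduction in percent
#'
#' 100 (p_control - p_intervention) / p_control.
#'
#' @param p_control control-arm incidence (> 0).
#' @param p_intervention intervention-arm incidence.
#' @return RRR in percent.
#' @export
relative_risk_reduction <- function(p_control, p_intervention) {
  if (any(p_control <= 0)) stop("undefined: p_control must be > 0")
  100 * (p_control - p_intervention) / p_control
}

#' Two-proportion z-test (pooled variance)
#'
#' z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2)) with the pooled proportion p;
#' two-sided p-value from the normal tail.
#'
#' @param x1,n1 events and size of group 1.
#' @param x2,n2 events and size of group 2.
#' @return List with \code{z}, \code{p}, \code{p1}, \code{p2}.
#' @export
two_proportion_test <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) stop("need 0 <= x <= n")
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' Kaplan-Meier product-limit curve
#'
#' With no censoring before the horizon this reduces to the empirical
#' survival function.
#'
#' @param event_days day of event or of censoring, in 1..horizon.
#' @param censored_flags TRUE where \code{event_days} is a censoring time.
#' @param horizon last day of follow-up.
#' @return data.frame with \code{time}, \code{n_risk}, \code{n_event},
#'   \code{n_censored}, \code{survival} (one row per day 1..horizon).
#' @export
km_curve <- function(event_days, censored_flags, horizon = 7) {
  stopifnot(length(event_days) == length(censored_flags))
  if (length(event_days) && (any(event_days < 1) || any(event_days > horizon)))
    stop("event days must lie in 1..horizon")
  s <- 1
  out <- data.frame(time = seq_len(horizon), n_risk = NA_integer_,
                    n_event = NA_integer_, n_censored = NA_integer_,
                    survival = NA_real_)
  for (d in seq_len(horizon)) {
    at_risk <- sum(event_days >= d)
    d_ev <- sum(event_days == d & !censored_flags)
    d_cn <- sum(event_days == d & censored_flags)
    if (at_risk > 0) s <- s * (1 - d_ev / at_risk)
    out$n_risk[d] <- at_risk
    out$n_event[d] <- d_ev
    out$n_censored[d] <- d_cn
    out$survival[d] <- s
  }
  out
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected accumulation of 2x2 tables over the
#' shared event times, chi-square with 1 df.
#'
#' @param days1,event1 follow-up day and event indicator, group 1
#'   (\code{event = FALSE} means censored at that day).
#' @param days2,event2 likewise for group 2.
#' @return List with \code{chi2}, \code{p}, \code{observed1},
#'   \code{expected1}.
#' @export
logrank_test <- function(days1, event1, days2, event2) {
  if (!length(days1) || !length(days2)) stop("both arms must be non-empty")
  if (!any(event1) && !any(event2)) stop("undefined test: no events in either arm")
  times <- sort(unique(c(days1[event1], days2[event2])))
  o1 <- e1 <- v <- 0
  for (t in times) {
    n1 <- sum(days1 >= t); n2 <- sum(days2 >= t)
    d1 <- sum(days1 == t & event1); d2 <- sum(days2 == t & event2)
    n <- n1 + n2; d <- d1 + d2
    if (n < 2 || d == 0) next
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (v > 0) (o1 - e1)^2 / v else 0
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
       observed1 = o1, expected1 = e1, variance = v)
}

#' Sweep the intervention lead time
#'
#' Re-runs the trial at each lead time (same seed, same cohort and
#' allocation) and reports the intervention-arm incidence per lead time and
#' the argmin window.
#'
#' @param cohort,twin_prob,gt,config,policy as in \code{\link{simulate_trial}}.
#' @param lead_times_h non-empty grid of lead times (h).
#' @return List: \code{table} (lead_h, incidence, rrr_percent),
#'   \code{best_lead_h}.
#' @export
window_sweep <- function(cohort, twin_prob, gt = gt_config(),
                         config = trial_config(),
                         policy = intervention_policy(),
                         lead_times_h = c(12, 24, 48, 60, 72, 96, 120)) {
  if (!length(lead_times_h)) stop("lead_times_h must be non-empty")
  rows <- lapply(lead_times_h, function(lt) {
    pol <- policy
    pol$lead_time_h <- lt
    rep <- simulate_trial(cohort, twin_prob, gt, config, pol)
    data.frame(lead_h = lt, incidence = rep$intervention$poaf_incidence,
               rrr_percent = rep$rrr_percent)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, best_lead_h = tab$lead_h[which.min(tab$incidence)])
}

#' Human-readable trial summary
#' @param x a \code{trial_report}.
#' @param ... ignored.
#' @return \code{x}, invisibly.
#' @export
print.trial_report <- function(x, ...) {
  fmt <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
  cat("Virtual RCT (", x$intervention$n, " vs ", x$control$n, ")\n", sep = "")
  cat(sprintf("  POAF incidence: %.1f%% vs %.1f%% (RRR %.1f%%, p %s)\n",
              100 * x$intervention$poaf_incidence,
              100 * x$control$poaf_incidence, x$rrr_percent, fmt(x$p_poaf)))
  cat(sprintf("  LOS: %.1f vs %.1f d (p %s); ICU: %.1f vs %.1f d (p %s)\n",
              x$intervention$mean_los_days, x$control$mean_los_days,
              fmt(x$p_los), x$intervention$mean_icu_days,
              x$control$mean_icu_days, fmt(x$p_icu)))
  cat(sprintf("  Stroke: %.1f%% vs %.1f%% (p %s); log-rank p %s\n",
              100 * x$intervention$stroke_incidence,
              100 * x$control$stroke_incidence, fmt(x$p_stroke),
              fmt(x$logrank_p)))
  invisible(x)
}

#' Export a trial report (JSON) and its KM curves (CSV)
#' @param report a \code{trial_report}.
#' @param json_path,km_csv_path output files (NULL = skip).
#' @return \code{report}, invisibly.
#' @export
write_trial_report <- function(report, json_path = NULL, km_csv_path = NULL) {
  if (!is.null(json_path)) {
    out <- report[c("intervention", "control", "rrr_percent", "p_poaf",
                    "p_stroke", "p_los", "p_icu", "los_reduction_days",
                    "icu_reduction_days", "logrank_p", "seed")]
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(km_csv_path)) {
    km <- rbind(cbind(arm = "intervention", report$km_intervention),
                cbind(arm = "control", report$km_control))
    utils::write.csv(km, km_csv_path, row.names = FALSE)
  }
  invisible(report)
}
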