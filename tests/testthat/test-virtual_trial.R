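test_that("randomization is an exact, seeded 1:1 partition", {
  co <- small_cohort(400, seed = 12)
  arms <- randomize_arms(co, seed = 3)
  expect_equal(nrow(arms$intervention), 200)
  expect_equal(nrow(arms$control), 200)
  expect_setequal(c(arms$intervention$id, arms$control$id), co$id)
  expect_length(intersect(arms$intervention$id, arms$control$id), 0)
  arms2 <- randomize_arms(co, seed = 3)
  expect_identical(arms$intervention$id, arms2$intervention$id)
  expect_error(randomize_arms(co[1:399, ], seed = 3), "even")
})

test_that("policy treats above threshold, repletes electrolytes, scales hazard", {
  co <- small_cohort(200, seed = 14)
  tp <- seq(0, 1, length.out = 200)
  pol <- intervention_policy(risk_threshold = 0.5, hazard_multiplier = 0.8,
                             lead_time_h = 60)
  ap <- apply_policy(co, tp, pol, gt_config())
  expect_equal(ap$treated, tp > 0.5)
  expect_equal(unique(ap$multiplier[ap$treated]), 0.8 * 0.6) # profile(60h) = 0.6
  expect_equal(unique(ap$multiplier[!ap$treated]), 1)
  expect_true(all(ap$cohort$potassium_meq_l[ap$treated] >= 4.0))
  expect_true(all(ap$cohort$magnesium_meq_l[ap$treated] >= 2.0))
  # untreated electrolytes untouched
  expect_equal(ap$cohort$potassium_meq_l[!ap$treated],
               co$potassium_meq_l[!ap$treated])
  # a 3.6 mEq/L potassium is raised exactly to the 4.0 target
  co2 <- co[1, ]; co2$potassium_meq_l <- 3.6
  ap2 <- apply_policy(co2, 0.9, pol, gt_config())
  expect_equal(ap2$cohort$potassium_meq_l, 4.0)
  # below threshold: nothing happens
  ap3 <- apply_policy(co2, 0.1, pol, gt_config())
  expect_equal(ap3$multiplier, 1)
  expect_equal(ap3$cohort$potassium_meq_l, 3.6)
})

test_that("null intervention (multiplier 1, lead 0 h, trivial targets) is inert", {
  co <- small_cohort(600, seed = 15)
  tp <- runif(600)
  pol <- intervention_policy(risk_threshold = 0.5, hazard_multiplier = 1,
                             k_target = 0, mg_target = 0, lead_time_h = 0)
  rep <- simulate_trial(co, tp, gt_config(), trial_config(seed = 2), pol)
  # both arms face the identical mechanism: RRR within 3 MC SE of zero
  p <- gt_config()$target_7day_incidence
  se_rrr <- 100 * sqrt(2 * p * (1 - p) / 300) / p
  expect_lt(abs(rep$rrr_percent), 3 * se_rrr)
})

test_that("absorbing intervention (multiplier -> 0, threshold 0) eliminates events", {
  co <- small_cohort(200, seed = 16)
  tp <- runif(200, 0.01, 0.99)
  pol <- intervention_policy(risk_threshold = 0, hazard_multiplier = 1e-12,
                             lead_time_h = 60)
  rep <- simulate_trial(co, tp, gt_config(), trial_config(seed = 5), pol)
  expect_equal(rep$intervention$poaf_events, 0)
  expect_gt(rep$control$poaf_events, 0)
})

test_that("relative risk reduction arithmetic", {
  expect_equal(relative_risk_reduction(0.2, 0.2), 0)
  expect_equal(relative_risk_reduction(0.2, 0.1), 50)
  expect_error(relative_risk_reduction(0, 0.1), "undefined")
})

test_that("two-proportion test matches hand-computed pooled z and is symmetric", {
  t1 <- two_proportion_test(910, 5000, 1380, 5000)
  # hand: pooled p = 0.229, se = sqrt(0.229*0.771*2/5000), z = -0.094/se
  se <- sqrt(0.229 * 0.771 * (1 / 5000 + 1 / 5000))
  expect_equal(t1$z, (0.182 - 0.276) / se, tolerance = 1e-10)
  expect_lt(t1$p, 0.001)
  t2 <- two_proportion_test(1380, 5000, 910, 5000)
  expect_equal(t2$z, -t1$z)
  expect_equal(t2$p, t1$p)
  # equal proportions at large n: p near 1
  expect_gt(two_proportion_test(500, 5000, 500, 5000)$p, 0.9)
  expect_error(two_proportion_test(1, 0, 1, 5), "positive")
  expect_error(two_proportion_test(6, 5, 1, 5), "0 <= x <= n")
})

test_that("Kaplan-Meier equals empirical survival without censoring", {
  expect_equal(km_curve(rep(7, 5), rep(TRUE, 5), 7)$survival, rep(1, 7))
  km <- km_curve(c(1, 2, 7, 7), c(FALSE, FALSE, TRUE, TRUE), 7)
  expect_equal(km$survival[2], 0.5) # events {1,2} of n=4
  expect_equal(km$survival[1], 0.75)
  expect_error(km_curve(c(0, 2), c(FALSE, FALSE), 7), "1..horizon")
})

test_that("Kaplan-Meier matches the hand-worked censored product-limit", {
  # 6 patients: events at 1, 3, 5; censored at 2, 4; admin-censored at 7
  days <- c(1, 2, 3, 4, 5, 7)
  cens <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  km <- km_curve(days, cens, 7)
  expect_equal(km$survival[1], 5 / 6)
  expect_equal(km$survival[3], 5 / 6 * 3 / 4)
  expect_equal(km$survival[5], 5 / 6 * 3 / 4 * 1 / 2)
  expect_equal(km$survival[7], km$survival[5]) # censoring does not drop S

  skip_if_not_installed("survival")
  sf <- survival::survfit(survival::Surv(days, !cens) ~ 1)
  expect_equal(km$survival[c(1, 3, 5)], summary(sf)$surv, tolerance = 1e-12)
})

test_that("log-rank matches brute-force accumulation and survdiff", {
  d1 <- c(1, 2, 2, 4, 6, 7, 7, 3, 5, 7)
  e1 <- c(T, T, F, T, F, T, F, T, T, F)
  d2 <- c(1, 1, 3, 4, 5, 6, 7, 7, 2, 7)
  e2 <- c(T, T, T, F, T, T, F, F, T, F)
  lr <- logrank_test(d1, e1, d2, e2)

  # brute-force 2x2 accumulation over shared event times
  o1 <- e1s <- v <- 0
  for (t in sort(unique(c(d1[e1], d2[e2])))) {
    n1 <- sum(d1 >= t); n2 <- sum(d2 >= t)
    dd1 <- sum(d1 == t & e1); dd2 <- sum(d2 == t & e2)
    n <- n1 + n2; d <- dd1 + dd2
    if (d == 0 || n < 2) next
    o1 <- o1 + dd1
    e1s <- e1s + d * n1 / n
    v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  expect_equal(lr$chi2, (o1 - e1s)^2 / v)

  # symmetric in arm labels
  lr2 <- logrank_test(d2, e2, d1, e1)
  expect_equal(lr2$chi2, lr$chi2)

  # identical arms: statistic 0
  lr0 <- logrank_test(d1, e1, d1, e1)
  expect_equal(lr0$chi2, 0)
  expect_error(logrank_test(c(7, 7), c(F, F), c(7, 7), c(F, F)), "no events")

  skip_if_not_installed("survival")
  sd <- survival::survdiff(
    survival::Surv(c(d1, d2), c(e1, e2)) ~ rep(1:2, each = 10))
  expect_equal(lr$chi2, sd$chisq, tolerance = 1e-10)
})

test_that("trial determinism, bookkeeping, and positive stay durations", {
  co <- small_cohort(400, seed = 17)
  tp <- runif(400)
  r1 <- simulate_trial(co, tp, gt_config(), trial_config(seed = 6))
  r2 <- simulate_trial(co, tp, gt_config(), trial_config(seed = 6))
  expect_identical(r1$rrr_percent, r2$rrr_percent)
  expect_identical(r1$arms$intervention$los_days, r2$arms$intervention$los_days)
  expect_lte(r1$intervention$poaf_events, r1$intervention$n)
  expect_true(all(r1$arms$intervention$los_days > 0))
  expect_true(all(r1$arms$control$icu_days > 0))
})

test_that("null trials give RRR centered on zero and uniform log-rank p", {
  co <- small_cohort(400, seed = 18)
  tp <- runif(400)
  pol <- intervention_policy(risk_threshold = 0.5, hazard_multiplier = 1,
                             k_target = 0, mg_target = 0, lead_time_h = 0)
  res <- vapply(1:200, function(s) {
    r <- simulate_trial(co, tp, gt_config(), trial_config(seed = 1000 + s), pol)
    c(r$rrr_percent, r$logrank_p)
  }, numeric(2))
  expect_lt(abs(mean(res[1, ])), 3 * sd(res[1, ]) / sqrt(200))
  expect_gt(suppressWarnings(ks.test(res[2, ], "punif"))$p.value, 0.01)
})

test_that("flat benefit profile makes the window sweep flat; errors propagate", {
  co <- small_cohort(400, seed = 19)
  tp <- runif(400)
  gt_flat <- gt_config(benefit_profile = data.frame(lead_h = c(0, 120),
                                                    multiplier = c(0.7, 0.7)))
  sw <- window_sweep(co, tp, gt_flat, trial_config(seed = 7),
                     lead_times_h = c(24, 60, 96))
  expect_identical(sw$table$incidence, rep(sw$table$incidence[1], 3))
  expect_error(window_sweep(co, tp, gt_flat, trial_config(seed = 7),
                            lead_times_h = numeric(0)), "non-empty")
  sw2 <- window_sweep(co, tp, gt_flat, trial_config(seed = 7),
                      lead_times_h = c(24, 60, 96))
  expect_identical(sw, sw2)
})

test_that("trial report exports JSON and KM CSV", {
  co <- small_cohort(200, seed = 20)
  r <- simulate_trial(co, runif(200), gt_config(), trial_config(seed = 8))
  js <- withr::local_tempfile(fileext = ".json")
  km <- withr::local_tempfile(fileext = ".csv")
  write_trial_report(r, js, km)
  j <- jsonlite::read_json(js)
  expect_equal(j$control$n, r$control$n)
  expect_equal(nrow(read.csv(km)), 14) # 7 days x 2 arms
  expect_output(print(r), "Virtual RCT")
})
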