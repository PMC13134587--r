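test_that("AUC equals the O(n^2) pair-counting oracle on random instances", {
  set.seed(11)
  for (i in 1:8) {
    n <- sample(10:50, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.4) # both classes guaranteed
    scores <- sample(round(rnorm(n), 1)) # ties likely
    expect_equal(roc_auc(scores, labels), auc_pairs(scores, labels))
  }
  expect_equal(roc_auc(c(1, 2, 3, 4), c(F, F, T, T)), 1.0)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("AUC of uninformative scores is 0.5 within Monte Carlo error", {
  set.seed(5)
  n <- 4000
  scores <- rnorm(n)
  labels <- runif(n) < 0.3
  n1 <- sum(labels); n0 <- n - n1
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0)) # Hanley-McNeil null SE scale
  expect_lt(abs(roc_auc(scores, labels) - 0.5), 3 * se)
})

test_that("bootstrap CI brackets the point AUC and is seed-stable", {
  fx <- small_cohort(300, seed = 31)
  s <- fx$crp_mg_l; y <- fx$poaf_event
  ci <- auc_bootstrap_ci(s, y, n_boot = 300, seed = 4)
  ci2 <- auc_bootstrap_ci(s, y, n_boot = 300, seed = 4)
  expect_identical(ci, ci2)
  a <- roc_auc(s, y)
  expect_lt(ci[1], a); expect_gt(ci[2], a)
})

test_that("Youden threshold matches an exhaustive scan and is rank-invariant", {
  set.seed(21)
  scores <- round(rnorm(30), 1)
  labels <- c(TRUE, FALSE, runif(28) < 0.5)
  th <- youden_threshold(scores, labels)
  # exhaustive scan over a fine grid
  grid <- seq(min(scores) - 1, max(scores) + 1, by = 0.01)
  j <- vapply(grid, function(t)
    mean(scores[labels] >= t) + mean(scores[!labels] < t) - 1, numeric(1))
  j_th <- mean(scores[labels] >= th) + mean(scores[!labels] < th) - 1
  expect_equal(j_th, max(j), tolerance = 1e-9)

  # invariant under a strictly monotone transform (same classification)
  th2 <- youden_threshold(exp(scores), labels)
  expect_equal(scores >= th, exp(scores) >= th2)

  # separable data: J = 1
  expect_equal({
    ths <- youden_threshold(c(1, 2, 10, 11), c(F, F, T, T))
    mean(c(10, 11) >= ths) + mean(c(1, 2) < ths) - 1
  }, 1)
})

test_that("confusion metrics reproduce direct ratios and a manual count", {
  scores <- c(rep(1, 87), rep(0, 13), rep(1, 18), rep(0, 82))
  labels <- c(rep(TRUE, 100), rep(FALSE, 100))
  cm <- confusion_metrics(scores, labels, 0.5)
  expect_equal(cm$sensitivity, 0.87)
  expect_equal(cm$specificity, 0.82)
  expect_equal(unname(cm$counts), c(87, 13, 18, 82))

  # manual count on 12 labelled scores
  s <- c(0.9, 0.8, 0.7, 0.6, 0.55, 0.4, 0.45, 0.3, 0.2, 0.65, 0.1, 0.05)
  y <- c(T, T, F, T, F, T, F, F, F, T, F, F)
  cm2 <- confusion_metrics(s, y, 0.5)
  expect_equal(unname(cm2$counts["tp"]), sum(s >= 0.5 & y))
  expect_equal(unname(cm2$counts["tn"]), sum(s < 0.5 & !y))
  expect_equal(cm2$ppv, sum(s >= 0.5 & y) / sum(s >= 0.5))

  # perfect separation: all four metrics 1
  cm3 <- confusion_metrics(c(0.9, 0.8, 0.1, 0.2), c(T, T, F, F), 0.5)
  expect_equal(c(cm3$sensitivity, cm3$specificity, cm3$ppv, cm3$npv),
               rep(1, 4))

  # Wilson interval sanity against binom (central coverage check at one point)
  w <- poaftwin:::.wilson_ci(8, 10)
  expect_true(w[1] > 0.4 && w[2] < 1)

  # empty predicted-positive set flags ppv undefined
  cm4 <- confusion_metrics(c(0.1, 0.2, 0.3, 0.4), c(T, F, T, F), 0.9)
  expect_true(is.na(cm4$ppv))
  expect_true(cm4$undefined[["ppv"]])
})

test_that("Hosmer-Lemeshow is zero under exact group calibration and matches hand math", {
  # predictions exactly equal to the group event rates -> chi2 = 0
  p <- rep(c(0.2, 0.8), each = 10)
  y <- c(rep(c(TRUE, FALSE), c(2, 8)), rep(c(TRUE, FALSE), c(8, 2)))
  hl <- hosmer_lemeshow(p, y, n_groups = 2)
  expect_equal(hl$chi2, 0, tolerance = 1e-12)

  # hand-summed 2-group toy: chi2 = 0.0625 + 0.0625 = 0.125
  p2 <- rep(c(0.2, 0.8), each = 4)
  y2 <- c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE)
  hl2 <- hosmer_lemeshow(p2, y2, n_groups = 2)
  expect_equal(hl2$chi2, 0.125)
  expect_error(hosmer_lemeshow(p2[1:5], y2[1:5], n_groups = 10), "at least")
})

test_that("Hosmer-Lemeshow p-values are uniform under a fitted null", {
  set.seed(1234)
  ps <- vapply(1:200, function(i) {
    n <- 1000
    x <- rnorm(n)
    y <- runif(n) < plogis(-1 + 0.8 * x)
    fit <- suppressWarnings(glm(y ~ x, family = binomial))
    hosmer_lemeshow(fitted(fit), y)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("calibration slope recovers 1 under truth and 0.5 under doubled logits", {
  set.seed(9)
  n <- 10000
  lp <- rnorm(n, -1, 1)
  p <- plogis(lp)
  y <- runif(n) < p
  cs <- calibration_slope(p, y)
  expect_gt(cs$slope, 0.9); expect_lt(cs$slope, 1.1)
  expect_true(cs$converged)

  over <- plogis(2 * lp)
  cs2 <- calibration_slope(over, y)
  expect_equal(cs2$slope, 0.5, tolerance = 0.05)

  # invariant under patient relabeling
  perm <- sample.int(n)
  cs3 <- calibration_slope(p[perm], y[perm])
  expect_equal(cs3$slope, cs$slope, tolerance = 1e-6)
  expect_error(calibration_slope(c(0, 0.5), c(TRUE, FALSE)), "strictly inside")
})

test_that("Brier score closed forms and hand arithmetic", {
  expect_equal(brier_score(c(1, 0, 1), c(TRUE, FALSE, TRUE)), 0)
  expect_equal(brier_score(rep(0.5, 100), rep(c(TRUE, FALSE), 50)), 0.25)
  expect_equal(brier_score(c(0.9, 0.2, 0.7, 0.1, 0.5), c(1, 0, 1, 0, 1)),
               (0.01 + 0.04 + 0.09 + 0.01 + 0.25) / 5)
  expect_error(brier_score(c(0.5), c(1, 0)), "same length")
  # perfectly calibrated constant predictor: Brier ~ p(1-p)
  set.seed(3)
  y <- runif(20000) < 0.3
  expect_equal(brier_score(rep(0.3, 20000), y), 0.3 * 0.7, tolerance = 0.01)
})

test_that("implementation agrees with independent library oracles", {
  skip_if_not_installed("pROC")
  co <- small_cohort(500, seed = 71)
  s <- co$bnp_pg_ml; y <- co$poaf_event
  expect_equal(roc_auc(s, y),
               as.numeric(suppressMessages(pROC::auc(y, s, direction = "<"))))
  # KS statistic against stats::ks.test
  x1 <- co$crp_mg_l[1:200]; x2 <- co$crp_mg_l[201:400]
  ks <- ks2_stat(x1, x2)
  ref <- suppressWarnings(stats::ks.test(x1, x2))
  expect_equal(ks$D, unname(ref$statistic))
})
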