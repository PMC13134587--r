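test_that("cohort generation handles the empty case and is deterministic", {
  empty <- generate_cohort(gt_config(), 0)
  expect_equal(nrow(empty), 0)
  expect_identical(names(empty), poaftwin:::.cohort_columns)
  expect_error(generate_cohort(gt_config(), -1), "non-negative")

  a <- generate_cohort(gt_config(), 500, seed = 7)
  b <- generate_cohort(gt_config(), 500, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(gt_config(), 500, seed = 8)))
})

test_that("generated records satisfy the record invariants", {
  co <- small_cohort(1000, seed = 3)
  expect_true(all(co$age >= 18))
  expect_true(all(co$qt_ms < co$rr_s * 1000))
  expect_true(all(co$pr_ms > 0 & co$qrs_ms > 0 & co$qt_ms > 0 & co$rr_s > 0))
  expect_true(all(is.na(co$poaf_day) == !co$poaf_event))
  expect_true(all(co$poaf_day[co$poaf_event] %in% 1:7))
  expect_true(all(co$censored == !co$poaf_event))
})

test_that("untreated 7-day incidence matches the calibrated target", {
  co <- generate_cohort(gt_config(), 10000, seed = 3)
  target <- gt_config()$target_7day_incidence
  se <- sqrt(target * (1 - target) / 10000)
  expect_lt(abs(mean(co$poaf_event) - target), 3 * se)
})

test_that("true_daily_hazard obeys its limiting cases and monotonicity", {
  co <- small_cohort(50)
  cfg0 <- gt_config(coef_vulnerability = 0, coef_electrolyte = 0,
                    coef_inflammation = 0, coef_age = 0,
                    day_shape = rep(1, 7))
  h <- true_daily_hazard(co, 4, cfg0, 1)
  expect_equal(h, rep(cfg0$baseline_daily_hazard, nrow(co)), tolerance = 1e-12)
  expect_equal(true_daily_hazard(co, 4, cfg0, 0), rep(0, nrow(co)))
  expect_error(true_daily_hazard(co, 8, cfg0), "1..7")
  expect_error(true_daily_hazard(co, 0, cfg0), "1..7")

  # monotone in CRP when the inflammation weight is positive
  r1 <- co[1, ]; r2 <- r1
  r2$crp_mg_l <- r1$crp_mg_l * 3
  cfg <- gt_config()
  expect_gt(true_daily_hazard(r2, 2, cfg), true_daily_hazard(r1, 2, cfg))
})

test_that("benefit profile is minimal on the 48-72 h window", {
  cfg <- gt_config()
  grid <- seq(0, 140, by = 4)
  m <- benefit_multiplier(cfg, grid)
  expect_equal(min(m), 0.6)
  expect_true(all(grid[m == min(m)] >= 48 & grid[m == min(m)] <= 72))
  expect_equal(benefit_multiplier(cfg, 0), 1)
  expect_equal(benefit_multiplier(cfg, 500), 1)
})

test_that("chained imputation restores masked values and reports convergence", {
  co <- small_cohort(600, seed = 9)
  # identity on complete data
  same <- impute_chained(co)
  expect_equal(same[poaftwin:::.continuous_lab_ecg],
               co[poaftwin:::.continuous_lab_ecg])
  expect_equal(attr(same, "imputation_report")$iterations, 0L)

  # two perfectly linearly related columns: masked value recovered exactly
  co2 <- co
  co2$magnesium_meq_l <- 0.5 * co2$potassium_meq_l + 0.1
  truth <- co2$magnesium_meq_l[5]
  co2$magnesium_meq_l[5] <- NA
  imp <- impute_chained(co2, max_iter = 25, tol = 1e-8)
  expect_equal(imp$magnesium_meq_l[5], truth, tolerance = 1e-4)

  # end-to-end injection: no missing values remain, change path is monotone
  out <- inject_and_impute(co, gt_config(), seed = 5)
  expect_false(anyNA(out[poaftwin:::.continuous_lab_ecg]))
  path <- attr(out, "imputation_report")$change_path
  expect_true(all(diff(path) < 0))

  # fully missing column is unimputable
  co3 <- co
  co3$crp_mg_l <- NA_real_
  expect_error(impute_chained(co3), "unimputable")

  # exceeding the <5% regime warns
  expect_warning(gt_config(missing_fraction = 0.10), "5%")
  cfg10 <- suppressWarnings(gt_config(missing_fraction = 0.10))
  expect_warning(inject_and_impute(co, cfg10, seed = 5), "5%")
})

test_that("multiple completions differ only in their residual draws", {
  co <- small_cohort(300, seed = 13)
  cfgm <- gt_config(missing_fraction = 0.04)
  ms <- inject_and_impute(co, cfgm, seed = 6, m = 3)
  expect_length(ms, 3)
  expect_false(identical(ms[[1]]$crp_mg_l, ms[[2]]$crp_mg_l))
  for (m in ms) expect_false(anyNA(m[poaftwin:::.continuous_lab_ecg]))
})

test_that("split_cohort partitions with floor sizes and remainder to training", {
  co <- small_cohort(1000, seed = 21)
  sp <- split_cohort(co, seed = 4)
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 700L, validation = 150L, test = 150L))
  ids <- c(sp$train$id, sp$validation$id, sp$test$id)
  expect_setequal(ids, co$id)
  expect_equal(anyDuplicated(ids), 0L)

  sp10 <- split_cohort(co[1:10, ], seed = 4)
  expect_equal(vapply(sp10, nrow, integer(1)),
               c(train = 8L, validation = 1L, test = 1L))
  expect_error(split_cohort(co, fractions = c(0.7, 0.2, 0.2)), "summing to 1")
})

test_that("gt_config round-trips through YAML", {
  cfg <- gt_config(coef_age = 0.4, seed = 9L)
  p <- withr::local_tempfile(fileext = ".yaml")
  write_gt_config(cfg, p)
  cfg2 <- read_gt_config(p)
  expect_equal(cfg2$coef_age, 0.4)
  expect_equal(cfg2$benefit_profile, cfg$benefit_profile)
  expect_equal(cfg2$seed, 9L)
})
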