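test_that("Bazett correction handles its reference cases", {
  expect_equal(qtc_bazett(400, 1.0), 400)
  expect_equal(qtc_bazett(400, 0.25), 800)
  expect_equal(qtc_bazett(350, 0.64), 437.5) # 350 / 0.8
  expect_error(qtc_bazett(0, 1), "> 0")
  expect_error(qtc_bazett(400, -1), "> 0")
})

test_that("self-consistent target recovers identity scales", {
  cache <- twin_cache_fixture()
  cfg <- calibration_config()
  base_apd <- cache$apd(1)
  rec <- small_cohort(10)[1, ]
  rec$rr_s <- 1
  rec$qt_ms <- base_apd + cfg$qt_to_apd_offset_ms
  tw <- calibrate_twin(rec, cfg, cache)
  expect_equal(tw$s_Kr, 1, tolerance = 0.02)
  expect_lt(tw$calibration_residual_ms, cfg$optimizer_tol_ms)
  expect_true(tw$converged)
})

test_that("unreachable target saturates the bound and is flagged", {
  cache <- twin_cache_fixture()
  cfg <- calibration_config()
  rec <- small_cohort(10)[1, ]
  rec$rr_s <- 1
  rec$qt_ms <- 500 # target APD 440 ms, above the achievable range
  tw <- calibrate_twin(rec, cfg, cache)
  expect_false(tw$converged)
  expect_equal(tw$s_Kr, cfg$scale_bounds[1], tolerance = 0.01)
  expect_equal(tw$calibration_residual_ms,
               abs(cache$apd(cfg$scale_bounds[1]) - (500 - 60)),
               tolerance = 0.5)
})

test_that("calibration recovers known s_Kr ground truth (median error < 0.05)", {
  cache <- twin_cache_fixture()
  cfg <- calibration_config()
  set.seed(77)
  s_true <- runif(50, 0.6, 1.4)
  recs <- small_cohort(50, seed = 55)
  err <- vapply(seq_len(50), function(i) {
    # ground-truth QTc from the full ODE, not the cached surrogate
    apd <- apd90_at_scales(s_Kr = s_true[i], dt_ms = cfg$dt_ms)
    r <- recs[i, ]
    r$rr_s <- 1
    r$qt_ms <- apd + cfg$qt_to_apd_offset_ms
    tw <- calibrate_twin(r, cfg, cache)
    abs(tw$s_Kr - s_true[i])
  }, numeric(1))
  expect_lt(median(err), 0.05)
})

test_that("calibration is deterministic and never worse than identity scales", {
  cache <- twin_cache_fixture()
  cfg <- calibration_config()
  recs <- small_cohort(20, seed = 66)
  for (i in c(1, 7, 13)) {
    r <- recs[i, , drop = FALSE]
    t1 <- calibrate_twin(r, cfg, cache)
    t2 <- calibrate_twin(r, cfg, cache)
    expect_identical(t1$s_Kr, t2$s_Kr)
    target <- qtc_bazett(r$qt_ms, r$rr_s) - cfg$qt_to_apd_offset_ms
    expect_lte((t1$apd90_ms - target)^2, (cache$apd(1) - target)^2 + 1e-9)
  }
})

test_that("multi-parameter mode is flagged under-determined", {
  cache <- twin_cache_fixture()
  cfg <- calibration_config(free = c("s_Kr", "s_CaL"))
  r <- small_cohort(10)[2, , drop = FALSE]
  expect_warning(tw <- calibrate_twin(r, cfg, cache), "under-determined")
  expect_true(tw$under_determined)
})

test_that("records with missing fields are rejected before calibration", {
  r <- small_cohort(10)[1, , drop = FALSE]
  r$qt_ms <- NA_real_
  expect_error(calibrate_twin(r), "impute")
})

test_that("vulnerability index is the logistic of the weighted components", {
  twin <- structure(list(patient_id = "x", apd90_ms = 285, cv_mm_per_ms = 0.39,
                         dispersion_ms = 0.5, converged = TRUE),
                    class = "twin_model")
  rec <- small_cohort(10)[1, ]
  rec$potassium_meq_l <- 4.5; rec$magnesium_meq_l <- 2.2; rec$crp_mg_l <- 5
  # all components at reference, zero weights -> logistic(0) = 0.5
  w0 <- vulnerability_weights() * 0
  expect_equal(vulnerability_index(twin, rec, w0), 0.5)
  expect_equal(vulnerability_index(twin, rec), 0.5, tolerance = 1e-9)

  # direct formula oracle on a hand-built component vector
  twin2 <- twin
  twin2$apd90_ms <- 310; twin2$cv_mm_per_ms <- 0.34; twin2$dispersion_ms <- 1.5
  rec2 <- rec
  rec2$potassium_meq_l <- 3.6; rec2$crp_mg_l <- 20
  z <- c((310 - 285) / 25, (0.39 - 0.34) / 0.05, (1.5 - 0.5) / 1.0,
         (4.0 - 3.6) / 0.4, (log(20) - log(5)) / 0.8)
  w <- vulnerability_weights()
  expect_equal(vulnerability_index(twin2, rec2), plogis(sum(w * z)))

  # strictly increasing in CRP
  rec3 <- rec2; rec3$crp_mg_l <- 40
  expect_gt(vulnerability_index(twin2, rec3), vulnerability_index(twin2, rec2))

  # degenerate (NA) components are standardized to zero
  twin_na <- twin; twin_na$cv_mm_per_ms <- NA_real_
  expect_equal(vulnerability_index(twin_na, rec), 0.5)
})

test_that("cohort-level calibration produces a complete, convergent table", {
  co <- small_cohort(40, seed = 91)
  tw <- calibrate_cohort(co, cache = twin_cache_fixture())
  expect_equal(nrow(tw), 40)
  expect_identical(tw$patient_id, co$id)
  expect_true(all(tw$s_Kr >= 0.5 & tw$s_Kr <= 1.5))
  expect_true(all(tw$calibration_residual_ms >= 0))
  expect_true(all(tw$vulnerability >= 0 & tw$vulnerability <= 1))
  expect_gt(mean(tw$converged), 0.9)
})
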