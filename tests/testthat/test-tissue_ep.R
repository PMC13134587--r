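test_that("homogeneous fiber activates causally with CV in the atrial band", {
  r <- simulate_fiber(fiber_config(dt_ms = 0.05), n_beats = 2)
  expect_true(all(r$captured))
  expect_true(all(diff(r$activation_time_ms) > 0))
  expect_gt(r$cv_mm_per_ms, 0.3)
  expect_lt(r$cv_mm_per_ms, 1.2)
})

test_that("uncoupled fiber blocks: only the stimulated nodes activate", {
  cfg <- fiber_config(n_nodes = 20, diffusion_mm2_per_ms = 0, dt_ms = 0.05)
  r <- simulate_fiber(cfg, n_beats = 2)
  expect_true(r$block)
  expect_true(is.na(r$cv_mm_per_ms))
  # pacing electrode covers the first two nodes; nothing beyond activates
  expect_true(all(which(r$captured) <= 2))
  expect_error(apd_dispersion(structure(list(apd90_ms = c(NA, NA),
                                             captured = c(FALSE, FALSE)),
                                        class = "propagation_result"),
                              central = 1), "block")
})

test_that("CFL violation is rejected before integration", {
  cfg <- fiber_config(diffusion_mm2_per_ms = 0.4, dt_ms = 0.2)
  expect_error(simulate_fiber(cfg), "CFL")
})

test_that("conduction velocity scales as sqrt(diffusion)", {
  r1 <- simulate_fiber(fiber_config(dt_ms = 0.05), n_beats = 2)
  r4 <- simulate_fiber(fiber_config(diffusion_mm2_per_ms = 0.4, dt_ms = 0.05),
                       n_beats = 2)
  ratio <- r4$cv_mm_per_ms / r1$cv_mm_per_ms
  expect_lt(abs(ratio - 2) / 2, 0.10)
})

test_that("conduction_velocity arithmetic and symmetry", {
  fake <- structure(list(activation_time_ms = c(10, 20),
                         captured = c(TRUE, TRUE), dx_mm = 10,
                         pacing_site = 1), class = "propagation_result")
  expect_equal(conduction_velocity(fake, 1, 2, dx_mm = 10), 1.0)
  expect_error(conduction_velocity(fake, 1, 1), "differ")

  # center-paced fiber: leftward and rightward CV agree within 1%
  cfg <- fiber_config(n_nodes = 81, pacing_site = 41, dt_ms = 0.05)
  r <- simulate_fiber(cfg, n_beats = 2)
  cv_l <- conduction_velocity(r, 33, 9)
  cv_r <- conduction_velocity(r, 49, 73)
  expect_lt(abs(cv_l - cv_r) / cv_r, 0.01)

  blocked <- fake; blocked$captured[2] <- FALSE
  expect_error(conduction_velocity(blocked, 1, 2), "block")
})

test_that("APD dispersion reflects constructed heterogeneity", {
  base <- simulate_fiber(fiber_config(n_nodes = 60, dt_ms = 0.05), n_beats = 2)
  d0 <- apd_dispersion(base)
  expect_lt(d0, 5)

  # s_Kr = 0.6 on the distal half prolongs repolarization there
  half <- c(rep(list(cell_params()), 30),
            rep(list(cell_params(s_Kr = 0.6)), 30))
  het <- simulate_fiber(fiber_config(n_nodes = 60, dt_ms = 0.05,
                                     cell_params_per_node = half), n_beats = 2)
  d1 <- apd_dispersion(het)
  expect_gt(d1, d0)

  # equals an independent brute-force max - min over the recorded array
  n <- length(base$apd90_ms)
  idx <- max(1, ceiling(n * 0.2)):min(n, floor(n * 0.8))
  ok <- idx[base$captured[idx]]
  expect_equal(d0, max(base$apd90_ms[ok]) - min(base$apd90_ms[ok]))
})

test_that("bidomain with equal anisotropy matches monodomain within 1 ms", {
  cfg <- fiber_config(n_nodes = 50, dt_ms = 0.05)
  rb <- simulate_fiber_bidomain(cfg, 0.2, 0.2, n_beats = 2) # harmonic mean 0.1
  rm <- simulate_fiber(cfg, n_beats = 2)
  expect_true(all(rb$captured))
  expect_lt(max(abs(rb$activation_time_ms - rm$activation_time_ms)), 1)
  expect_true(is.finite(rb$cv_mm_per_ms) && rb$cv_mm_per_ms > 0)

  # halving both conductivities slows conduction
  rh <- simulate_fiber_bidomain(cfg, 0.1, 0.1, n_beats = 2)
  expect_lt(rh$cv_mm_per_ms, rb$cv_mm_per_ms)
})

test_that("fiber configs round-trip through YAML and results export to CSV", {
  cfg <- fiber_config(n_nodes = 12, diffusion_mm2_per_ms = 0.05, dt_ms = 0.05)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_fiber_config(cfg, f)
  cfg2 <- read_fiber_config(f)
  expect_equal(cfg2$n_nodes, 12L)
  expect_equal(cfg2$diffusion_mm2_per_ms, 0.05)
  r <- simulate_fiber(cfg, n_beats = 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_propagation_csv(r, csv)
  back <- read.csv(csv)
  expect_equal(back$activation_ms, r$activation_time_ms)
})
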