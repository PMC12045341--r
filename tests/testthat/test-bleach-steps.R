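test_that("bleach_trace validates its invariants", {
  expect_error(bleach_trace(5, 0.015), "length")
  expect_error(bleach_trace(c(1, NA), 0.015))
  expect_error(bleach_trace(c(1, 2), 0))
  tr <- bleach_trace(c(3, 2, 1, 0), 0.015, roi_id = "f1")
  expect_s3_class(tr, "bleach_trace")
  expect_equal(tr$roi_id, "f1")
})

test_that("extract_trace recovers per-frame ROI intensity minus background", {
  cfg <- sim_config(noise_sd = 0)
  # constant image: trace is exactly zero
  stack <- array(cfg$background_level, dim = c(64, 64, 3))
  tr <- extract_trace(stack, center = c(5, 5), radius = 0.4, cfg)
  expect_equal(tr$intensities, rep(0, 3))
  # noiseless rendered 3-emitter focus, nobody bleaching
  em <- data.frame(frame = rep(1:3, each = 3), x_um = 5, y_um = 5)
  stack <- render_movie(em, cfg, n_frames = 3)
  tr <- extract_trace(stack, center = c(5, 5), radius = 0.64, cfg)
  expect_equal(tr$intensities, rep(3 * cfg$photon_scale, 3),
               tolerance = 0.02)
  expect_error(extract_trace(stack, center = c(0.2, 0.2), radius = 0.4, cfg),
               "outside")
})

test_that("extract_trace round-trips a rendered bleaching movie", {
  cfg <- sim_config(noise_sd = 0, rng_seed = 23L)
  sim <- simulate_bleach_trace(4, cfg, 60)
  em <- data.frame(frame = seq_len(60), x_um = 5, y_um = 5,
                   intensity = cfg$photon_scale * sim$truth$survivors)
  em <- em[em$intensity > 0, , drop = FALSE]
  stack <- render_movie(em, cfg, n_frames = 60)
  tr <- extract_trace(stack, center = c(5, 5), radius = 0.64, cfg)
  expect_equal(tr$intensities,
               cfg$photon_scale * sim$truth$survivors,
               tolerance = 0.05)
})

test_that("detect_steps is exact on noiseless piecewise-constant input", {
  tr <- c(rep(100, 3), rep(70, 2), rep(40, 2), rep(10, 2))
  fit <- detect_steps(bleach_trace(tr, 0.015))
  expect_identical(fit$change_frames, c(3L, 5L, 7L))
  expect_equal(fit$step_sizes, c(-30, -30, -30))
  expect_equal(fit$level_means, c(100, 70, 40, 10))
})

test_that("detect_steps returns no change points on a flat trace", {
  fit <- detect_steps(bleach_trace(rep(5, 20), 0.015))
  expect_length(fit$change_frames, 0)
  expect_error(detect_steps(c(1, 2, 3)), "at least 4")
})

test_that("step fit reconstruction never exceeds the raw trace variance", {
  set.seed(31)
  cfg <- sim_config(noise_sd = sim_config()$photon_scale / 5)
  for (k in c(2, 5, 9)) {
    sim <- simulate_bleach_trace(k, cfg, 200)
    fit <- detect_steps(sim$trace)
    seg_ends <- c(fit$change_frames, length(sim$trace$intensities))
    recon <- rep(fit$level_means, diff(c(0L, seg_ends)))
    expect_lte(mean((sim$trace$intensities - recon)^2),
               var(sim$trace$intensities))
  }
})

test_that("change-point counts match distinct bleach frames at 5x noise", {
  # 200 simulated foci at unit-step / noise = 5; the detected change-point
  # count should equal the number of distinct true bleach frames in >= 95%
  # of traces
  set.seed(21)
  cfg <- sim_config(noise_sd = sim_config()$photon_scale / 5)
  n_true <- sample(1:10, 200, replace = TRUE)
  agree <- 0L
  for (i in seq_along(n_true)) {
    sim <- simulate_bleach_trace(n_true[i], cfg, 400)
    fit <- quiet_count(sim$trace)
    truth_cp <- unique(sim$truth$bleach_frames[sim$truth$bleach_frames <= 400])
    agree <- agree + (length(fit$change_frames) == length(truth_cp))
  }
  expect_gte(agree / 200, 0.95)
})

test_that("estimate_unit_step matches the hand-worked examples", {
  expect_equal(estimate_unit_step(30), 30)
  expect_equal(estimate_unit_step(c(29, 31, 60, 30)), 30, tolerance = 0.02)
  expect_equal(estimate_unit_step(c(10, 10, 10, 10)), 10)
  expect_error(estimate_unit_step(numeric(0)), "at least one")
})

test_that("count_molecules generalizes coincident steps and flags blinking", {
  fit <- detect_steps(c(rep(40, 4), rep(30, 4), rep(10, 4), rep(0, 4)))
  fit <- count_molecules(fit, unit_step = 10)
  expect_identical(fit$n_molecules, 4L)  # steps -1, -2, -1 units
  expect_identical(fit$dropped_steps, 0L)
  # single step
  fit1 <- count_molecules(detect_steps(c(rep(10, 4), rep(0, 4))),
                          unit_step = 10)
  expect_identical(fit1$n_molecules, 1L)
  # an upward step is blinking: warned about and not counted
  up <- detect_steps(c(rep(10, 4), rep(0, 4), rep(10, 4), rep(0, 4)))
  expect_warning(fitb <- count_molecules(up, unit_step = 10), "blinking")
  expect_identical(fitb$n_molecules, 2L)
  expect_error(count_molecules(fit, unit_step = -1), "positive")
})

test_that("counting is equivariant under intensity rescaling", {
  set.seed(37)
  cfg <- sim_config(noise_sd = sim_config()$photon_scale / 5)
  sim <- simulate_bleach_trace(6, cfg, 300)
  f1 <- quiet_count(sim$trace)
  scaled <- bleach_trace(sim$trace$intensities * 3.7, 0.015)
  f2 <- quiet_count(scaled)
  expect_identical(f2$n_molecules, f1$n_molecules)
  expect_equal(f2$unit_step / f1$unit_step, 3.7, tolerance = 1e-6)
})

test_that("refine_steps recovers frame-exact change points", {
  # noiseless two-step trace with a deliberately misplaced change point
  x <- c(rep(30, 5), rep(20, 1), rep(10, 10))
  fit <- detect_steps(x)
  fit$change_frames <- c(4L, 6L)   # perturb
  fit$level_means <- c(30, 25, 10)
  ref <- refine_steps(fit, unit_step = 10)
  expect_identical(ref$change_frames, c(5L, 6L))
  expect_equal(ref$level_means, c(30, 20, 10))
})

test_that("summarize_counts reports histogram, normal fit and odd fraction", {
  s <- summarize_counts(c(2, 10))
  expect_identical(s$min_count, 2L)
  expect_identical(s$max_count, 10L)
  expect_equal(s$odd_fraction, 0)
  s2 <- summarize_counts(c(1, 2, 3))
  expect_equal(s2$odd_fraction, 2 / 3)
  expect_equal(sum(s2$histogram), 3)
  # Monte-Carlo: ML mean of rounded N(6, 2^2) draws is close to 6
  set.seed(41)
  draws <- pmax(1, round(rnorm(174, 6, 2)))
  s3 <- summarize_counts(draws)
  se <- 2 / sqrt(174)
  expect_lt(abs(s3$gaussian_mean - 6), 3 * se)
})

test_that("count_trace errors cleanly when nothing bleaches", {
  expect_error(count_trace(bleach_trace(rep(50, 20), 0.015)),
               "no downward steps")
})
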