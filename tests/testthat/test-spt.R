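test_that("detect_particles localizes a noiseless emitter to sub-pixel accuracy", {
  cfg <- sim_config(noise_sd = 0)
  em <- data.frame(frame = 1L, x_um = 5.043, y_um = 4.781)
  img <- render_movie(em, cfg, n_frames = 1)[, , 1]
  det <- detect_particles(img, cfg)
  expect_equal(nrow(det), 1)
  expect_equal(det$x_um, 5.043, tolerance = 1e-3)
  expect_equal(det$y_um, 4.781, tolerance = 1e-3)
  expect_equal(det$sigma, cfg$psf_sigma, tolerance = 0.02)
})

test_that("detect_particles returns no spots on pure background", {
  cfg <- sim_config()
  set.seed(3)
  img <- matrix(rnorm(64 * 64, cfg$background_level, cfg$noise_sd), 64, 64)
  det <- detect_particles(img, cfg)
  expect_equal(nrow(det), 0)
})

test_that("detection precision on noisy frames is near the localization limit", {
  set.seed(19)
  cfg <- sim_config(rng_seed = 19L)
  pos <- data.frame(frame = 1:40,
                    x_um = 5 + runif(40, -0.08, 0.08),
                    y_um = 5 + runif(40, -0.08, 0.08))
  stack <- render_movie(pos, cfg, n_frames = 40)
  det <- detect_stack(stack, cfg)
  expect_gte(nrow(det), 35)
  m <- merge(det, pos, by = "frame", suffixes = c("", "_true"))
  err <- sqrt((m$x_um - m$x_um_true)^2 + (m$y_um - m$y_um_true)^2)
  # ~25 nm localization precision at these photon counts
  expect_lt(sqrt(mean(err^2)), 0.050)
})

test_that("link reconstructs well-separated trajectories exactly", {
  # two particles 2 um apart, drifting slowly: greedy linking is unambiguous
  f <- rep(1:10, each = 2)
  det <- data.frame(frame = f,
                    x_um = ifelse(seq_along(f) %% 2 == 1, 1 + f * 0.01,
                                  3 - f * 0.01),
                    y_um = rep(c(1, 3), 10))
  tr <- link(det)
  expect_equal(length(unique(tr$track_id)), 2)
  expect_equal(as.vector(table(tr$track_id)), c(10L, 10L))
  # within a track, y never changes between the two lanes
  expect_true(all(tapply(tr$y_um, tr$track_id, function(v) length(unique(v))) == 1))
})

test_that("link splits tracks across displacement gaps and missing frames", {
  det <- data.frame(frame = c(1, 2, 3, 4),
                    x_um = c(1, 1.05, 2.5, 2.55), y_um = 0)
  tr <- link(det, max_disp = 0.320)
  expect_equal(length(unique(tr$track_id)), 2)   # jump of 1.45 um breaks it
  det2 <- data.frame(frame = c(1, 2, 4, 5), x_um = c(1, 1.01, 1.02, 1.03),
                     y_um = 0)
  tr2 <- link(det2)
  expect_equal(length(unique(tr2$track_id)), 2)  # no gap closing
})

test_that("greedy linking matches the optimal assignment in the tracking regime", {
  # sparse-activation regime: inter-particle spacing (>= 1.2 um) is far above
  # the per-frame diffusive step (sd ~75 nm at D = 0.19) and the 0.32-um
  # gate, so the one-to-one matching is unambiguous and the greedy
  # ascending-distance pairing must coincide exactly with the exhaustive
  # minimum-cost assignment
  set.seed(29)
  grid <- as.matrix(expand.grid(x = c(0.5, 1.7), y = c(0.5, 1.7)))
  for (rep in 1:25) {
    n <- sample(2:4, 1)
    p1 <- grid[sample(4, n), , drop = FALSE] +
      matrix(runif(2 * n, -0.15, 0.15), ncol = 2)
    p2 <- p1 + matrix(rnorm(2 * n, 0, 0.075), ncol = 2)
    det <- data.frame(frame = rep(1:2, each = n),
                      x_um = c(p1[, 1], p2[, 1]),
                      y_um = c(p1[, 2], p2[, 2]))
    tr <- link(det, max_disp = 0.320)
    opt <- optimal_assignment(p1[, 1], p1[, 2], p2[, 1], p2[, 2],
                              gate = 0.320)
    expect_identical(linked_pairs(det, tr), opt)
  }
})

test_that("filter_trajectories applies the in-focus length window", {
  mk <- function(id, n) data.frame(track_id = id, frame = seq_len(n),
                                   x_um = 0, y_um = 0)
  tracks <- rbind(mk(1, 3), mk(2, 4), mk(3, 12), mk(4, 15))
  kept <- filter_trajectories(tracks)
  expect_setequal(unique(kept$track_id), c(2, 3))
  trunc <- filter_trajectories(tracks, too_long = "truncate")
  expect_setequal(unique(trunc$track_id), c(2, 3, 4))
  expect_equal(sum(trunc$track_id == 4), 12)
  expect_equal(max(trunc$frame[trunc$track_id == 4]), 12)
})

test_that("compute_msd agrees with the brute-force oracle", {
  cfg <- sim_config(rng_seed = 5L)
  sim <- simulate_trajectories(0.2, 25, 9, cfg)
  msd <- compute_msd(sim$tracks, max_lag = 4, frame_interval = 0.015)
  oracle <- brute_force_msd(sim$tracks, 4, 0.015)
  expect_equal(msd$msd_um2, oracle$msd_um2, tolerance = 1e-12)
  expect_identical(msd$n_pairs, oracle$n_pairs)
  bad <- data.frame(track_id = 1, frame = c(1, 3, 4), x_um = 0, y_um = 0)
  expect_error(compute_msd(bad), "consecutive")
})

test_that("estimate_D is exact on an ideal MSD line", {
  dt <- 0.015; D <- 0.19
  msd <- data.frame(lag_s = (1:4) * dt, msd_um2 = 4 * D * (1:4) * dt,
                    n_pairs = 100L)
  class(msd) <- c("msd_curve", "data.frame")
  expect_equal(estimate_D(msd)$D, D, tolerance = 1e-12)
  # with a positive offset, the free-intercept fit recovers slope and offset
  msd$msd_um2 <- msd$msd_um2 + 0.01
  f <- estimate_D(msd, intercept = TRUE)
  expect_equal(f$D, D, tolerance = 1e-12)
  expect_equal(f$intercept_um2, 0.01, tolerance = 1e-12)
})

test_that("a stationary particle yields D = 0", {
  tracks <- data.frame(track_id = 1, frame = 1:10, x_um = 2, y_um = 3)
  est <- estimate_D_tracks(tracks)
  expect_equal(est$D, 0)
  expect_equal(est$n_trajectories, 1L)
})

test_that("estimate_D_tracks recovers the simulated diffusion coefficient", {
  cfg <- sim_config(rng_seed = 61L)
  sim <- simulate_trajectories(0.22, 600, 8, cfg)
  est <- estimate_D_tracks(sim$tracks, n_boot = 200, seed = 1)
  expect_equal(est$D, 0.22, tolerance = 0.05)
  expect_equal(est$n_trajectories, 600L)
  expect_gt(est$bootstrap_sd, 0)
  # true D well within a few bootstrap SDs
  expect_lt(abs(est$D - 0.22), 4 * est$bootstrap_sd)
})

test_that("bootstrap_D needs at least two trajectories", {
  one <- data.frame(track_id = 1, frame = 1:8, x_um = rnorm(8), y_um = rnorm(8))
  expect_error(bootstrap_D(one), "two trajectories")
})

test_that("the linking gate admits 0.30 um and rejects 0.40 um", {
  inside <- data.frame(frame = 1:2, x_um = c(1, 1.30), y_um = 0)
  expect_equal(length(unique(link(inside, max_disp = 0.320)$track_id)), 1)
  outside <- data.frame(frame = 1:2, x_um = c(1, 1.40), y_um = 0)
  expect_equal(length(unique(link(outside, max_disp = 0.320)$track_id)), 2)
})

test_that("compute_msd matches the hand-computed single-track example", {
  tr <- data.frame(track_id = 1, frame = 1:3,
                   x_um = c(0, 0.160, 0.160), y_um = c(0, 0, 0.160))
  m <- compute_msd(tr, max_lag = 2, frame_interval = 0.015)
  # lag 1: mean of 0.160^2 and 0.160^2; lag 2: 0.160^2 + 0.160^2
  expect_equal(m$msd_um2, c(0.0256, 0.0512), tolerance = 1e-12)
  expect_identical(m$n_pairs, c(2L, 1L))
})

test_that("ensemble MSD of Brownian tracks matches 4 D lag time", {
  cfg <- sim_config(rng_seed = 13L)
  sim <- simulate_trajectories(0.2, 5000, 20, cfg)
  msd <- compute_msd(sim$tracks, max_lag = 4,
                     frame_interval = cfg$frame_interval)
  ratio <- msd$msd_um2 / (4 * (1:4) * cfg$frame_interval)
  expect_true(all(abs(ratio - 0.2) / 0.2 < 0.02))
})

test_that("identical resampled tracks give a zero bootstrap SD", {
  tr <- do.call(rbind, lapply(1:3, function(i)
    data.frame(track_id = i, frame = 1:6,
               x_um = c(0, 0.1, 0.05, 0.2, 0.15, 0.3),
               y_um = c(0, 0, 0.1, 0.1, 0.2, 0.2))))
  est <- estimate_D_tracks(tr, n_boot = 100, seed = 1)
  expect_identical(est$bootstrap_sd, 0)
})
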