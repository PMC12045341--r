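test_that("sim_config validates inputs and carries units", {
  cfg <- sim_config()
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$pixel_size, 0.160)
  expect_equal(cfg$frame_interval, 0.015)
  expect_error(sim_config(pixel_size = -1))
  expect_error(sim_config(noise_sd = -5))
  expect_error(sim_config(image_shape = 64))
})

test_that("diffusion presets expose the three population coefficients", {
  p <- diffusion_presets()
  expect_named(p, c("om", "im", "transfer"))
  expect_true(all(p > 0))
  expect_lt(p[["om"]], p[["im"]])
})

test_that("seeded configs reproduce bit-identical simulations", {
  cfg <- sim_config(rng_seed = 42L)
  a <- simulate_bleach_trace(5, cfg, 100)
  b <- simulate_bleach_trace(5, cfg, 100)
  expect_identical(a$trace$intensities, b$trace$intensities)
  sa <- simulate_trajectories(0.2, 3, 10, cfg)
  sb <- simulate_trajectories(0.2, 3, 10, cfg)
  expect_identical(sa$tracks, sb$tracks)
})

test_that("bleach trace ground truth matches the noiseless trace", {
  cfg <- sim_config(noise_sd = 0, background_level = 0, rng_seed = 7L)
  sim <- simulate_bleach_trace(6, cfg, 300)
  expect_equal(sim$trace$intensities,
               cfg$photon_scale * sim$truth$survivors)
  # survivors are non-increasing and start at the full complement
  expect_true(all(diff(sim$truth$survivors) <= 0))
  expect_equal(sim$truth$survivors[1], 6L)
  # a fluorophore is dark from its recorded bleach frame onwards
  bf <- sim$truth$bleach_frames
  expect_true(all(bf >= 2))
})

test_that("free trajectories have the prescribed displacement statistics", {
  cfg <- sim_config(rng_seed = 11L)
  D <- 0.25
  sim <- simulate_trajectories(D, 400, 12, cfg)
  dx <- unlist(lapply(split(sim$tracks, sim$tracks$track_id),
                      function(tr) diff(tr$x_um)))
  # var(dx) = 2 D dt; with ~4400 steps the sample variance is within a few %
  expect_equal(var(dx), 2 * D * cfg$frame_interval, tolerance = 0.08)
  expect_equal(mean(dx), 0, tolerance = 0.005)
})

test_that("confined trajectories never leave the cell", {
  cfg <- sim_config(rng_seed = 13L)
  cell <- cell_geometry(1L, c(5, 5), angle = 0.4, length = 4, width = 0.7)
  sim <- simulate_trajectories(0.3, 20, 60, cfg, geometry = cell)
  expect_true(all(points_in_cell(sim$tracks$x_um, sim$tracks$y_um, cell)))
})

test_that("rendered emitters conserve integrated intensity and position", {
  cfg <- sim_config(noise_sd = 0, background_level = 0)
  em <- data.frame(frame = 1L, x_um = 5.08, y_um = 4.87)
  img <- render_movie(em, cfg, n_frames = 1)[, , 1]
  # pixel values sum to photon_scale (PSF far from the border)
  expect_equal(sum(img), cfg$photon_scale, tolerance = 1e-6)
  # intensity-weighted centroid reproduces the emitter position
  xs <- (col(img) - 1) * cfg$pixel_size
  ys <- (row(img) - 1) * cfg$pixel_size
  expect_equal(sum(xs * img) / sum(img), 5.08, tolerance = 1e-6)
  expect_equal(sum(ys * img) / sum(img), 4.87, tolerance = 1e-6)
})

test_that("out-of-field emitters are clipped with a warning", {
  cfg <- sim_config(noise_sd = 0)
  em <- data.frame(frame = 1L, x_um = -3, y_um = 2)
  expect_warning(render_movie(em, cfg, n_frames = 1), "clipped")
})

test_that("rasterized cell masks match the analytic geometry", {
  cfg <- sim_config(image_shape = c(48L, 48L))
  cells <- adjacent_rod_pair(cfg)
  lab <- rasterize_cells(cells, cfg)
  expect_setequal(unique(as.vector(lab)), c(0L, 1L, 2L))
  # every labelled pixel centre lies inside its cell
  for (cell in cells) {
    idx <- which(lab == cell$cell_id, arr.ind = TRUE)
    xs <- (idx[, 2] - 1) * cfg$pixel_size
    ys <- (idx[, 1] - 1) * cfg$pixel_size
    expect_true(all(points_in_cell(xs, ys, cell)))
  }
  expect_error(rasterize_cells(list(cells[[1]], cells[[1]]), cfg), "overlap")
})

test_that("OME scenario tracks realise their crossing plans exactly", {
  cfg <- sim_config(image_shape = c(48L, 48L), rng_seed = 17L)
  cells <- adjacent_rod_pair(cfg)
  plans <- list(c(1L, 2L), c(1L, 2L, 1L), c(2L, 1L))
  sc <- simulate_ome_scenario(cfg, cells, plans, render = FALSE)
  for (i in seq_along(plans)) {
    lab <- sc$truth$labels$cell_id[sc$truth$labels$track_id == i]
    expect_identical(rle(lab)$values, plans[[i]])
  }
  # one crossing per plan transition, recorded between the flanking cells
  cr <- sc$truth$crossings
  expect_equal(nrow(cr), sum(lengths(plans) - 1L))
  expect_true(all(cr$from_cell != cr$to_cell))
})

test_that("simulated density profiles carry their true peak centres", {
  prof <- simulate_density_profile(c(10, 40), peak_widths_nm = 2.5)
  truth <- attr(prof, "truth")
  expect_equal(truth$peak_centers, c(10, 40))
  expect_s3_class(prof, "density_profile")
  expect_error(simulate_density_profile(c(10, 12), peak_widths_nm = 2.5),
               "overlap")
})

test_that("degenerate generator limits behave exactly", {
  # no fluorophores, no noise: the trace is flat at the background level
  s0 <- simulate_bleach_trace(0, sim_config(noise_sd = 0), 50)
  expect_true(all(s0$trace$value == sim_config()$background_level))
  expect_length(s0$truth$bleach_frames, 0)
  # D = 0: every trajectory stays at its starting point
  sim <- simulate_trajectories(0, 5, 10, sim_config(rng_seed = 3L))
  moved <- tapply(sim$tracks$x_um, sim$tracks$track_id,
                  function(v) length(unique(v)))
  expect_true(all(moved == 1))
})

test_that("fluorophore lifetimes follow the exponential bleach law", {
  # law of large numbers: at rate 2/s the mean of 10,000 bleach times must
  # fall within 3 standard errors of 1/rate = 0.5 s
  cfg <- sim_config(rng_seed = 11L, bleach_rate = 2)
  sim <- simulate_bleach_trace(10000, cfg, n_frames = 2)
  se <- 0.5 / sqrt(10000)
  expect_lt(abs(mean(sim$truth$bleach_times) - 0.5), 3 * se)
})
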