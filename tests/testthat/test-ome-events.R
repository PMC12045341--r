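# A small 3-cell label raster used across tests: cells 1 and 2 touch, cell 3
# is isolated in the opposite corner.
make_masks <- function() {
  lab <- matrix(0L, 20, 20)
  lab[5:16, 2:9] <- 1L
  lab[5:16, 11:18] <- 2L   # one background column between 1 and 2
  lab[1:2, 19:20] <- 3L
  cell_mask_set(lab)
}

test_that("cell_mask_set derives adjacency from near-contact", {
  masks <- make_masks()
  expect_identical(masks$cell_ids, c(1L, 2L, 3L))
  expect_identical(masks$adjacency, cbind(1L, 2L))
  # the one-column gap puts the facing pixels at Chebyshev distance 2, so a
  # 1-pixel neighbourhood no longer declares the cells adjacent
  masks1 <- cell_mask_set(masks$label_image, adjacency_px = 1L)
  expect_equal(nrow(masks1$adjacency), 0)
  # direct contact is adjacent even at radius 1
  lab2 <- masks$label_image
  lab2[5:16, 10] <- 1L
  masks_touch <- cell_mask_set(lab2, adjacency_px = 1L)
  expect_identical(masks_touch$adjacency, cbind(1L, 2L))
})

test_that("assign_cells maps positions to labels and flags out-of-raster", {
  masks <- make_masks()
  cfg <- sim_config()
  track <- data.frame(track_id = 1, frame = 1:3,
                      x_um = c(0.8, 1.44, 2.4),   # cols 6, 10 (gap), 16
                      y_um = rep(1.6, 3))         # row 11
  expect_identical(assign_cells(track, masks, cfg), c(1L, NA, 2L))
  bad <- data.frame(track_id = 1, frame = 1, x_um = 50, y_um = 1)
  expect_error(assign_cells(bad, masks, cfg), "outside")
})

test_that("bridge_labels fills only short unassigned runs", {
  expect_identical(bridge_labels(c(1L, NA, NA, 2L)), c(1L, 1L, 1L, 2L))
  expect_identical(bridge_labels(c(1L, NA, NA, NA, 2L)),
                   c(1L, NA, NA, NA, 2L))
  expect_identical(bridge_labels(c(NA, NA, 1L, 1L)), c(1L, 1L, 1L, 1L))
  expect_identical(bridge_labels(c(1L, 1L, NA)), c(1L, 1L, 1L))
})

test_that("detect_crossings classifies event directionality", {
  masks <- make_masks()
  cfg <- sim_config()
  base <- function(labels) {
    n <- length(labels)
    data.frame(track_id = 7L, frame = seq_len(n),
               x_um = seq(0.8, 2.4, length.out = n), y_um = 1.6)
  }
  uni <- detect_crossings(base(c(1L, 1L, 2L, 2L)), masks, cfg,
                          labels = c(1L, 1L, 2L, 2L))
  expect_s3_class(uni, "transfer_event")
  expect_identical(uni$event_type, "unidirectional")
  expect_identical(uni$n_boundaries, 1L)
  bi <- detect_crossings(base(c(1L, 2L, 1L, 1L)), masks, cfg,
                         labels = c(1L, 2L, 1L, 1L))
  expect_identical(bi$event_type, "bidirectional")
  expect_identical(bi$n_boundaries, 2L)
  # no label change at all: NULL, silently
  none <- detect_crossings(base(c(1L, 1L, 1L)), masks, cfg,
                           labels = c(1L, 1L, 1L))
  expect_null(none)
})

test_that("serial transfer through three cells is recognised", {
  lab <- matrix(0L, 10, 30)
  lab[3:8, 1:9] <- 1L; lab[3:8, 11:19] <- 2L; lab[3:8, 21:29] <- 3L
  masks <- cell_mask_set(lab)
  cfg <- sim_config()
  track <- data.frame(track_id = 1L, frame = 1:3,
                      x_um = c(0.6, 2.2, 3.8), y_um = 0.8)
  ev <- detect_crossings(track, masks, cfg, labels = c(1L, 2L, 3L))
  expect_identical(ev$event_type, "serial")
  expect_identical(ev$cells_visited, c(1L, 2L, 3L))
})

test_that("jumps between non-adjacent cells are excluded as teleports", {
  masks <- make_masks()
  cfg <- sim_config()
  track <- data.frame(track_id = 9L, frame = 1:2,
                      x_um = c(0.8, 3.04), y_um = c(1.6, 0.16))
  expect_warning(ev <- detect_crossings(track, masks, cfg,
                                        labels = c(1L, 3L)),
                 "teleport")
  expect_null(ev)
})

test_that("crossing coordinates are flanking-detection midpoints", {
  masks <- make_masks()
  cfg <- sim_config()
  track <- data.frame(track_id = 2L, frame = 1:2,
                      x_um = c(1.2, 1.9), y_um = c(1.5, 1.7))
  ev <- detect_crossings(track, masks, cfg, labels = c(1L, 2L))
  expect_equal(ev$crossings$x_um, 1.55)
  expect_equal(ev$crossings$y_um, 1.6)
  expect_identical(ev$crossings$from_cell, 1L)
  expect_identical(ev$crossings$to_cell, 2L)
})

test_that("simulated OME scenarios are detected track-for-track", {
  cfg <- sim_config(image_shape = c(48L, 48L), rng_seed = 83L)
  cells <- adjacent_rod_pair(cfg)
  plans <- rep(list(c(1L, 2L), c(2L, 1L), c(1L, 2L, 1L)), 3)
  sc <- simulate_ome_scenario(cfg, cells, plans, render = FALSE)
  masks <- cell_mask_set(rasterize_cells(cells, cfg))
  det <- detect_transfer_events(sc$tracks, masks, cfg)
  expect_equal(length(det$events), length(plans))
  expect_setequal(det$crossing_track_ids, seq_along(plans))
  # every planned boundary crossing is found
  expect_equal(sum(det$event_table$n_boundaries),
               sum(lengths(plans) - 1L))
  types <- det$event_table$event_type[order(det$event_table$track_id)]
  expect_identical(types, rep(c("unidirectional", "unidirectional",
                                "bidirectional"), 3))
})

test_that("event_diffusion pools crossing tracks and reports per-track D", {
  cfg <- sim_config(rng_seed = 101L)
  cells <- adjacent_rod_pair(cfg)
  sc <- simulate_ome_scenario(cfg, cells, rep(list(c(1L, 2L)), 6),
                              render = FALSE)
  ed <- event_diffusion(sc$tracks)
  expect_s3_class(ed$pooled, "diffusion_estimate")
  expect_equal(ed$pooled$n_trajectories, 6L)
  expect_equal(nrow(ed$per_track), 6)
  expect_true(all(ed$per_track$D >= 0))
})

test_that("focus_proximity measures distance to the nearest focus", {
  ev <- list(crossings = data.frame(frame = 5L, from_cell = 1L, to_cell = 2L,
                                    x_um = 2, y_um = 2))
  class(ev) <- "transfer_event"
  foci <- data.frame(x_um = c(2.1, 5), y_um = c(2, 5))
  pr <- focus_proximity(ev, foci)
  expect_equal(pr$nearest_focus_distance_um, 0.1)
  expect_true(pr$within_threshold)
  pr2 <- focus_proximity(ev, foci, threshold = 0.05)
  expect_false(pr2$within_threshold)
  expect_error(focus_proximity(ev, foci[0, ]), "non-empty")
})
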