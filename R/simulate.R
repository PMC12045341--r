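#' Simulate a stepwise photobleaching intensity trace
#'
#' Each of `n_fluorophores` independent fluorophores bleaches after an
#' exponential waiting time with rate `cfg$bleach_rate`. The trace value at
#' frame `t` is `background_level + photon_scale * survivors(t)` plus Gaussian
#' noise of standard deviation `cfg$noise_sd`. A fluorophore counts as a
#' survivor at frame `f` while its bleaching time exceeds the frame's start
#' time `(f - 1) * frame_interval`, so the trace starts at the full intensity.
#'
#' @param n_fluorophores Number of fluorophores in the focus (>= 0).
#' @param cfg A [sim_config()].
#' @param n_frames Number of frames to simulate (>= 2).
#' @param roi_id Identifier stored on the returned trace.
#' @return A list with `trace` (a [bleach_trace()]) and `truth`, where
#'   `truth$bleach_frames` gives each fluorophore's first dark frame
#'   (`n_frames + 1` if it outlives the trace) and `truth$survivors` the
#'   noiseless per-frame survivor count.
#' @export
simulate_bleach_trace <- function(n_fluorophores, cfg, n_frames, roi_id = "sim") {
  if (!is.numeric(n_fluorophores) || length(n_fluorophores) != 1L ||
      n_fluorophores < 0 || n_fluorophores != round(n_fluorophores))
    stop("n_fluorophores must be a non-negative integer")
  if (!is.numeric(n_frames) || length(n_frames) != 1L || n_frames < 2 ||
      n_frames != round(n_frames))
    stop("n_frames must be an integer >= 2")
  maybe_seed(cfg)
  n_fluorophores <- as.integer(n_fluorophores)
  n_frames <- as.integer(n_frames)
  t_bleach <- if (n_fluorophores > 0)
    stats::rexp(n_fluorophores, rate = cfg$bleach_rate) else numeric(0)
  frame_start <- (seq_len(n_frames) - 1) * cfg$frame_interval
  survivors <- vapply(frame_start, function(ts) sum(t_bleach > ts), integer(1))
  bleach_frames <- vapply(t_bleach, function(tb) {
    alive <- sum(frame_start < tb)
    as.integer(alive + 1L)
  }, integer(1))
  values <- cfg$background_level + cfg$photon_scale * survivors
  if (cfg$noise_sd > 0)
    values <- values + stats::rnorm(n_frames, 0, cfg$noise_sd)
  list(trace = bleach_trace(values, cfg$frame_interval, roi_id),
       truth = list(bleach_frames = sort(bleach_frames),
                    bleach_times = sort(t_bleach),
                    survivors = survivors,
                    n_fluorophores = n_fluorophores))
}

#' Simulate planar Brownian trajectories
#'
#' Per-frame displacements on each axis are independent Gaussian with variance
#' `2 * true_D * frame_interval`. With a `geometry`, steps that would leave
#' the cell are re-drawn (reflective confinement by rejection).
#'
#' @param true_D Diffusion coefficient (um^2/s, >= 0).
#' @param n_traj Number of trajectories.
#' @param lengths Track lengths in frames: a single integer, a vector of
#'   length `n_traj`, or a function `f(n)` returning `n` integer lengths.
#' @param cfg A [sim_config()].
#' @param geometry Optional [cell_geometry()] (or list of them, treated as a
#'   union) confining the motion. Starting points are sampled uniformly inside.
#' @param start_positions Optional `n_traj x 2` matrix of start points (um);
#'   defaults to uniform sampling inside the geometry, or inside the image
#'   with a margin when no geometry is given.
#' @param start_frames Optional integer vector of first-frame indices
#'   (default all 1).
#' @return A list with `tracks` (data.frame `track_id, frame, x_um, y_um`) and
#'   `truth` (`true_D`, per-track lengths).
#' @export
simulate_trajectories <- function(true_D, n_traj, lengths, cfg,
                                  geometry = NULL,
                                  start_positions = NULL,
                                  start_frames = NULL) {
  stopifnot(is.numeric(true_D), length(true_D) == 1L, true_D >= 0,
            n_traj >= 1, n_traj == round(n_traj))
  maybe_seed(cfg)
  n_traj <- as.integer(n_traj)
  len <- if (is.function(lengths)) as.integer(lengths(n_traj))
         else as.integer(rep_len(lengths, n_traj))
  if (any(len < 1)) stop("track lengths must be >= 1")
  cells <- normalize_geometry(geometry)
  in_region <- function(x, y) {
    if (is.null(cells)) return(rep(TRUE, length(x)))
    ok <- rep(FALSE, length(x))
    for (cell in cells) ok <- ok | points_in_cell(x, y, cell)
    ok
  }
  if (is.null(start_positions)) {
    if (!is.null(cells)) {
      pick <- sample.int(length(cells), n_traj, replace = TRUE)
      start_positions <- matrix(NA_real_, n_traj, 2)
      for (ci in unique(pick)) {
        idx <- which(pick == ci)
        start_positions[idx, ] <- sample_in_cell(length(idx), cells[[ci]])
      }
    } else {
      margin <- 0.8
      xmax <- (cfg$image_shape[2] - 1) * cfg$pixel_size - margin
      ymax <- (cfg$image_shape[1] - 1) * cfg$pixel_size - margin
      start_positions <- cbind(stats::runif(n_traj, margin, xmax),
                               stats::runif(n_traj, margin, ymax))
    }
  }
  if (is.null(start_frames)) start_frames <- rep(1L, n_traj)
  step_sd <- sqrt(2 * true_D * cfg$frame_interval)
  out <- vector("list", n_traj)
  for (i in seq_len(n_traj)) {
    n <- len[i]
    x <- numeric(n); y <- numeric(n)
    x[1] <- start_positions[i, 1]; y[1] <- start_positions[i, 2]
    if (!all(in_region(x[1], y[1]))) stop("start position outside geometry")
    if (n > 1) for (f in 2:n) {
      repeat {
        px <- x[f - 1] + stats::rnorm(1, 0, step_sd)
        py <- y[f - 1] + stats::rnorm(1, 0, step_sd)
        if (in_region(px, py)) break
      }
      x[f] <- px; y[f] <- py
    }
    out[[i]] <- data.frame(track_id = i,
                           frame = start_frames[i] + seq_len(n) - 1L,
                           x_um = x, y_um = y)
  }
  tracks <- do.call(rbind, out)
  rownames(tracks) <- NULL
  list(tracks = tracks,
       truth = list(true_D = true_D, lengths = len))
}

normalize_geometry <- function(geometry) {
  if (is.null(geometry)) return(NULL)
  if (inherits(geometry, "cell_geometry")) return(list(geometry))
  stopifnot(is.list(geometry), all(vapply(geometry, inherits, logical(1),
                                          "cell_geometry")))
  geometry
}

# Gaussian-PSF rendering of one frame's emitters into an image matrix.
# positions in um, intensities are *integrated* counts per emitter.
render_frame <- function(img, xs_um, ys_um, intensities, cfg) {
  a <- cfg$pixel_size; s <- cfg$psf_sigma
  peak_coef <- a^2 / (2 * pi * s^2)
  rad <- ceiling(5 * s / a)
  nr <- nrow(img); nc <- ncol(img)
  for (e in seq_along(xs_um)) {
    cx <- xs_um[e] / a; cy <- ys_um[e] / a   # 0-based pixel coordinates
    c0 <- max(0L, floor(cx) - rad); c1 <- min(nc - 1L, ceiling(cx) + rad)
    r0 <- max(0L, floor(cy) - rad); r1 <- min(nr - 1L, ceiling(cy) + rad)
    if (c0 > c1 || r0 > r1) next
    ex <- exp(-((c0:c1) - cx)^2 * a^2 / (2 * s^2))
    ey <- exp(-((r0:r1) - cy)^2 * a^2 / (2 * s^2))
    img[(r0:r1) + 1L, (c0:c1) + 1L] <-
      img[(r0:r1) + 1L, (c0:c1) + 1L] +
      intensities[e] * peak_coef * (ey %o% ex)
  }
  img
}

#' Render emitters into a synthetic fluorescence movie
#'
#' Each emitter is drawn as a symmetric 2D Gaussian of width `cfg$psf_sigma`
#' sampled at pixel centres, scaled so its pixel values sum to the emitter's
#' intensity, on a constant background with Gaussian read noise. With
#' `cfg$shot_noise = TRUE` the noiseless image is first replaced by a Poisson
#' draw. Emitters outside the field of view are clipped to the border with a
#' warning.
#'
#' @param emitters A data.frame with columns `frame`, `x_um`, `y_um` and
#'   optionally `intensity` (defaults to `cfg$photon_scale`).
#' @param cfg A [sim_config()].
#' @param n_frames Number of frames (default: max emitter frame).
#' @return A numeric array `image_shape[1] x image_shape[2] x n_frames`.
#' @export
render_movie <- function(emitters, cfg, n_frames = NULL) {
  maybe_seed(cfg)
  if (is.null(n_frames))
    n_frames <- if (nrow(emitters) > 0) max(emitters$frame) else 1L
  n_frames <- as.integer(n_frames)
  shp <- cfg$image_shape
  if (is.null(emitters$intensity)) emitters$intensity <- cfg$photon_scale
  xmax <- (shp[2] - 1) * cfg$pixel_size
  ymax <- (shp[1] - 1) * cfg$pixel_size
  if (nrow(emitters) > 0 &&
      (any(emitters$x_um < 0 | emitters$x_um > xmax) ||
       any(emitters$y_um < 0 | emitters$y_um > ymax))) {
    warning("emitter position(s) outside the field of view; clipped")
    emitters$x_um <- pmin(pmax(emitters$x_um, 0), xmax)
    emitters$y_um <- pmin(pmax(emitters$y_um, 0), ymax)
  }
  stack <- array(cfg$background_level, dim = c(shp[1], shp[2], n_frames))
  if (nrow(emitters) > 0) {
    byf <- split(seq_len(nrow(emitters)), emitters$frame)
    for (fn in names(byf)) {
      f <- as.integer(fn)
      if (f < 1 || f > n_frames) next
      idx <- byf[[fn]]
      stack[, , f] <- render_frame(stack[, , f], emitters$x_um[idx],
                                   emitters$y_um[idx],
                                   emitters$intensity[idx], cfg)
    }
  }
  if (cfg$shot_noise) {
    stack[] <- stats::rpois(length(stack), pmax(stack, 0))
  }
  if (cfg$noise_sd > 0)
    stack <- stack + array(stats::rnorm(length(stack), 0, cfg$noise_sd),
                           dim = dim(stack))
  stack
}

#' Render a dual-channel (beam-splitter) movie
#'
#' Emulates a beam splitter writing the two colour channels side by side in a
#' single frame: channel A occupies the left half and channel B the right
#' half, with channel B shifted by a fixed registration `offset` (um, applied
#' within its half-image).
#'
#' @param emitters_a,emitters_b Emitter tables as for [render_movie()], in
#'   shared physical coordinates.
#' @param cfg A [sim_config()]; `image_shape` describes one half-image.
#' @param offset Numeric `c(dx, dy)` registration offset of channel B (um).
#' @param n_frames Number of frames.
#' @return Array `image_shape[1] x (2*image_shape[2]) x n_frames`.
#' @export
render_dual_movie <- function(emitters_a, emitters_b, cfg,
                              offset = c(0, 0), n_frames = NULL) {
  maybe_seed(cfg)
  if (is.null(n_frames))
    n_frames <- max(1L, suppressWarnings(max(c(emitters_a$frame,
                                               emitters_b$frame, 1L))))
  eb <- emitters_b
  if (nrow(eb) > 0) {
    eb$x_um <- eb$x_um + offset[1]
    eb$y_um <- eb$y_um + offset[2]
  }
  cfg_noseed <- cfg; cfg_noseed$rng_seed <- NULL
  left <- render_movie(emitters_a, cfg_noseed, n_frames)
  right <- render_movie(eb, cfg_noseed, n_frames)
  out <- array(NA_real_, dim = c(dim(left)[1], dim(left)[2] * 2L, n_frames))
  out[, seq_len(dim(left)[2]), ] <- left
  out[, dim(left)[2] + seq_len(dim(left)[2]), ] <- right
  out
}

#' Simulate a ground-truthed single-particle tracking movie
#'
#' Lays trajectories out in sequential "activation bursts": a grid of
#' well-separated start positions receives a cohort of particles, the cohort
#' is imaged until its longest track ends, then (after a blank frame) the next
#' cohort starts. This emulates sparse photoactivation while keeping particle
#' density low enough that nearest-neighbour linking is unambiguous.
#'
#' @param true_D Ground-truth diffusion coefficient (um^2/s).
#' @param n_traj Number of trajectories.
#' @param cfg A [sim_config()].
#' @param lengths Length sampler passed to [simulate_trajectories()]
#'   (default: uniform on 4..12 frames).
#' @param grid_spacing_um Spacing of the activation grid (um).
#' @param margin_um Margin kept free at the field edge (um).
#' @return A list with `stack` (rendered movie), `tracks` (ground-truth
#'   positions), and `truth`.
#' @export
simulate_tracking_movie <- function(true_D, n_traj, cfg,
                                    lengths = function(n) sample(4:12, n, replace = TRUE),
                                    grid_spacing_um = 2.56,
                                    margin_um = 1.0) {
  maybe_seed(cfg)
  shp <- cfg$image_shape
  xmax <- (shp[2] - 1) * cfg$pixel_size
  ymax <- (shp[1] - 1) * cfg$pixel_size
  gx <- seq(margin_um, xmax - margin_um, by = grid_spacing_um)
  gy <- seq(margin_um, ymax - margin_um, by = grid_spacing_um)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  per_burst <- nrow(grid)
  len <- if (is.function(lengths)) as.integer(lengths(n_traj))
         else as.integer(rep_len(lengths, n_traj))
  max_len <- max(len)
  burst_of <- (seq_len(n_traj) - 1L) %/% per_burst
  slot_of <- (seq_len(n_traj) - 1L) %% per_burst
  # jitter start positions within +-0.3 um of the grid node
  starts <- grid[slot_of + 1L, , drop = FALSE] +
    matrix(stats::runif(2L * n_traj, -0.3, 0.3), ncol = 2)
  start_frames <- burst_of * (max_len + 1L) + 1L
  cfg_noseed <- cfg; cfg_noseed$rng_seed <- NULL
  sim <- simulate_trajectories(true_D, n_traj, len, cfg_noseed,
                               start_positions = starts,
                               start_frames = start_frames)
  n_frames <- max(sim$tracks$frame)
  stack <- render_movie(sim$tracks, cfg_noseed, n_frames)
  list(stack = stack, tracks = sim$tracks,
       truth = c(sim$truth, list(n_frames = n_frames)))
}

#' Simulate dual-channel two-colour foci with 1:1 composition
#'
#' Places `n_foci` stationary foci in the field; each focus holds `counts[i]`
#' fluorophores in channel A and (for the default exact 1:1 composition) the
#' same number in channel B. Channel B coordinates are the channel A
#' coordinates plus the registration `offset` and a small residual jitter.
#' Bleaching traces for both channels are simulated independently with
#' [simulate_bleach_trace()].
#'
#' @param counts Integer vector of per-focus fluorophore numbers (channel A);
#'   channel B uses `counts_b` (default identical — exact 1:1).
#' @param cfg A [sim_config()] (use `frame_interval = 0.2` for the 5-Hz
#'   dual-channel acquisitions).
#' @param n_frames Trace length in frames.
#' @param offset Registration offset `c(dx, dy)` of channel B (um).
#' @param jitter_sd Residual channel-mapping error (um, default 0.02).
#' @param counts_b Optional channel-B counts.
#' @return List with `foci_a`, `foci_b` (data.frames `roi_id, x_um, y_um`),
#'   `traces_a`, `traces_b` (lists of [bleach_trace()]), `offset`, and `truth`
#'   (the per-channel counts).
#' @export
simulate_dual_channel_foci <- function(counts, cfg, n_frames = 250,
                                       offset = c(0.2, 0),
                                       jitter_sd = 0.02,
                                       counts_b = counts) {
  maybe_seed(cfg)
  n <- length(counts)
  stopifnot(n >= 1, all(counts >= 1), all(counts_b >= 1),
            length(counts_b) == n)
  shp <- cfg$image_shape
  margin <- 0.8
  xs <- stats::runif(n, margin, (shp[2] - 1) * cfg$pixel_size - margin)
  ys <- stats::runif(n, margin, (shp[1] - 1) * cfg$pixel_size - margin)
  foci_a <- data.frame(roi_id = seq_len(n), x_um = xs, y_um = ys)
  foci_b <- data.frame(roi_id = seq_len(n),
                       x_um = xs + offset[1] + stats::rnorm(n, 0, jitter_sd),
                       y_um = ys + offset[2] + stats::rnorm(n, 0, jitter_sd))
  cfg_noseed <- cfg; cfg_noseed$rng_seed <- NULL
  traces_a <- lapply(seq_len(n), function(i)
    simulate_bleach_trace(counts[i], cfg_noseed, n_frames,
                          roi_id = i)$trace)
  traces_b <- lapply(seq_len(n), function(i)
    simulate_bleach_trace(counts_b[i], cfg_noseed, n_frames,
                          roi_id = i)$trace)
  list(foci_a = foci_a, foci_b = foci_b,
       traces_a = traces_a, traces_b = traces_b, offset = offset,
       truth = list(count_a = as.integer(counts),
                    count_b = as.integer(counts_b)))
}

#' Simulate an intercellular transfer (OME) scenario
#'
#' Generates trajectories that cross the boundaries between adjacent rod
#' cells according to per-track crossing plans, together with the rendered
#' movie, the rasterized cell masks, stationary boundary foci, and full ground
#' truth. Each track diffuses with reflective confinement inside its current
#' cell; a planned crossing is realised as a genuine first passage — after a
#' minimum dwell, the first Brownian proposal that lands inside the next
#' planned cell is accepted — so crossing steps follow the same displacement
#' statistics as every other step.
#'
#' @param cfg A [sim_config()].
#' @param cells List of [cell_geometry()] (pairwise adjacency is implied by
#'   the plans; plans referencing unknown cell ids are an error).
#' @param plans List of integer vectors of cell ids, one per track, e.g.
#'   `c(1, 2, 1)` for an out-and-back transfer.
#' @param true_D Ground-truth diffusion coefficient (um^2/s).
#' @param dwell_min Minimum frames spent in a cell before the next planned
#'   crossing may occur.
#' @param post_frames Frames recorded after the final planned crossing.
#' @param max_frames Per-track frame budget; a track whose plan has not
#'   completed by then is re-drawn.
#' @param foci Optional data.frame `x_um, y_um` of stationary focus positions;
#'   default: two foci placed on the first shared boundary near the cell tips.
#' @param start_window_um Tracks start within this distance (along the cell
#'   axis) of the field centre, keeping crossings away from tip foci.
#' @param render If `TRUE` (default) also render the particle-channel movie.
#' @param gap_frames Blank frames inserted between consecutive tracks in the
#'   rendered movie.
#' @return List with `stack` (or `NULL`), `masks` (label matrix), `cells`,
#'   `foci`, `tracks` (true positions), and `truth` holding per-frame cell
#'   labels, planned crossings (`track_id, frame, from_cell, to_cell,
#'   x_um, y_um`), and plans.
#' @export
simulate_ome_scenario <- function(cfg, cells, plans, true_D = diffusion_presets()[["transfer"]],
                                  dwell_min = 8L, post_frames = 10L,
                                  max_frames = 300L, foci = NULL,
                                  start_window_um = 0.8,
                                  render = TRUE, gap_frames = 2L) {
  maybe_seed(cfg)
  ids <- vapply(cells, function(c) c$cell_id, integer(1))
  for (p in plans)
    if (!all(p %in% ids)) stop("crossing plan references unknown cell id(s)")
  cell_by_id <- stats::setNames(cells, ids)
  step_sd <- sqrt(2 * true_D * cfg$frame_interval)
  all_tracks <- list(); all_cross <- list(); all_labels <- list()
  next_start_frame <- 1L
  for (ti in seq_along(plans)) {
    plan <- as.integer(plans[[ti]])
    repeat {
      res <- simulate_planned_track(plan, cell_by_id, step_sd, dwell_min,
                                    post_frames, max_frames,
                                    start_window_um)
      if (!is.null(res)) break
    }
    n <- length(res$x)
    frames <- next_start_frame + seq_len(n) - 1L
    all_tracks[[ti]] <- data.frame(track_id = ti, frame = frames,
                                   x_um = res$x, y_um = res$y)
    all_labels[[ti]] <- data.frame(track_id = ti, frame = frames,
                                   cell_id = res$cell)
    if (nrow(res$crossings) > 0) {
      res$crossings$track_id <- ti
      res$crossings$frame <- next_start_frame + res$crossings$frame - 1L
      all_cross[[ti]] <- res$crossings
    }
    next_start_frame <- next_start_frame + n + gap_frames
  }
  tracks <- do.call(rbind, all_tracks); rownames(tracks) <- NULL
  labels <- do.call(rbind, all_labels); rownames(labels) <- NULL
  crossings <- if (length(all_cross))
    do.call(rbind, all_cross) else
    data.frame(frame = integer(0), from_cell = integer(0),
               to_cell = integer(0), x_um = numeric(0), y_um = numeric(0),
               track_id = integer(0))
  rownames(crossings) <- NULL
  masks <- rasterize_cells(cells, cfg)
  if (is.null(foci)) foci <- default_boundary_foci(cells)
  stack <- NULL
  if (render) {
    cfg_noseed <- cfg; cfg_noseed$rng_seed <- NULL
    stack <- render_movie(tracks, cfg_noseed, max(tracks$frame))
  }
  list(stack = stack, masks = masks, cells = cells, foci = foci,
       tracks = tracks,
       truth = list(true_D = true_D, labels = labels,
                    crossings = crossings, plans = plans))
}

# One planned track; returns NULL if the plan did not complete in max_frames.
simulate_planned_track <- function(plan, cell_by_id, step_sd, dwell_min,
                                   post_frames, max_frames, start_window_um) {
  cur <- 1L
  cell <- cell_by_id[[as.character(plan[cur])]]
  # start near the field centre along the cell axis
  repeat {
    p <- sample_in_cell(1L, cell)
    ca <- cos(cell$angle); sa <- sin(cell$angle)
    u <- (p[1] - cell$center[1]) * ca + (p[2] - cell$center[2]) * sa
    if (abs(u) <= start_window_um) break
  }
  x <- p[1]; y <- p[2]
  cell_seq <- plan[cur]
  cross <- list()
  dwell <- 1L
  for (f in 2:max_frames) {
    px <- py <- NA_real_
    crossed <- FALSE
    next_cell <- if (cur < length(plan))
      cell_by_id[[as.character(plan[cur + 1L])]] else NULL
    for (try in 1:200) {
      cx <- x[f - 1] + stats::rnorm(1, 0, step_sd)
      cy <- y[f - 1] + stats::rnorm(1, 0, step_sd)
      if (!is.null(next_cell) && dwell >= dwell_min &&
          points_in_cell(cx, cy, next_cell)) {
        px <- cx; py <- cy; crossed <- TRUE; break
      }
      if (points_in_cell(cx, cy, cell)) { px <- cx; py <- cy; break }
    }
    if (is.na(px)) { px <- x[f - 1]; py <- y[f - 1] }  # degenerate; stay put
    x[f] <- px; y[f] <- py
    if (crossed) {
      cross[[length(cross) + 1L]] <- data.frame(
        frame = f, from_cell = plan[cur], to_cell = plan[cur + 1L],
        x_um = (x[f - 1] + px) / 2, y_um = (y[f - 1] + py) / 2)
      cur <- cur + 1L
      cell <- cell_by_id[[as.character(plan[cur])]]
      dwell <- 1L
    } else dwell <- dwell + 1L
    cell_seq[f] <- plan[cur]
    if (cur == length(plan) && dwell >= max(dwell_min, post_frames)) {
      if (cur > 1L || f >= 2L * dwell_min) break
    }
  }
  if (cur < length(plan)) return(NULL)
  crossings <- if (length(cross)) do.call(rbind, cross) else
    data.frame(frame = integer(0), from_cell = integer(0),
               to_cell = integer(0), x_um = numeric(0), y_um = numeric(0))
  list(x = x, y = y, cell = cell_seq, crossings = crossings)
}

# Two foci on the boundary between the first two cells, near the cell tips
# (far from the field centre where the planned crossings happen).
default_boundary_foci <- function(cells, tip_offset_um = 0.3) {
  a <- cells[[1]]; b <- cells[[2]]
  mid <- (a$center + b$center) / 2
  ca <- cos(a$angle); sa <- sin(a$angle)
  tip <- a$length / 2 - tip_offset_um
  data.frame(x_um = c(mid[1] - tip * ca, mid[1] + tip * ca),
             y_um = c(mid[2] - tip * sa, mid[2] + tip * sa))
}

#' Simulate a cross-membrane density line profile
#'
#' Builds a 1-D profile as a sum of Gaussian-shaped density peaks on a flat
#' baseline plus Gaussian noise, the synthetic analogue of a line profile
#' drawn across one or two membranes in a cryo-EM micrograph.
#'
#' @param peak_positions_nm Peak centres (nm); must be separated by more than
#'   twice the corresponding widths.
#' @param peak_widths_nm Gaussian sigma per peak (nm), recycled.
#' @param amplitudes Peak amplitudes (density units), recycled.
#' @param noise_sd Additive Gaussian noise on the profile values.
#' @param sampling_step_nm Spacing of the sampled positions (nm).
#' @param pad_nm Extra range beyond the outermost peaks.
#' @param baseline Constant baseline value.
#' @param profile_id Identifier stored on the profile.
#' @return A [density_profile()] with attribute `truth` holding the centres.
#' @export
simulate_density_profile <- function(peak_positions_nm,
                                     peak_widths_nm = 2.5,
                                     amplitudes = 1,
                                     noise_sd = 0,
                                     sampling_step_nm = 0.5,
                                     pad_nm = 10,
                                     baseline = 0,
                                     profile_id = "sim") {
  k <- length(peak_positions_nm)
  stopifnot(k >= 1)
  w <- rep_len(peak_widths_nm, k)
  a <- rep_len(amplitudes, k)
  if (k > 1) {
    ord <- order(peak_positions_nm)
    pos <- peak_positions_nm[ord]; ws <- w[ord]
    sep <- diff(pos)
    lim <- 2 * pmax(ws[-k], ws[-1])
    if (any(sep <= lim))
      stop("peaks overlap: separations must exceed twice the peak width")
  }
  xs <- seq(min(peak_positions_nm) - pad_nm,
            max(peak_positions_nm) + pad_nm, by = sampling_step_nm)
  vals <- rep(baseline, length(xs))
  for (i in seq_len(k))
    vals <- vals + a[i] * exp(-(xs - peak_positions_nm[i])^2 / (2 * w[i]^2))
  if (noise_sd > 0) vals <- vals + stats::rnorm(length(xs), 0, noise_sd)
  prof <- density_profile(xs, vals, profile_id)
  attr(prof, "truth") <- list(peak_centers = sort(peak_positions_nm))
  prof
}
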