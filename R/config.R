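#' Simulation / acquisition configuration
#'
#' Bundles the camera and illumination parameters shared by the synthetic-data
#' generator and the analysis stages. Units follow microscopy conventions:
#' lengths in micrometres, times in seconds, intensities in camera counts.
#'
#' `photon_scale` is the *integrated* intensity contributed by one fluorophore
#' per frame. At the trace level this is the unit bleaching step; at the image
#' level an emitter of `k` live fluorophores is rendered as a 2D Gaussian whose
#' pixel values sum to `k * photon_scale` (peak amplitude
#' `photon_scale * pixel_size^2 / (2 * pi * psf_sigma^2)`).
#'
#' @param pixel_size Effective camera pixel size in the sample plane (um).
#' @param frame_interval Time between frames (s). 0.015 corresponds to the
#'   67-Hz tracking acquisitions, 0.200 to the 5-Hz dual-channel bleaching.
#' @param psf_sigma Standard deviation of the Gaussian point-spread function
#'   (um).
#' @param image_shape Integer `c(rows, cols)` of the rendered field.
#' @param photon_scale Integrated counts per live fluorophore per frame.
#' @param background_level Constant background offset (counts).
#' @param noise_sd Gaussian read-noise standard deviation per pixel (counts);
#'   for directly simulated traces it is the per-frame trace noise.
#' @param bleach_rate Photobleaching rate per fluorophore (1/s).
#' @param shot_noise If `TRUE`, add Poisson shot noise on the emitter signal
#'   in addition to Gaussian read noise. Off by default so that noiseless
#'   closed-form checks stay exact.
#' @param laser_power_kW_cm2 Illumination power density; stored as inert
#'   metadata only, nothing downstream consumes it.
#' @param rng_seed Optional integer seed; when set, generator functions that
#'   receive this config reseed deterministically so identical configs give
#'   bit-identical output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(pixel_size = 0.160,
                       frame_interval = 0.015,
                       psf_sigma = 0.160,
                       image_shape = c(64L, 64L),
                       photon_scale = 1260,
                       background_level = 100,
                       noise_sd = 38,
                       bleach_rate = 2,
                       shot_noise = FALSE,
                       laser_power_kW_cm2 = NA_real_,
                       rng_seed = NULL) {
  stopifnot(
    is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0,
    is.numeric(frame_interval), length(frame_interval) == 1L, frame_interval > 0,
    is.numeric(psf_sigma), length(psf_sigma) == 1L, psf_sigma > 0,
    length(image_shape) == 2L, all(image_shape >= 1),
    is.numeric(photon_scale), photon_scale > 0,
    is.numeric(noise_sd), noise_sd >= 0,
    is.numeric(bleach_rate), bleach_rate > 0,
    is.logical(shot_noise)
  )
  if (!is.null(rng_seed)) {
    stopifnot(is.numeric(rng_seed), length(rng_seed) == 1L,
              rng_seed == round(rng_seed))
    rng_seed <- as.integer(rng_seed)
  }
  structure(
    list(pixel_size = pixel_size,
         frame_interval = frame_interval,
         psf_sigma = psf_sigma,
         image_shape = as.integer(image_shape),
         photon_scale = photon_scale,
         background_level = background_level,
         noise_sd = noise_sd,
         bleach_rate = bleach_rate,
         shot_noise = shot_noise,
         laser_power_kW_cm2 = laser_power_kW_cm2,
         rng_seed = rng_seed),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      sprintf("%g um/px, %g ms/frame, PSF sigma %g um,", x$pixel_size,
              1000 * x$frame_interval, x$psf_sigma),
      sprintf("field %dx%d px", x$image_shape[1], x$image_shape[2]), "\n")
  cat(sprintf("  photon_scale %g, background %g, noise_sd %g, bleach_rate %g/s\n",
              x$photon_scale, x$background_level, x$noise_sd, x$bleach_rate))
  invisible(x)
}

# Seed the RNG from a config if it carries a seed; no-op otherwise.
maybe_seed <- function(cfg) {
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  invisible(NULL)
}

#' Diffusion presets
#'
#' Ground-truth diffusion coefficients used as simulation presets for the
#' outer-membrane lipoprotein reporter, its inner-membrane control, and
#' particles undergoing intercellular transfer. Values are the population
#' coefficients the tracking pipeline is expected to recover (um^2/s).
#'
#' @return Named numeric vector with elements `om`, `im`, `transfer`.
#' @export
diffusion_presets <- function() {
  c(om = 0.19, im = 0.22, transfer = 0.21)
}

#' Rod-shaped cell geometry (spherocylinder)
#'
#' A cell is modelled as a 2D spherocylinder: a rectangle of length `length`
#' capped by half-discs, total tip-to-tip extent `length + width`. Positions
#' are in micrometres in image coordinates (origin at the centre of the
#' top-left pixel, x along columns, y along rows).
#'
#' @param cell_id Positive integer label.
#' @param center Numeric `c(x, y)` centre (um).
#' @param angle Axis angle in radians (0 = along x).
#' @param length Axis length between the cap centres (um).
#' @param width Cell width / cap diameter (um).
#' @return An object of class `cell_geometry`.
#' @export
cell_geometry <- function(cell_id, center, angle = 0, length = 5, width = 0.7) {
  stopifnot(cell_id >= 1, cell_id == round(cell_id),
            base::length(center) == 2L, length > 0, width > 0)
  structure(list(cell_id = as.integer(cell_id), center = as.numeric(center),
                 angle = angle, length = length, width = width),
            class = "cell_geometry")
}

# Signed distance helper: TRUE for points inside the spherocylinder.
points_in_cell <- function(x, y, cell) {
  ca <- cos(cell$angle); sa <- sin(cell$angle)
  dx <- x - cell$center[1]; dy <- y - cell$center[2]
  u <- dx * ca + dy * sa          # along axis
  v <- -dx * sa + dy * ca         # across axis
  half <- cell$length / 2
  uc <- pmin(pmax(u, -half), half)
  (u - uc)^2 + v^2 <= (cell$width / 2)^2
}

# Uniform sample of n points inside a spherocylinder (rejection from the
# bounding box in cell frame).
sample_in_cell <- function(n, cell) {
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  halfL <- cell$length / 2 + cell$width / 2
  halfW <- cell$width / 2
  while (got < n) {
    m <- max(16L, 2L * (n - got))
    u <- stats::runif(m, -halfL, halfL)
    v <- stats::runif(m, -halfW, halfW)
    ca <- cos(cell$angle); sa <- sin(cell$angle)
    x <- cell$center[1] + u * ca - v * sa
    y <- cell$center[2] + u * sa + v * ca
    ok <- points_in_cell(x, y, cell)
    k <- min(sum(ok), n - got)
    if (k > 0) {
      idx <- which(ok)[seq_len(k)]
      out[got + seq_len(k), ] <- cbind(x[idx], y[idx])
      got <- got + k
    }
  }
  out
}

#' Rasterize cell geometries into a label image
#'
#' @param cells List of [cell_geometry()] objects with disjoint footprints.
#' @param cfg A [sim_config()]; supplies pixel size and image shape.
#' @return Integer matrix (`image_shape`) with 0 = background and the
#'   `cell_id` of the covering cell elsewhere. Overlapping cells are an error.
#' @export
rasterize_cells <- function(cells, cfg) {
  shp <- cfg$image_shape
  lab <- matrix(0L, shp[1], shp[2])
  xs <- (seq_len(shp[2]) - 1) * cfg$pixel_size
  ys <- (seq_len(shp[1]) - 1) * cfg$pixel_size
  xg <- matrix(xs, shp[1], shp[2], byrow = TRUE)
  yg <- matrix(ys, shp[1], shp[2])
  for (cell in cells) {
    inside <- points_in_cell(as.vector(xg), as.vector(yg), cell)
    if (any(lab[inside] != 0L))
      stop("cell masks overlap; cells must be disjoint")
    lab[matrix(inside, shp[1], shp[2])] <- cell$cell_id
  }
  lab
}
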