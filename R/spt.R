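# Separable Gaussian smoothing of a matrix (reflected edges).
gauss_smooth <- function(img, sigma_px) {
  half <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-half):half)^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  pad_filter <- function(m) {
    # pad rows by reflection, filter each column, crop
    top <- m[rev(seq_len(half)), , drop = FALSE]
    bot <- m[nrow(m) - seq_len(half) + 1L, , drop = FALSE]
    mp <- rbind(top, m, bot)
    f <- stats::filter(mp, k, sides = 2)
    f[half + seq_len(nrow(m)), , drop = FALSE]
  }
  t(pad_filter(t(pad_filter(img))))
}

# Local maxima of a matrix (8-neighbourhood, strict against >= on one side to
# break plateau ties deterministically). Returns cbind(row, col), 1-based.
local_maxima <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 3 || nc < 3) return(matrix(integer(0), 0, 2))
  c_ <- img[2:(nr - 1), 2:(nc - 1)]
  ok <- c_ > img[1:(nr - 2), 2:(nc - 1)] & c_ >= img[3:nr, 2:(nc - 1)] &
        c_ > img[2:(nr - 1), 1:(nc - 2)] & c_ >= img[2:(nr - 1), 3:nc] &
        c_ > img[1:(nr - 2), 1:(nc - 2)] & c_ >= img[3:nr, 3:nc] &
        c_ > img[1:(nr - 2), 3:nc] & c_ >= img[3:nr, 1:(nc - 2)]
  idx <- which(ok, arr.ind = TRUE)
  idx + 1L
}

# Levenberg-Marquardt fit of A*G(x0,y0,s) + b over a square window.
# zs: window values; xs, ys: 0-based pixel coordinate offsets (vectors over
# the window, same length as zs). Returns named vector or NULL.
fit_gaussian_spot <- function(zs, xs, ys, init, half, sigma_bounds) {
  resid_fn <- function(p)
    p[1] * exp(-((xs - p[2])^2 + (ys - p[3])^2) / (2 * p[4]^2)) + p[5] - zs
  fit <- tryCatch(
    minpack.lm::nls.lm(par = init, fn = resid_fn,
                       lower = c(0, init[2] - half, init[3] - half,
                                 sigma_bounds[1] * 0.5, -Inf),
                       upper = c(Inf, init[2] + half, init[3] + half,
                                 sigma_bounds[2] * 2, Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 60)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- unname(fit$par)
  c(amplitude = p[1], x0 = p[2], y0 = p[3], sigma = p[4], background = p[5],
    rss = sum(fit$fvec^2))
}

#' Localize particles in one frame by 2D Gaussian fitting
#'
#' Candidate spots are local maxima of a Gaussian-smoothed copy of the frame
#' whose smoothed, background-subtracted amplitude exceeds `threshold`
#' (background taken as the median of the smoothed frame; with
#' `threshold = NULL` it defaults to 5 robust standard deviations of the
#' smoothed frame). Each candidate is refined by nonlinear least squares of
#' `amplitude * G(x0, y0, sigma) + background` over a `window x window`
#' region. Fits that fail, wander outside the window, or return a width
#' outside `sigma_bounds` times the nominal PSF sigma (defocused / merged
#' spots) are discarded.
#'
#' @param img Numeric matrix (one frame).
#' @param cfg A [sim_config()] supplying pixel size and nominal PSF sigma.
#' @param threshold Detection threshold on the smoothed, background-subtracted
#'   amplitude (counts); `NULL` for automatic.
#' @param window Odd fit-window size in pixels (>= 5).
#' @param sigma_bounds Acceptable fitted sigma as multiples of the nominal
#'   PSF sigma; default `c(0.4, 2)` (the upper bound rejects blurry,
#'   out-of-focus objects).
#' @param frame Frame index stored on the detections.
#' @return data.frame `frame, x_um, y_um, amplitude, sigma, background,
#'   fit_rss` (possibly 0 rows).
#' @export
detect_particles <- function(img, cfg, threshold = NULL, window = 9L,
                             sigma_bounds = c(0.4, 2), frame = 1L) {
  stopifnot(window >= 5, window %% 2 == 1)
  half <- (window - 1L) %/% 2L
  s_px <- cfg$psf_sigma / cfg$pixel_size
  sm <- gauss_smooth(img, s_px)
  bg_sm <- stats::median(sm)
  if (is.null(threshold))
    threshold <- 5 * stats::mad(sm)
  cand <- local_maxima(sm)
  if (nrow(cand) > 0)
    cand <- cand[sm[cand] - bg_sm >= threshold, , drop = FALSE]
  out <- list()
  nr <- nrow(img); nc <- ncol(img)
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c_ <- cand[i, 2]
    r0 <- max(1L, r - half); r1 <- min(nr, r + half)
    c0 <- max(1L, c_ - half); c1 <- min(nc, c_ + half)
    if ((r1 - r0 + 1) < window - 1 || (c1 - c0 + 1) < window - 1) next
    sub <- img[r0:r1, c0:c1]
    xs <- rep((c0:c1) - 1L, each = r1 - r0 + 1)
    ys <- rep((r0:r1) - 1L, times = c1 - c0 + 1)
    bg0 <- stats::median(sub)
    init <- c(max(sub) - bg0, c_ - 1, r - 1, s_px, bg0)
    p <- fit_gaussian_spot(as.vector(sub), xs, ys, init, half,
                           sigma_bounds * s_px)
    if (is.null(p)) next
    if (p["sigma"] < sigma_bounds[1] * s_px ||
        p["sigma"] > sigma_bounds[2] * s_px) next
    if (abs(p["x0"] - (c_ - 1)) > half || abs(p["y0"] - (r - 1)) > half) next
    out[[length(out) + 1L]] <- data.frame(
      frame = frame,
      x_um = unname(p["x0"]) * cfg$pixel_size,
      y_um = unname(p["y0"]) * cfg$pixel_size,
      amplitude = unname(p["amplitude"]),
      sigma = unname(p["sigma"]) * cfg$pixel_size,
      background = unname(p["background"]),
      fit_rss = unname(p["rss"]))
  }
  if (!length(out))
    return(data.frame(frame = integer(0), x_um = numeric(0),
                      y_um = numeric(0), amplitude = numeric(0),
                      sigma = numeric(0), background = numeric(0),
                      fit_rss = numeric(0)))
  res <- do.call(rbind, out)
  # de-duplicate fits that converged to the same spot
  if (nrow(res) > 1) {
    ord <- order(res$fit_rss)
    keep <- logical(nrow(res))
    for (i in ord) {
      if (any(keep & (res$x_um - res$x_um[i])^2 +
                     (res$y_um - res$y_um[i])^2 <
                     (0.5 * cfg$pixel_size)^2)) next
      keep[i] <- TRUE
    }
    res <- res[keep, , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Localize particles in every frame of a stack
#'
#' @param stack Array `rows x cols x frames`.
#' @inheritParams detect_particles
#' @return Combined detections data.frame (see [detect_particles()]).
#' @export
detect_stack <- function(stack, cfg, threshold = NULL, window = 9L,
                         sigma_bounds = c(0.4, 2)) {
  n_frames <- dim(stack)[3]
  res <- lapply(seq_len(n_frames), function(f)
    detect_particles(stack[, , f], cfg, threshold = threshold,
                     window = window, sigma_bounds = sigma_bounds,
                     frame = f))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Link detections into trajectories
#'
#' Frame-to-frame greedy nearest-neighbour linking: for each consecutive
#' frame pair, candidate links closer than `max_disp` are assigned in order
#' of ascending distance; unmatched detections start new tracks. There is no
#' gap closing, so every trajectory covers strictly consecutive frames.
#'
#' @param detections data.frame with columns `frame, x_um, y_um` (other
#'   columns are carried along).
#' @param max_disp Linking gate (um); default 0.320 um (two pixels at 160 nm).
#' @return The detections with a `track_id` column, ordered by track and
#'   frame.
#' @export
link <- function(detections, max_disp = 0.320) {
  if (nrow(detections) == 0) {
    detections$track_id <- integer(0)
    return(detections)
  }
  det <- detections[order(detections$frame), , drop = FALSE]
  det$track_id <- NA_integer_
  frames <- sort(unique(det$frame))
  next_id <- 1L
  idx_prev <- which(det$frame == frames[1])
  det$track_id[idx_prev] <- seq_along(idx_prev)
  next_id <- length(idx_prev) + 1L
  for (fi in seq_along(frames)[-1]) {
    idx_cur <- which(det$frame == frames[fi])
    consecutive <- frames[fi] == frames[fi - 1] + 1L
    if (consecutive && length(idx_prev) > 0) {
      dx <- outer(det$x_um[idx_prev], det$x_um[idx_cur], "-")
      dy <- outer(det$y_um[idx_prev], det$y_um[idx_cur], "-")
      dist <- sqrt(dx^2 + dy^2)
      cand <- which(dist <= max_disp, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        cand <- cand[order(dist[cand]), , drop = FALSE]
        used_p <- logical(length(idx_prev))
        used_c <- logical(length(idx_cur))
        for (k in seq_len(nrow(cand))) {
          p <- cand[k, 1]; cc <- cand[k, 2]
          if (used_p[p] || used_c[cc]) next
          used_p[p] <- TRUE; used_c[cc] <- TRUE
          det$track_id[idx_cur[cc]] <- det$track_id[idx_prev[p]]
        }
      }
    }
    new <- idx_cur[is.na(det$track_id[idx_cur])]
    if (length(new) > 0) {
      det$track_id[new] <- next_id + seq_along(new) - 1L
      next_id <- next_id + length(new)
    }
    idx_prev <- idx_cur
  }
  det <- det[order(det$track_id, det$frame), , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Filter trajectories by length
#'
#' Keeps tracks whose length in frames lies in `[min_len, max_len]`,
#' mirroring the in-focus window of the tracking experiments. Longer tracks
#' are dropped by default or truncated to `max_len` with
#' `too_long = "truncate"`.
#'
#' @param tracks data.frame with `track_id, frame` columns.
#' @param min_len,max_len Length bounds in frames (defaults 4 and 12).
#' @param too_long `"drop"` (default) or `"truncate"`.
#' @return Filtered tracks data.frame.
#' @export
filter_trajectories <- function(tracks, min_len = 4L, max_len = 12L,
                                too_long = c("drop", "truncate")) {
  too_long <- match.arg(too_long)
  if (nrow(tracks) == 0) return(tracks)
  lens <- table(tracks$track_id)
  if (too_long == "truncate") {
    keep_ids <- names(lens)[lens >= min_len]
    out <- tracks[tracks$track_id %in% as_same_type(keep_ids, tracks$track_id), ,
                  drop = FALSE]
    out <- do.call(rbind, lapply(split(out, out$track_id), function(tr) {
      tr <- tr[order(tr$frame), , drop = FALSE]
      utils::head(tr, max_len)
    }))
  } else {
    keep_ids <- names(lens)[lens >= min_len & lens <= max_len]
    out <- tracks[tracks$track_id %in% as_same_type(keep_ids, tracks$track_id), ,
                  drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

as_same_type <- function(x, template) {
  if (is.numeric(template)) as.numeric(x) else x
}

# Per-track sum of squared displacements and pair counts for lags 1..max_lag.
# Returns list(ss = n_tracks x max_lag, np = n_tracks x max_lag).
track_lag_sums <- function(tracks, max_lag) {
  by_track <- split(tracks[c("frame", "x_um", "y_um")], tracks$track_id)
  nt <- length(by_track)
  ss <- matrix(0, nt, max_lag)
  np <- matrix(0L, nt, max_lag)
  for (i in seq_len(nt)) {
    tr <- by_track[[i]]
    ord <- order(tr$frame)
    x <- tr$x_um[ord]; y <- tr$y_um[ord]; f <- tr$frame[ord]
    if (any(diff(f) != 1L))
      stop("trajectories must cover strictly consecutive frames")
    n <- length(x)
    for (k in seq_len(min(max_lag, n - 1))) {
      d2 <- (x[(1 + k):n] - x[1:(n - k)])^2 + (y[(1 + k):n] - y[1:(n - k)])^2
      ss[i, k] <- sum(d2)
      np[i, k] <- n - k
    }
  }
  list(ss = ss, np = np)
}

#' Time-and-ensemble averaged mean squared displacement
#'
#' `MSD(k * dt)` is the mean of `|r(t + k) - r(t)|^2` over all tracks and all
#' valid start frames, i.e. displacement pairs are pooled across the whole
#' ensemble before averaging.
#'
#' @param tracks data.frame `track_id, frame, x_um, y_um` with consecutive
#'   frames within each track.
#' @param max_lag Largest lag in frames; at least one track must be longer
#'   than `max_lag`.
#' @param frame_interval Frame spacing (s).
#' @return An `msd_curve` data.frame with columns `lag_s, msd_um2, n_pairs`
#'   and attribute `frame_interval`.
#' @export
compute_msd <- function(tracks, max_lag = 4L, frame_interval = 0.015) {
  if (nrow(tracks) == 0) stop("no tracks")
  sums <- track_lag_sums(tracks, max_lag)
  np <- colSums(sums$np)
  if (np[max_lag] == 0)
    stop("max_lag exceeds every track length")
  msd <- colSums(sums$ss) / pmax(np, 1L)
  msd[np == 0] <- NA_real_
  out <- data.frame(lag_s = seq_len(max_lag) * frame_interval,
                    msd_um2 = msd, n_pairs = as.integer(np))
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Diffusion coefficient from an MSD curve
#'
#' Fits `MSD = 4 * D * dt` by unweighted least squares through the origin
#' over the first `fit_lags` points; `D = slope / 4`. With
#' `intercept = TRUE` an ordinary line is fitted instead (the intercept
#' absorbing static localization error) and D taken from its slope.
#' Negative fitted values are clamped to zero, with the raw value retained.
#'
#' @param msd An `msd_curve` from [compute_msd()].
#' @param fit_lags Number of leading MSD points used (default 4).
#' @param intercept Fit a free intercept instead of forcing the origin.
#' @return A `diffusion_estimate` list: `D`, `D_raw`, `bootstrap_sd` (`NA`
#'   until [bootstrap_D()]), `n_trajectories` (`NA` here), `fit_lags`,
#'   `intercept_um2`.
#' @export
estimate_D <- function(msd, fit_lags = 4L, intercept = FALSE) {
  if (nrow(msd) < fit_lags)
    stop(sprintf("MSD curve has %d points; %d required", nrow(msd), fit_lags))
  lag <- msd$lag_s[seq_len(fit_lags)]
  y <- msd$msd_um2[seq_len(fit_lags)]
  if (anyNA(y)) stop("MSD undefined at a fitted lag")
  if (intercept) {
    co <- stats::coef(stats::lm(y ~ lag))
    slope <- co[[2]]; b0 <- co[[1]]
  } else {
    slope <- sum(lag * y) / sum(lag^2)
    b0 <- 0
  }
  D_raw <- slope / 4
  structure(list(D = max(0, D_raw), D_raw = D_raw,
                 bootstrap_sd = NA_real_,
                 n_trajectories = NA_integer_,
                 fit_lags = as.integer(fit_lags),
                 intercept_um2 = b0),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("D = %.4f um^2/s", x$D))
  if (!is.na(x$bootstrap_sd)) cat(sprintf(" +- %.4f (bootstrap SD)", x$bootstrap_sd))
  if (!is.na(x$n_trajectories)) cat(sprintf(", n = %d tracks", x$n_trajectories))
  cat(sprintf(", first %d MSD points\n", x$fit_lags))
  invisible(x)
}

#' Full MSD + diffusion estimate for a set of tracks
#'
#' @inheritParams compute_msd
#' @inheritParams estimate_D
#' @param n_boot Bootstrap samples for the SD (0 to skip).
#' @param seed Optional seed for the bootstrap resampling.
#' @return A `diffusion_estimate` with `n_trajectories` and (if requested)
#'   `bootstrap_sd` filled in.
#' @export
estimate_D_tracks <- function(tracks, fit_lags = 4L, frame_interval = 0.015,
                              intercept = FALSE, n_boot = 0L, seed = NULL) {
  msd <- compute_msd(tracks, max_lag = fit_lags,
                     frame_interval = frame_interval)
  est <- estimate_D(msd, fit_lags = fit_lags, intercept = intercept)
  est$n_trajectories <- length(unique(tracks$track_id))
  if (n_boot > 0)
    est$bootstrap_sd <- bootstrap_D(tracks, n_boot = n_boot, seed = seed,
                                    fit_lags = fit_lags,
                                    frame_interval = frame_interval,
                                    intercept = intercept)
  est
}

#' Bootstrap standard deviation of the diffusion estimate
#'
#' Resamples whole trajectories with replacement `n_boot` times, recomputes
#' the ensemble MSD and the diffusion coefficient for each replicate, and
#' returns the standard deviation of the replicate values.
#'
#' @inheritParams compute_msd
#' @inheritParams estimate_D
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Optional RNG seed for reproducible resampling.
#' @return Bootstrap standard deviation of D (um^2/s).
#' @export
bootstrap_D <- function(tracks, n_boot = 1000L, seed = NULL, fit_lags = 4L,
                        frame_interval = 0.015, intercept = FALSE) {
  nt <- length(unique(tracks$track_id))
  if (nt < 2) stop("bootstrap requires at least two trajectories")
  if (!is.null(seed)) set.seed(seed)
  sums <- track_lag_sums(tracks, fit_lags)
  lag <- seq_len(fit_lags) * frame_interval
  boots <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(nt, nt, replace = TRUE)
    np <- colSums(sums$np[idx, , drop = FALSE])
    if (any(np == 0)) return(NA_real_)
    msd <- colSums(sums$ss[idx, , drop = FALSE]) / np
    if (intercept) {
      slope <- stats::coef(stats::lm(msd ~ lag))[[2]]
    } else {
      slope <- sum(lag * msd) / sum(lag^2)
    }
    max(0, slope / 4)
  }, numeric(1))
  stats::sd(boots[!is.na(boots)])
}
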