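# Shared helpers for the test suite.

# count_trace with warnings suppressed (blinking / unexplained-step warnings
# are expected on noisy simulated traces and asserted separately).
quiet_count <- function(trace, ...) {
  suppressWarnings(count_trace(trace, ...))
}

# Brute-force time-and-ensemble MSD: pools every displacement pair of every
# track with an explicit double loop. Oracle for compute_msd().
brute_force_msd <- function(tracks, max_lag, frame_interval) {
  by_track <- split(tracks, tracks$track_id)
  msd <- numeric(max_lag)
  np <- integer(max_lag)
  for (k in seq_len(max_lag)) {
    acc <- 0; n <- 0L
    for (tr in by_track) {
      tr <- tr[order(tr$frame), ]
      m <- nrow(tr)
      if (m <= k) next
      for (s in seq_len(m - k)) {
        acc <- acc + (tr$x_um[s + k] - tr$x_um[s])^2 +
          (tr$y_um[s + k] - tr$y_um[s])^2
        n <- n + 1L
      }
    }
    msd[k] <- if (n > 0) acc / n else NA_real_
    np[k] <- n
  }
  data.frame(lag_s = seq_len(max_lag) * frame_interval, msd_um2 = msd,
             n_pairs = np)
}

# Extract the frame-1 -> frame-2 pairing produced by link() as a two-column
# index matrix (row in frame 1, row in frame 2, both 1-based within frame).
linked_pairs <- function(det, tr) {
  n1 <- sum(det$frame == 1L)
  key <- paste(tr$x_um, tr$y_um, tr$frame)
  orig <- paste(det$x_um, det$y_um, det$frame)
  pairs <- lapply(split(seq_len(nrow(tr)), tr$track_id), function(idx) {
    if (length(idx) != 2L) return(NULL)
    rows <- match(key[idx], orig)
    f <- det$frame[rows]
    c(rows[f == 1L], rows[f == 2L] - n1)
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) return(matrix(integer(0), 0, 2))
  dimnames(pairs) <- NULL
  pairs[order(pairs[, 1]), , drop = FALSE]
}

# Minimum-total-distance one-to-one assignment between two point sets, by
# exhaustive enumeration (oracle for greedy linking on small frames).
# Returns a two-column matrix (index in a, index in b) of matched pairs.
optimal_assignment <- function(ax, ay, bx, by, gate) {
  na <- length(ax); nb <- length(bx)
  dist <- sqrt(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2)
  k <- min(na, nb)
  best <- NULL; best_cost <- Inf; best_n <- -1L
  subsets_a <- utils::combn(na, k, simplify = FALSE)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  subsets_b <- utils::combn(nb, k, simplify = FALSE)
  for (sa in subsets_a) for (sb in subsets_b) for (p in perms(sb)) {
    d <- dist[cbind(sa, p)]
    ok <- d <= gate
    cost <- sum(d[ok]); n_ok <- sum(ok)
    if (n_ok > best_n || (n_ok == best_n && cost < best_cost)) {
      best_n <- n_ok; best_cost <- cost
      best <- cbind(sa[ok], p[ok])
    }
  }
  if (is.null(best)) matrix(integer(0), 0, 2) else
    best[order(best[, 1]), , drop = FALSE]
}
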