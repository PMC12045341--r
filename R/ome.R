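#' Cell mask set
#'
#' Wraps a label image (0 = background) with its cell id set and adjacency
#' relation. Two cells are adjacent when some pixel of one lies within
#' `adjacency_px` (Chebyshev) pixels of a pixel of the other, which treats
#' cells separated by a sub-pixel gap — as physically contacting rods are —
#' as sharing a boundary.
#'
#' @param label_image Integer matrix of cell labels (0 background).
#' @param adjacency_px Neighbourhood radius in pixels used to declare
#'   adjacency (default 2).
#' @return A `cell_mask_set` list: `label_image`, `cell_ids`, `adjacency`
#'   (two-column matrix of unordered adjacent id pairs).
#' @export
cell_mask_set <- function(label_image, adjacency_px = 2L) {
  stopifnot(is.matrix(label_image), all(label_image >= 0))
  ids <- sort(setdiff(unique(as.integer(label_image)), 0L))
  adj <- matrix(integer(0), 0, 2)
  if (length(ids) > 1) {
    nr <- nrow(label_image); nc <- ncol(label_image)
    pairs <- list()
    for (dr in 0:adjacency_px) for (dc in (-adjacency_px):adjacency_px) {
      if (dr == 0 && dc <= 0) next
      r1 <- seq_len(nr - dr)
      c1 <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
      a <- label_image[r1, c1, drop = FALSE]
      b <- label_image[r1 + dr, c1 + dc, drop = FALSE]
      sel <- a != 0L & b != 0L & a != b
      if (any(sel))
        pairs[[length(pairs) + 1L]] <- cbind(pmin(a[sel], b[sel]),
                                             pmax(a[sel], b[sel]))
    }
    if (length(pairs)) adj <- unique(do.call(rbind, pairs))
  }
  structure(list(label_image = label_image, cell_ids = ids,
                 adjacency = adj, adjacency_px = adjacency_px),
            class = "cell_mask_set")
}

cells_adjacent <- function(masks, a, b) {
  adj <- masks$adjacency
  any(adj[, 1] == min(a, b) & adj[, 2] == max(a, b))
}

#' Assign trajectory points to cells
#'
#' Maps each detection to the label of its nearest pixel in the mask raster;
#' background pixels yield `NA` (unassigned). Positions outside the raster
#' extent are an error.
#'
#' @param track data.frame with `frame, x_um, y_um` for one trajectory.
#' @param masks A [cell_mask_set()].
#' @param cfg A [sim_config()] supplying the pixel size of the raster.
#' @return Integer vector of per-frame cell labels (`NA` = unassigned),
#'   ordered by frame.
#' @export
assign_cells <- function(track, masks, cfg) {
  lab <- masks$label_image
  ord <- order(track$frame)
  col <- round(track$x_um[ord] / cfg$pixel_size) + 1L
  row <- round(track$y_um[ord] / cfg$pixel_size) + 1L
  if (any(col < 1 | col > ncol(lab) | row < 1 | row > nrow(lab)))
    stop("track position(s) outside the mask raster extent")
  out <- lab[cbind(row, col)]
  out[out == 0L] <- NA_integer_
  as.integer(out)
}

# Bridge unassigned (NA) runs of length <= gap by carrying the previous label
# forward (leading NAs take the first real label). Longer runs stay NA.
bridge_labels <- function(labels, gap = 2L) {
  n <- length(labels)
  out <- labels
  r <- rle(is.na(out))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i] || r$lengths[i] > gap) next
    fill <- if (starts[i] > 1) out[starts[i] - 1L]
            else if (ends[i] < n) labels[ends[i] + 1L] else NA_integer_
    out[starts[i]:ends[i]] <- fill
  }
  out
}

#' Detect intercellular boundary crossings along one trajectory
#'
#' Short unassigned runs (particle sitting on ambiguous boundary pixels) are
#' bridged first; a crossing is then recorded at every frame where the
#' bridged label changes between two adjacent cells, with the crossing point
#' taken as the midpoint of the two flanking detections. Label changes
#' between non-adjacent cells mark the track as a teleport artifact and no
#' event is returned. The event is classified as `unidirectional` (one
#' direction, two cells), `bidirectional` (a later crossing returns to a
#' previously occupied cell), or `serial` (at least three distinct cells
#' visited over >= 2 crossings).
#'
#' @param track data.frame `frame, x_um, y_um` for one trajectory.
#' @param masks A [cell_mask_set()].
#' @param cfg A [sim_config()].
#' @param labels Optional precomputed per-frame labels (else
#'   [assign_cells()] is called).
#' @param gap Maximum bridged run of unassigned frames (default 2).
#' @return A `transfer_event` list (`track_id, crossings, n_boundaries,
#'   event_type, cells_visited`) or `NULL` when the track never changes
#'   cell. Teleport-artifact tracks also return `NULL`, with a warning.
#' @export
detect_crossings <- function(track, masks, cfg, labels = NULL, gap = 2L) {
  ord <- order(track$frame)
  track <- track[ord, , drop = FALSE]
  if (is.null(labels)) labels <- assign_cells(track, masks, cfg)
  lab <- bridge_labels(labels, gap = gap)
  n <- length(lab)
  crossings <- list()
  for (f in 2:n) {
    a <- lab[f - 1]; b <- lab[f]
    if (is.na(a) || is.na(b) || a == b) next
    if (!cells_adjacent(masks, a, b)) {
      warning(sprintf("track %s: label change %d -> %d between non-adjacent cells; excluded as teleport artifact",
                      as.character(track$track_id[1]), a, b))
      return(NULL)
    }
    crossings[[length(crossings) + 1L]] <- data.frame(
      frame = track$frame[f], from_cell = a, to_cell = b,
      x_um = (track$x_um[f - 1] + track$x_um[f]) / 2,
      y_um = (track$y_um[f - 1] + track$y_um[f]) / 2)
  }
  if (!length(crossings)) return(NULL)
  cr <- do.call(rbind, crossings)
  rownames(cr) <- NULL
  visited <- unique(c(cr$from_cell[1], cr$to_cell))
  # a return is a crossing into any previously occupied cell
  seen <- cr$from_cell[1]
  returned <- FALSE
  for (i in seq_len(nrow(cr))) {
    if (cr$to_cell[i] %in% seen) returned <- TRUE
    seen <- unique(c(seen, cr$to_cell[i]))
  }
  event_type <- if (length(visited) >= 3) "serial"
                else if (returned) "bidirectional"
                else "unidirectional"
  structure(list(track_id = track$track_id[1],
                 crossings = cr,
                 n_boundaries = nrow(cr),
                 event_type = event_type,
                 cells_visited = visited),
            class = "transfer_event")
}

#' @export
print.transfer_event <- function(x, ...) {
  cat(sprintf("transfer_event (track %s): %s, %d boundary crossing(s), cells %s\n",
              as.character(x$track_id), x$event_type, x$n_boundaries,
              paste(x$cells_visited, collapse = " -> ")))
  invisible(x)
}

#' Detect transfer events for many trajectories
#'
#' @param tracks data.frame `track_id, frame, x_um, y_um`.
#' @inheritParams detect_crossings
#' @return List with `events` (list of `transfer_event`), `event_table`
#'   (data.frame `track_id, event_type, n_boundaries`), and
#'   `crossing_track_ids`.
#' @export
detect_transfer_events <- function(tracks, masks, cfg, gap = 2L) {
  ids <- unique(tracks$track_id)
  events <- list()
  for (id in ids) {
    ev <- detect_crossings(tracks[tracks$track_id == id, , drop = FALSE],
                           masks, cfg, gap = gap)
    if (!is.null(ev)) events[[length(events) + 1L]] <- ev
  }
  tab <- if (length(events))
    data.frame(track_id = sapply(events, function(e) e$track_id),
               event_type = vapply(events, function(e) e$event_type, character(1)),
               n_boundaries = vapply(events, function(e) e$n_boundaries, integer(1)))
  else data.frame(track_id = integer(0), event_type = character(0),
                  n_boundaries = integer(0))
  list(events = events, event_table = tab,
       crossing_track_ids = tab$track_id)
}

#' Diffusion of boundary-crossing particles
#'
#' Pools the crossing trajectories and delegates to the tracking module's
#' ensemble MSD and origin-constrained fit ([compute_msd()],
#' [estimate_D()]); also returns per-track estimates for tracks long enough
#' to fit.
#'
#' @param tracks data.frame of the crossing trajectories.
#' @param frame_interval Frame spacing (s).
#' @param fit_lags MSD points used in the fit (default 4).
#' @param n_boot Bootstrap replicates for the pooled SD (0 to skip).
#' @param seed Bootstrap seed.
#' @return List with `pooled` (a `diffusion_estimate`) and `per_track`
#'   (data.frame `track_id, D`).
#' @export
event_diffusion <- function(tracks, frame_interval = 0.015, fit_lags = 4L,
                            n_boot = 0L, seed = NULL) {
  pooled <- estimate_D_tracks(tracks, fit_lags = fit_lags,
                              frame_interval = frame_interval,
                              n_boot = n_boot, seed = seed)
  ids <- unique(tracks$track_id)
  per <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    if (nrow(tr) < fit_lags + 1) return(NULL)
    est <- estimate_D_tracks(tr, fit_lags = fit_lags,
                             frame_interval = frame_interval)
    data.frame(track_id = id, D = est$D)
  })
  per <- do.call(rbind, per)
  if (is.null(per)) per <- data.frame(track_id = ids[0], D = numeric(0))
  list(pooled = pooled, per_track = per)
}

#' Distance of crossing points to the nearest focus
#'
#' For each boundary crossing of an event, computes the Euclidean distance
#' to the nearest focus and whether it falls within `threshold` — the
#' operational test of whether transfers pass through receptor foci.
#'
#' @param event A `transfer_event` from [detect_crossings()].
#' @param foci data.frame `x_um, y_um` of focus positions (non-empty).
#' @param threshold Proximity threshold (um); default 0.320 um (two pixels),
#'   matching the localization/linking scale.
#' @return data.frame `frame, x_um, y_um, nearest_focus_distance_um,
#'   within_threshold, threshold_um`.
#' @export
focus_proximity <- function(event, foci, threshold = 0.320) {
  if (is.null(foci) || nrow(foci) == 0) stop("foci must be non-empty")
  cr <- event$crossings
  d <- vapply(seq_len(nrow(cr)), function(i)
    min(sqrt((foci$x_um - cr$x_um[i])^2 + (foci$y_um - cr$y_um[i])^2)),
    numeric(1))
  data.frame(frame = cr$frame, x_um = cr$x_um, y_um = cr$y_um,
             nearest_focus_distance_um = d,
             within_threshold = d <= threshold,
             threshold_um = threshold)
}
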