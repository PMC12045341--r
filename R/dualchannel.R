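#' Register and pair two-colour foci across beam-splitter channels
#'
#' Applies the channel registration `offset` to channel B coordinates, then
#' pairs foci greedily by ascending distance: the closest A/B pair within
#' `tolerance` is accepted first, both members are retired, and so on.
#' Unpaired foci in either channel are returned separately.
#'
#' @param foci_a,foci_b data.frames with `x_um, y_um` (and optionally
#'   `roi_id`; defaults to row numbers).
#' @param offset Registration offset `c(dx, dy)` (um) subtracted from
#'   channel B to bring it onto channel A.
#' @param tolerance Maximum pairing distance after registration (um).
#' @return List with `pairs` (data.frame `roi_a, roi_b, pair_distance_um`),
#'   `unpaired_a`, `unpaired_b` (roi ids).
#' @export
register_and_pair <- function(foci_a, foci_b, offset = c(0, 0),
                              tolerance = 0.320) {
  if (is.null(foci_a$roi_id)) foci_a$roi_id <- seq_len(nrow(foci_a))
  if (is.null(foci_b$roi_id)) foci_b$roi_id <- seq_len(nrow(foci_b))
  bx <- foci_b$x_um - offset[1]
  by <- foci_b$y_um - offset[2]
  if (nrow(foci_a) == 0 || nrow(foci_b) == 0) {
    return(list(pairs = data.frame(roi_a = integer(0), roi_b = integer(0),
                                   pair_distance_um = numeric(0)),
                unpaired_a = foci_a$roi_id, unpaired_b = foci_b$roi_id))
  }
  dist <- sqrt(outer(foci_a$x_um, bx, "-")^2 + outer(foci_a$y_um, by, "-")^2)
  cand <- which(dist <= tolerance, arr.ind = TRUE)
  pairs <- list()
  if (nrow(cand) > 0) {
    cand <- cand[order(dist[cand]), , drop = FALSE]
    used_a <- logical(nrow(foci_a)); used_b <- logical(nrow(foci_b))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(
        roi_a = foci_a$roi_id[i], roi_b = foci_b$roi_id[j],
        pair_distance_um = dist[i, j])
    }
  } else {
    used_a <- logical(nrow(foci_a)); used_b <- logical(nrow(foci_b))
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(roi_a = integer(0), roi_b = integer(0),
               pair_distance_um = numeric(0))
  rownames(pairs) <- NULL
  list(pairs = pairs,
       unpaired_a = foci_a$roi_id[!used_a],
       unpaired_b = foci_b$roi_id[!used_b])
}

#' Fit the inter-channel stoichiometric ratio
#'
#' Primary estimator: zero-intercept least squares of channel-B counts on
#' channel-A counts, `slope = sum(a * b) / sum(a^2)` — the number of B
#' molecules per A molecule. A focus without any A molecules cannot host the
#' complex, which motivates the origin constraint; an ordinary regression
#' with intercept is available via `intercept = TRUE`. The mean of per-focus
#' ratios and the total-count ratio `sum(b)/sum(a)` are reported alongside.
#'
#' @param pairs data.frame with integer columns `count_a`, `count_b`
#'   (both >= 1), one row per paired focus.
#' @param intercept If `TRUE`, also fit `count_b ~ count_a` with a free
#'   intercept and report its slope as `slope_intercept_fit`.
#' @return A `ratio_fit` list: `slope`, `n_pairs`, `residual_sd`,
#'   `ratio_tally` (table of (A,B) combinations), `mean_of_ratios`,
#'   `total_ratio`, and optionally `slope_intercept_fit`, `intercept`.
#' @export
fit_ratio <- function(pairs, intercept = FALSE) {
  stopifnot(nrow(pairs) >= 2, all(pairs$count_a >= 1),
            all(pairs$count_b >= 1))
  a <- as.numeric(pairs$count_a)
  b <- as.numeric(pairs$count_b)
  slope <- sum(a * b) / sum(a^2)
  res <- b - slope * a
  out <- list(slope = slope,
              n_pairs = nrow(pairs),
              residual_sd = stats::sd(res),
              ratio_tally = table(count_a = pairs$count_a,
                                  count_b = pairs$count_b),
              mean_of_ratios = mean(b / a),
              total_ratio = sum(b) / sum(a))
  if (intercept) {
    co <- stats::coef(stats::lm(b ~ a))
    out$slope_intercept_fit <- co[[2]]
    out$intercept <- co[[1]]
  }
  structure(out, class = "ratio_fit")
}

#' @export
print.ratio_fit <- function(x, ...) {
  cat(sprintf("ratio_fit: %.3f B per A molecule (n = %d foci, residual sd %.2f)\n",
              x$slope, x$n_pairs, x$residual_sd))
  cat(sprintf("  mean of ratios %.3f, total-count ratio %.3f\n",
              x$mean_of_ratios, x$total_ratio))
  invisible(x)
}

#' Count molecules in both channels of paired foci
#'
#' Step-counts each focus trace independently per channel with
#' [count_trace()], then assembles the paired count table for
#' [fit_ratio()]. Foci whose trace in either channel yields no countable
#' downward step are dropped with a message.
#'
#' @param pairing Result of [register_and_pair()].
#' @param traces_a,traces_b Lists of [bleach_trace()] indexed by roi id.
#' @param penalty Step-detection penalty passed to [detect_steps()].
#' @param unit_step Optional pooled unit step for both channels.
#' @return data.frame `roi_a, roi_b, count_a, count_b, pair_distance_um`.
#' @export
count_focus_pairs <- function(pairing, traces_a, traces_b, penalty = NULL,
                              unit_step = NULL) {
  pr <- pairing$pairs
  res <- lapply(seq_len(nrow(pr)), function(i) {
    fa <- tryCatch(count_trace(traces_a[[pr$roi_a[i]]], penalty, unit_step),
                   error = function(e) NULL)
    fb <- tryCatch(count_trace(traces_b[[pr$roi_b[i]]], penalty, unit_step),
                   error = function(e) NULL)
    if (is.null(fa) || is.null(fb) || fa$n_molecules < 1 ||
        fb$n_molecules < 1) return(NULL)
    data.frame(roi_a = pr$roi_a[i], roi_b = pr$roi_b[i],
               count_a = fa$n_molecules, count_b = fb$n_molecules,
               pair_distance_um = pr$pair_distance_um[i])
  })
  dropped <- sum(vapply(res, is.null, logical(1)))
  if (dropped > 0)
    message(sprintf("%d focus pair(s) dropped (uncountable trace)", dropped))
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(roi_a = integer(0), roi_b = integer(0),
                      count_a = integer(0), count_b = integer(0),
                      pair_distance_um = numeric(0))
  rownames(out) <- NULL
  out
}
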