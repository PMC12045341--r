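#' Cross-membrane density line profile
#'
#' @param position_nm Uniformly spaced, strictly increasing positions (nm),
#'   length >= 7.
#' @param value Density values (arbitrary units).
#' @param profile_id Identifier.
#' @return An object of class `density_profile` (a data.frame
#'   `position_nm, value`).
#' @export
density_profile <- function(position_nm, value, profile_id = NA) {
  stopifnot(length(position_nm) >= 7,
            length(position_nm) == length(value),
            all(diff(position_nm) > 0))
  steps <- diff(position_nm)
  if (max(steps) - min(steps) > 1e-6 * stats::median(steps))
    stop("positions must be uniformly spaced")
  out <- data.frame(position_nm = as.numeric(position_nm),
                    value = as.numeric(value))
  attr(out, "profile_id") <- profile_id
  class(out) <- c("density_profile", "data.frame")
  out
}

#' Locate membrane density centres in a line profile
#'
#' Finds the `n_peaks` strongest local extrema of the requested polarity and
#' refines each to subsample precision with a three-point parabolic fit
#' around the extremum. On raw cryo-EM-like profiles membranes are dark, so
#' use `polarity = "troughs"`; on inverted or synthetic density profiles use
#' `"peaks"` (no auto-detection — the choice is explicit).
#'
#' @param profile A [density_profile()].
#' @param n_peaks Expected number of membrane densities (2 or 3).
#' @param polarity `"peaks"` (default) or `"troughs"`.
#' @param min_separation_nm Minimum distance between selected extrema (nm).
#'   Noise riding on a broad density peak can split its top into several
#'   local maxima; candidates closer than this to an already-selected,
#'   stronger extremum are suppressed so that each membrane contributes one
#'   centre. Default 5 nm, well below any membrane separation of interest.
#' @return Numeric vector of refined centres (nm), sorted by position.
#' @export
locate_density_centers <- function(profile, n_peaks = 2L,
                                   polarity = c("peaks", "troughs"),
                                   min_separation_nm = 5) {
  polarity <- match.arg(polarity)
  stopifnot(n_peaks %in% c(2L, 3L))
  v <- profile$value
  if (polarity == "troughs") v <- -v
  n <- length(v)
  i <- 2:(n - 1)
  is_max <- v[i] > v[i - 1] & v[i] >= v[i + 1]
  idx <- i[is_max]
  # strongest-first selection with minimum-separation suppression
  idx <- idx[order(v[idx], decreasing = TRUE)]
  sel <- integer(0)
  for (j in idx) {
    if (length(sel) == n_peaks) break
    if (all(abs(profile$position_nm[j] - profile$position_nm[sel]) >=
            min_separation_nm))
      sel <- c(sel, j)
  }
  if (length(sel) < n_peaks)
    stop(sprintf("found %d separated local extrem%s, %d required",
                 length(sel), if (length(sel) == 1) "um" else "a", n_peaks))
  idx <- sel
  step <- profile$position_nm[2] - profile$position_nm[1]
  centers <- vapply(sort(idx), function(j) {
    y0 <- v[j - 1]; y1 <- v[j]; y2 <- v[j + 1]
    denom <- y0 - 2 * y1 + y2
    dx <- if (abs(denom) < .Machine$double.eps) 0 else
      0.5 * (y0 - y2) / denom
    profile$position_nm[j] + dx * step
  }, numeric(1))
  sort(centers)
}

#' Membrane separation from located density centres
#'
#' @param centers Sorted density centres (nm) from
#'   [locate_density_centers()].
#' @param pair Indices `c(i, j)` of the two centres to measure between
#'   (default the first and last).
#' @param kind Measurement kind: `"OM-OM"` (outer-membrane separation at a
#'   cell-cell contact) or `"OM-IM"` (periplasm thickness).
#' @return A `membrane_measurement` list: `peak_centers`, `separation_nm`,
#'   `kind`, `pair`.
#' @export
measure_separation <- function(centers, pair = NULL,
                               kind = c("OM-OM", "OM-IM")) {
  kind <- match.arg(kind)
  if (length(centers) < 2) stop("need at least two centres")
  if (is.null(pair)) pair <- c(1L, length(centers))
  if (any(pair < 1 | pair > length(centers)) || pair[1] == pair[2])
    stop("pair selection out of range")
  sep <- abs(centers[pair[2]] - centers[pair[1]])
  structure(list(peak_centers = centers, separation_nm = sep,
                 kind = kind, pair = as.integer(pair)),
            class = "membrane_measurement")
}

#' @export
print.membrane_measurement <- function(x, ...) {
  cat(sprintf("membrane_measurement (%s): %.2f nm between centres %.2f and %.2f nm\n",
              x$kind, x$separation_nm, x$peak_centers[x$pair[1]],
              x$peak_centers[x$pair[2]]))
  invisible(x)
}

#' Measure a batch of density profiles
#'
#' @param profiles List of [density_profile()] objects.
#' @inheritParams locate_density_centers
#' @inheritParams measure_separation
#' @return data.frame `profile_id, separation_nm` (one row per profile).
#' @export
measure_profiles <- function(profiles, n_peaks = 2L, polarity = "peaks",
                             pair = NULL, kind = "OM-OM") {
  res <- lapply(profiles, function(p) {
    ctr <- locate_density_centers(p, n_peaks = n_peaks, polarity = polarity)
    m <- measure_separation(ctr, pair = pair, kind = kind)
    data.frame(profile_id = attr(p, "profile_id") %||% NA,
               separation_nm = m$separation_nm)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' One-way ANOVA comparison of measurement groups
#'
#' Standard one-way analysis of variance across two or more independent
#' groups: `F = (SSB / (k - 1)) / (SSW / (N - k))`, with the p value from
#' the F distribution (delegated to [stats::aov()]). The degenerate case of
#' zero within-group variance with equal means returns `F = 0, p = 1`.
#'
#' @param groups Named list of numeric vectors, each of length >= 2.
#' @return A `group_comparison` list: `group_means, group_sds, group_ns,
#'   F, p, df`.
#' @export
anova_one_way <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, integer(1)) >= 2))
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  means <- vapply(groups, mean, numeric(1))
  sds <- vapply(groups, stats::sd, numeric(1))
  ns <- vapply(groups, length, integer(1))
  k <- length(groups); N <- length(values)
  if (all(sds == 0) && length(unique(means)) == 1L) {
    Fv <- 0; pv <- 1
  } else {
    tab <- stats::anova(stats::aov(values ~ g))
    Fv <- tab[["F value"]][1]
    pv <- tab[["Pr(>F)"]][1]
  }
  structure(list(group_means = means, group_sds = sds, group_ns = ns,
                 F = Fv, p = pv, df = c(k - 1L, N - k)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  for (i in seq_along(x$group_means))
    cat(sprintf("  %s: %.2f +- %.2f (n = %d)\n", names(x$group_means)[i],
                x$group_means[i], x$group_sds[i], x$group_ns[i]))
  invisible(x)
}
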