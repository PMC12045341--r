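#' Write an image stack as multi-page TIFF
#'
#' Camera counts are clamped to `[0, max_value]` and stored as 16-bit
#' samples; [read_stack_tiff()] with the same `max_value` restores them to
#' within one count.
#'
#' @param stack Numeric array `rows x cols x frames` (or a matrix).
#' @param path Output file.
#' @param max_value Full-scale count value (default 65535).
#' @export
write_stack_tiff <- function(stack, path, max_value = 65535) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  pages <- lapply(seq_len(dim(stack)[3]), function(f)
    pmin(pmax(stack[, , f] / max_value, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF stack written by [write_stack_tiff()]
#'
#' @param path Input file.
#' @param max_value Full-scale count value used when writing.
#' @return Numeric array `rows x cols x frames` in camera counts.
#' @export
read_stack_tiff <- function(path, max_value = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(NA_real_, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (f in seq_along(pages)) {
    p <- pages[[f]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    arr[, , f] <- p * max_value
  }
  arr
}

#' Write a label image as 16-bit TIFF
#' @param labels Integer matrix (0 = background).
#' @param path Output file.
#' @export
write_labels_tiff <- function(labels, path) {
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label image written by [write_labels_tiff()]
#' @param path Input file.
#' @return Integer matrix of labels.
#' @export
read_labels_tiff <- function(path) {
  p <- tiff::readTIFF(path)
  if (length(dim(p)) == 3) p <- p[, , 1]
  matrix(as.integer(round(p * 65535)), nrow(p), ncol(p))
}

#' Write / read trajectory tables
#'
#' Plain CSV with columns `track_id, frame, x_um, y_um` (plus any extras).
#' @param tracks data.frame of trajectories.
#' @param path File path.
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read density profiles
#'
#' Long CSV with columns `profile_id, position_nm, value`.
#' @param profiles List of [density_profile()] objects.
#' @param path File path.
#' @export
write_profiles_csv <- function(profiles, path) {
  rows <- lapply(profiles, function(p)
    data.frame(profile_id = attr(p, "profile_id"),
               position_nm = p$position_nm, value = p$value))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$profile_id), function(d)
    density_profile(d$position_nm, d$value, profile_id = d$profile_id[1]))
}

#' Save a configuration or report as JSON
#' @param x A list (e.g. a [sim_config()] or pipeline report).
#' @param path Output file.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
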