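#' Read and write FRAP trace CSV files
#'
#' The on-disk schema is fixed: columns `time_s`, `f_bleached`,
#' `f_unbleached`, `f_background`, `is_prebleach`, `exclude`. Reading
#' validates the header and monotone times and returns a [frap_trace()];
#' writing is its inverse (write then read is the identity on valid files).
#'
#' @param path File path.
#' @return `read_frap_csv()` returns a `frap_trace`.
#' @export
read_frap_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("time_s", "f_bleached", "f_unbleached", "f_background",
           "is_prebleach", "exclude")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (any(diff(df$time_s) <= 0))
    stop(sprintf("%s: time_s must be strictly increasing", path),
         call. = FALSE)
  frap_trace(df$time_s, df$f_bleached, df$f_unbleached, df$f_background,
             n_pre_frames = sum(df$is_prebleach),
             exclude_mask = as.logical(df$exclude))
}

#' @rdname read_frap_csv
#' @param trace A `frap_trace`.
#' @export
write_frap_csv <- function(trace, path) {
  stopifnot(inherits(trace, "frap_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Read and write particle-track CSV files
#'
#' 2D tracks carry columns `track_id`, `time_s`, `x_um`, `y_um`; 1D
#' (path-projected) tracks carry `track_id`, `time_s`, `pos_um`. Times must
#' be strictly increasing within each track.
#'
#' @param path File path.
#' @return A data frame of tracks.
#' @export
read_track_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"track_id" %in% names(df) || !"time_s" %in% names(df))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(setdiff(c("track_id", "time_s"), names(df)),
                       collapse = ", ")), call. = FALSE)
  is2d <- all(c("x_um", "y_um") %in% names(df))
  is1d <- "pos_um" %in% names(df)
  if (!is2d && !is1d)
    stop(sprintf("%s: need either x_um,y_um or pos_um columns", path),
         call. = FALSE)
  bad <- vapply(split(df$time_s, df$track_id),
                function(t) any(diff(t) <= 0), logical(1))
  if (any(bad))
    stop(sprintf("%s: non-monotone times in track(s) %s", path,
                 paste(names(bad)[bad], collapse = ", ")), call. = FALSE)
  df
}

#' @rdname read_track_csv
#' @param tracks Data frame of tracks.
#' @export
write_track_csv <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' Write track segments to CSV
#'
#' Columns: `track_id`, `t_start_s`, `t_end_s`, `d_start_um`, `d_end_um`,
#' `speed_um_s`, `kind`.
#'
#' @param segments A `track_segments` data frame (or an rbind of several).
#' @param path File path.
#' @export
write_segment_csv <- function(segments, path) {
  utils::write.csv(as.data.frame(segments), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segment_csv
#' @export
read_segment_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("t_start_s", "t_end_s", "d_start_um", "d_end_um", "speed_um_s",
           "kind")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  class(df) <- c("track_segments", "data.frame")
  df
}

#' Read and write arbors in SWC format
#'
#' Standard 7-column SWC (`id type x y z radius parent`), whitespace
#' separated, `#` comments, coordinates in um, soma as the type-1 root node.
#'
#' @param path File path.
#' @return `read_swc()` returns an [arbor()].
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop(sprintf("%s: no SWC records", path), call. = FALSE)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(vapply(fields, length, integer(1)) != 7)
  if (length(bad)) {
    lineno <- which(keep)[bad[1]]
    stop(sprintf("%s: line %d: expected 7 SWC columns", path, lineno),
         call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, as.numeric))
  if (anyNA(m)) {
    lineno <- which(keep)[which(rowSums(is.na(m)) > 0)[1]]
    stop(sprintf("%s: line %d: non-numeric SWC field", path, lineno),
         call. = FALSE)
  }
  arbor(data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                   x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                   parent = as.integer(m[, 7])))
}

#' @rdname read_swc
#' @param ar An [arbor()].
#' @export
write_swc <- function(ar, path) {
  stopifnot(inherits(ar, "arbor"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC export; coordinates in um", con)
  writeLines(sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                     ar$id, ar$type, ar$x, ar$y, ar$z, ar$radius, ar$parent),
             con)
  invisible(path)
}

#' Write a summary report as JSON
#'
#' @param x A list (e.g. from [compare_groups()]) or data frame.
#' @param path File path.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_summary_json
#' @export
read_summary_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a kymograph as a 16-bit grayscale TIFF
#'
#' Requires the `tiff` package. Occupancy counts are scaled to the full
#' 16-bit range.
#'
#' @param kymo A [build_kymograph()] result.
#' @param path File path.
#' @export
write_kymograph_tiff <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymograph"))
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the `tiff` package is required to write TIFF kymographs",
         call. = FALSE)
  m <- kymo$matrix
  mx <- max(m)
  img <- if (mx > 0) m / mx else m
  tiff::writeTIFF(img, path, bits.per.sample = 16)
  invisible(path)
}

#' Write a simulation configuration as JSON
#' @param config Any of the simulator configuration objects.
#' @param path File path.
#' @export
write_config_json <- function(config, path) {
  jsonlite::write_json(c(list(class = class(config)[1]), unclass(config)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' One-row data frame view of a FRAP fit (for CSV/JSON export)
#' @param fit A `frap_fit`.
#' @return One-row data frame.
#' @export
frap_fit_as_row <- function(fit) {
  stopifnot(inherits(fit, "frap_fit"))
  data.frame(k_off = fit$k_off, t_half = fit$t_half,
             total_recovery = fit$total_recovery,
             se_k_off = fit$se_k_off,
             se_total_recovery = fit$se_total_recovery,
             rss = fit$rss, n_points = fit$n_points,
             converged = fit$converged)
}
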