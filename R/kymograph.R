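#' Build a kymograph (time vs arc-position occupancy matrix) from 1D tracks
#'
#' Rows are frames, columns are arc-length bins along the path; each visit of
#' a particle to a bin at a frame increments the cell. A particle moving at
#' constant speed v appears as a line of slope v (um per s), which is how
#' speeds are read off kymographs.
#'
#' @param tracks Data frame of 1D tracks: `track_id`, `time_s`, `pos_um`.
#' @param path_length Length of the path, um (sets the column range).
#' @param frame_times Times of the kymograph rows, s; defaults to the sorted
#'   unique track times.
#' @param bin_size Arc-length bin width, um.
#' @return An object of class `kymograph`: a list with the occupancy `matrix`
#'   (frames x bins), `bin_size`, `frame_times` and `bin_centers`.
#' @export
build_kymograph <- function(tracks, path_length, frame_times = NULL,
                            bin_size = 0.2) {
  stopifnot(bin_size > 0, path_length > 0)
  if (is.null(frame_times)) frame_times <- sort(unique(tracks$time_s))
  n_bins <- max(1L, ceiling(path_length / bin_size))
  mat <- matrix(0L, nrow = length(frame_times), ncol = n_bins)
  if (nrow(tracks) > 0) {
    row_idx <- match(tracks$time_s, frame_times)
    col_idx <- pmin(pmax(floor(tracks$pos_um / bin_size) + 1L, 1L), n_bins)
    keep <- !is.na(row_idx) & !is.na(col_idx)
    for (k in which(keep)) {
      mat[row_idx[k], col_idx[k]] <- mat[row_idx[k], col_idx[k]] + 1L
    }
  }
  structure(list(matrix = mat, bin_size = bin_size,
                 frame_times = frame_times,
                 bin_centers = (seq_len(n_bins) - 0.5) * bin_size),
            class = "kymograph")
}

#' Estimate the speed of a single-particle kymograph trace by regression
#'
#' Regresses the occupied bin centers on frame time; the slope magnitude is
#' the particle's speed in um/s. Intended for validating kymograph geometry,
#' not as the primary speed estimator (see [segment_track()]).
#'
#' @param kymo A [build_kymograph()] result containing one particle.
#' @return Slope of the occupancy trace, um/s.
#' @export
kymograph_trace_slope <- function(kymo) {
  stopifnot(inherits(kymo, "kymograph"))
  occ <- which(kymo$matrix > 0, arr.ind = TRUE)
  if (nrow(occ) < 2) return(NA_real_)
  t <- kymo$frame_times[occ[, 1]]
  pos <- kymo$bin_centers[occ[, 2]]
  unname(stats::coef(stats::lm(pos ~ t))[2])
}

#' Temporal color-code projection of 2D tracks
#'
#' Visualization analog of the temporal color-code projection used to reveal
#' motile trajectories: positions are rasterized onto a 2D grid and each pixel
#' records the frame indices at which it was visited, rendered as a hue ramp
#' (early = first colors, late = last). No statistics are derived from it.
#'
#' @param tracks Data frame `track_id`, `time_s`, `x_um`, `y_um`.
#' @param pixel_size Grid pixel size, um.
#' @return A list of class `temporal_projection`: `first_visit` and
#'   `last_visit` matrices of frame indices (NA where never visited),
#'   `occupancy` counts, the grid axes, and `n_frames`.
#' @export
temporal_projection <- function(tracks, pixel_size = 0.2) {
  stopifnot(is.data.frame(tracks),
            all(c("time_s", "x_um", "y_um") %in% names(tracks)),
            pixel_size > 0)
  ft <- sort(unique(tracks$time_s))
  frame_idx <- match(tracks$time_s, ft)
  xr <- range(tracks$x_um); yr <- range(tracks$y_um)
  nx <- max(1L, ceiling((xr[2] - xr[1]) / pixel_size) + 1L)
  ny <- max(1L, ceiling((yr[2] - yr[1]) / pixel_size) + 1L)
  ix <- pmin(floor((tracks$x_um - xr[1]) / pixel_size) + 1L, nx)
  iy <- pmin(floor((tracks$y_um - yr[1]) / pixel_size) + 1L, ny)
  first <- matrix(NA_integer_, ny, nx)
  last <- matrix(NA_integer_, ny, nx)
  occ <- matrix(0L, ny, nx)
  for (k in seq_along(ix)) {
    r <- iy[k]; c <- ix[k]; f <- frame_idx[k]
    occ[r, c] <- occ[r, c] + 1L
    if (is.na(first[r, c]) || f < first[r, c]) first[r, c] <- f
    if (is.na(last[r, c]) || f > last[r, c]) last[r, c] <- f
  }
  structure(list(first_visit = first, last_visit = last, occupancy = occ,
                 x = xr[1] + (seq_len(nx) - 0.5) * pixel_size,
                 y = yr[1] + (seq_len(ny) - 0.5) * pixel_size,
                 n_frames = length(ft)),
            class = "temporal_projection")
}
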