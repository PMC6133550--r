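#' Polyline path for projecting 2D trajectories
#'
#' The computational analog of drawing a segmented line over a trajectory:
#' an ordered polyline (soma to terminal for axons, drawing direction for
#' cells) onto which 2D particle positions are projected by arc length.
#'
#' @param xy Two-column matrix or data frame of control points, um, >= 2 rows,
#'   consecutive points distinct.
#' @return An object of class `path_spec` with precomputed segment lengths and
#'   cumulative arc length.
#' @export
path_spec <- function(xy) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, nrow(xy) >= 2, is.numeric(xy))
  seg <- diff(xy)
  len <- sqrt(rowSums(seg^2))
  if (any(len == 0))
    stop("consecutive path points must be distinct", call. = FALSE)
  structure(list(xy = xy, seg_len = len, cum_len = c(0, cumsum(len))),
            class = "path_spec")
}

#' Total length of a path
#' @param path A [path_spec()].
#' @return Length in um.
#' @export
path_length <- function(path) {
  stopifnot(inherits(path, "path_spec"))
  utils::tail(path$cum_len, 1)
}

# arc positions + distances of one point against every polyline segment
project_point <- function(p, path) {
  a <- path$xy[-nrow(path$xy), , drop = FALSE]
  d <- diff(path$xy)
  ap <- cbind(p[1] - a[, 1], p[2] - a[, 2])
  tt <- (ap[, 1] * d[, 1] + ap[, 2] * d[, 2]) / (path$seg_len^2)
  tt <- pmin(pmax(tt, 0), 1)
  qx <- a[, 1] + tt * d[, 1]
  qy <- a[, 2] + tt * d[, 2]
  dist <- sqrt((p[1] - qx)^2 + (p[2] - qy)^2)
  arc <- path$cum_len[-length(path$cum_len)] + tt * path$seg_len
  list(arc = arc, dist = dist)
}

#' Project a 2D track onto a path by arc length
#'
#' Each frame's position is replaced by the arc-length coordinate of the
#' nearest point on the polyline. Where several polyline segments are equally
#' near (within `tie_tol`), the candidate closest to the previous frame's
#' projection wins, preserving continuity through hairpins. Frames farther
#' than `corridor` from the path are flagged and excluded.
#'
#' @param track Data frame with columns `time_s`, `x_um`, `y_um` (and
#'   optionally `track_id`).
#' @param path A [path_spec()].
#' @param corridor Maximum allowed distance from the path, um (default 2).
#' @param tie_tol Distance slack within which candidates count as tied, um.
#' @return Data frame with columns `track_id` (if present), `time_s`,
#'   `pos_um`; excluded frames are dropped and reported in attribute
#'   `excluded` (their row indices).
#' @export
project_onto_path <- function(track, path, corridor = 2, tie_tol = 1e-9) {
  stopifnot(is.data.frame(track), all(c("time_s", "x_um", "y_um") %in%
                                        names(track)))
  stopifnot(inherits(path, "path_spec"), corridor > 0)
  n <- nrow(track)
  arc <- rep(NA_real_, n)
  ok <- rep(TRUE, n)
  prev_arc <- NA_real_
  for (i in seq_len(n)) {
    pr <- project_point(c(track$x_um[i], track$y_um[i]), path)
    dmin <- min(pr$dist)
    if (dmin > corridor) {
      ok[i] <- FALSE
      next
    }
    cand <- which(pr$dist <= dmin + tie_tol)
    if (length(cand) > 1 && !is.na(prev_arc)) {
      cand <- cand[which.min(abs(pr$arc[cand] - prev_arc))]
    } else {
      cand <- cand[1]
    }
    arc[i] <- pr$arc[cand]
    prev_arc <- arc[i]
  }
  out <- data.frame(time_s = track$time_s[ok], pos_um = arc[ok])
  if ("track_id" %in% names(track))
    out <- cbind(track_id = track$track_id[ok], out)
  attr(out, "excluded") <- which(!ok)
  out
}

#' Reduce a 2D track to 1D by cumulative arc length along its own trajectory
#'
#' The in-silico counterpart of drawing the segmented line along the
#' trajectory itself: positions are optionally boxcar-smoothed (to keep
#' localization noise from inflating path length during pauses) and the
#' cumulative travelled distance becomes the 1D coordinate. Speeds are
#' preserved; direction is not (the coordinate is monotone), which is the
#' right reduction for run/pause/switch analysis of planar tracks.
#'
#' @param track Data frame with `time_s`, `x_um`, `y_um`.
#' @param smoothing_window Odd boxcar width in frames applied to x and y
#'   before arc-length accumulation; 1 disables smoothing.
#' @return Data frame `time_s`, `pos_um` (plus `track_id` if present).
#' @export
track_arc_length <- function(track, smoothing_window = 3) {
  stopifnot(is.data.frame(track), all(c("time_s", "x_um", "y_um") %in%
                                        names(track)))
  x <- boxcar(track$x_um, smoothing_window)
  y <- boxcar(track$y_um, smoothing_window)
  steps <- sqrt(diff(x)^2 + diff(y)^2)
  out <- data.frame(time_s = track$time_s, pos_um = c(0, cumsum(steps)))
  if ("track_id" %in% names(track))
    out <- cbind(track_id = track$track_id, out)
  out
}

# centered boxcar with edge replication; window coerced to odd
boxcar <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1) return(x)
  if (window %% 2 == 0) window <- window + 1L
  half <- window %/% 2
  n <- length(x)
  padded <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(padded, rep(1 / window, window),
                           sides = 2))[(half + 1):(half + n)]
}
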