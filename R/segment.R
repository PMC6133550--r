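#' Parameters controlling track segmentation
#'
#' A segment is a maximal portion of a track with constant speed, bounded by
#' speed changes or pauses. The pause threshold (movement slower than
#' 0.1 um/s) is the field's operational definition; the remaining parameters
#' operationalize what a human rater does when partitioning a kymograph track
#' by eye: ignore speed fluctuations below ~30% (or 0.1 um/s absolute),
#' do not call segments shorter than ~2 s, and read speeds on slightly
#' smoothed traces.
#'
#' @param pause_speed_threshold Speed below which a segment is a pause, um/s.
#' @param min_segment_duration Shortest admissible segment, s.
#' @param rel_speed_change Minimum relative speed difference (fraction of the
#'   larger speed) between adjacent run segments.
#' @param abs_speed_change Minimum absolute speed difference, um/s.
#' @param smoothing_window Boxcar width (frames, odd) applied to instantaneous
#'   speeds before change detection; 1 disables.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(pause_speed_threshold = 0.1,
                                min_segment_duration = 2,
                                rel_speed_change = 0.3,
                                abs_speed_change = 0.1,
                                smoothing_window = 3) {
  stopifnot(pause_speed_threshold > 0, min_segment_duration > 0,
            rel_speed_change > 0, abs_speed_change > 0,
            smoothing_window >= 1)
  structure(list(pause_speed_threshold = pause_speed_threshold,
                 min_segment_duration = min_segment_duration,
                 rel_speed_change = rel_speed_change,
                 abs_speed_change = abs_speed_change,
                 smoothing_window = as.integer(smoothing_window)),
            class = "segmentation_params")
}

#' Partition a 1D track into constant-speed run and pause segments
#'
#' Bottom-up change-point segmentation: instantaneous frame-to-frame speeds
#' (boxcar-smoothed) start as one segment per frame interval; the adjacent
#' pair with the smallest speed difference is merged repeatedly while that
#' difference is below the speed-change criterion
#' `max(abs_speed_change, rel_speed_change * larger |speed|)` or while either
#' member is shorter than `min_segment_duration`. Merged segments are
#' classified run or pause by mean |speed| against the pause threshold, and
#' adjacent pauses are coalesced. Segments partition the observed time span
#' exactly; reported speeds are signed net displacement over duration from
#' the raw positions, so concatenated displacement is preserved.
#'
#' @param track Data frame with `time_s` (strictly increasing, >= 2 frames)
#'   and `pos_um`.
#' @param params A [segmentation_params()].
#' @return Data frame of class `track_segments` with columns `t_start_s`,
#'   `t_end_s`, `d_start_um`, `d_end_um`, `speed_um_s`, `kind` ("run" or
#'   "pause"), plus `track_id` if present in the input. Attribute
#'   `short_track` is TRUE when the whole track is shorter than
#'   `min_segment_duration` (returned as a single flagged segment).
#' @examples
#' t <- 0:50
#' pos <- c(cumsum(rep(0.6, 21)), rep(12.6, 10), 12.6 + cumsum(rep(0.3, 20)))
#' seg <- segment_track(data.frame(time_s = t, pos_um = c(0, pos)),
#'                      segmentation_params(smoothing_window = 1))
#' seg[, c("t_start_s", "t_end_s", "speed_um_s", "kind")]
#' @export
segment_track <- function(track, params = segmentation_params()) {
  stopifnot(is.data.frame(track),
            all(c("time_s", "pos_um") %in% names(track)))
  t <- track$time_s
  pos <- track$pos_um
  n <- length(t)
  if (n < 2 || any(diff(t) <= 0))
    stop("track needs >= 2 frames with strictly increasing times",
         call. = FALSE)

  dt <- diff(t)
  raw_speed <- diff(pos) / dt
  det_speed <- boxcar(raw_speed, params$smoothing_window)

  short_track <- (t[n] - t[1]) < params$min_segment_duration

  # bottom-up merge on interval groups; seg boundaries as interval index sets
  starts <- seq_len(n - 1)          # first interval of each segment
  ends <- seq_len(n - 1)            # last interval of each segment
  seg_dur <- dt
  seg_disp <- det_speed * dt        # detection-scale displacement
  repeat {
    k <- length(starts)
    if (k == 1) break
    v <- seg_disp / seg_dur
    dl <- abs(diff(v))
    vmax <- pmax(abs(v[-k]), abs(v[-1]))
    thr <- pmax(params$abs_speed_change, params$rel_speed_change * vmax)
    short <- seg_dur < params$min_segment_duration
    mergeable <- (dl < thr) | short[-k] | short[-1]
    if (!any(mergeable)) break
    cand <- which(mergeable)
    j <- cand[which.min(dl[cand])]
    ends[j] <- ends[j + 1]
    seg_dur[j] <- seg_dur[j] + seg_dur[j + 1]
    seg_disp[j] <- seg_disp[j] + seg_disp[j + 1]
    starts <- starts[-(j + 1)]
    ends <- ends[-(j + 1)]
    seg_dur <- seg_dur[-(j + 1)]
    seg_disp <- seg_disp[-(j + 1)]
  }

  # boundary refinement: smoothing smears change points by up to the boxcar
  # half-width, so each boundary may shift locally to the breakpoint that
  # minimizes the duration-weighted residual of the raw interval speeds
  halfw <- params$smoothing_window %/% 2 + 1L
  if (length(starts) > 1) {
    for (j in seq_len(length(starts) - 1)) {
      i0 <- starts[j]; i2 <- ends[j + 1]
      lo <- max(i0, ends[j] - halfw)
      hi <- min(i2 - 1L, ends[j] + halfw)
      # a shift must not squeeze either side below the minimum duration
      cum <- c(0, cumsum(dt))
      while (lo < ends[j] &&
             cum[lo + 1] - cum[i0] < params$min_segment_duration) lo <- lo + 1L
      while (hi > ends[j] &&
             cum[i2 + 1] - cum[hi + 1] < params$min_segment_duration) hi <- hi - 1L
      if (lo >= hi) next
      cost <- vapply(lo:hi, function(b) {
        ia <- i0:b; ib <- (b + 1):i2
        va <- sum(raw_speed[ia] * dt[ia]) / sum(dt[ia])
        vb <- sum(raw_speed[ib] * dt[ib]) / sum(dt[ib])
        sum(dt[ia] * (raw_speed[ia] - va)^2) +
          sum(dt[ib] * (raw_speed[ib] - vb)^2)
      }, numeric(1))
      b <- (lo:hi)[which.min(cost)]
      ends[j] <- b
      starts[j + 1] <- b + 1L
    }
    seg_dur <- vapply(seq_along(starts),
                      function(j) sum(dt[starts[j]:ends[j]]), numeric(1))
    seg_disp <- vapply(seq_along(starts),
                       function(j) sum(raw_speed[starts[j]:ends[j]] *
                                         dt[starts[j]:ends[j]]), numeric(1))
  }

  # classify on the eroded segment core: smoothing smears speed ramps across
  # boundaries by up to halfw intervals, so boundary intervals are excluded
  # from the mean when the segment is long enough to spare them
  core_speed <- function(j) {
    idx <- starts[j]:ends[j]
    k <- length(idx)
    drop <- min(halfw, (k - 1L) %/% 2L)
    if (drop > 0) idx <- idx[(drop + 1):(k - drop)]
    sum(raw_speed[idx] * dt[idx]) / sum(dt[idx])
  }
  core_v <- vapply(seq_along(starts), core_speed, numeric(1))
  kind <- ifelse(abs(core_v) < params$pause_speed_threshold, "pause", "run")

  # coalesce adjacent pauses
  keep_start <- c(TRUE, !(kind[-1] == "pause" & kind[-length(kind)] == "pause"))
  grp <- cumsum(keep_start)
  starts <- as.integer(tapply(starts, grp, function(i) i[1]))
  ends <- as.integer(tapply(ends, grp, function(i) i[length(i)]))
  kind <- as.character(tapply(kind, grp, function(k) k[1]))
  core_v <- vapply(seq_along(starts), core_speed, numeric(1))

  # sub-frame boundary placement: each boundary moves to the intersection of
  # the two flanking constant-speed lines (the vertex a rater would draw on
  # the kymograph), clamped to within one frame of the grid boundary; the
  # lines are anchored at the eroded-core centroid with the core slope
  k <- length(starts)
  b_t <- t[c(starts, ends[k] + 1L)]      # k+1 boundary times (grid)
  b_p <- pos[c(starts, ends[k] + 1L)]
  if (k > 1) {
    core_anchor <- function(j) {
      idx <- starts[j]:(ends[j] + 1L)    # frames of segment j
      m <- length(idx)
      drop <- min(halfw, (m - 2L) %/% 2L)
      if (drop > 0) idx <- idx[(drop + 1):(m - drop)]
      c(mean(t[idx]), mean(pos[idx]))
    }
    anchors <- vapply(seq_len(k), core_anchor, numeric(2))
    for (j in seq_len(k - 1)) {
      v1 <- core_v[j]; v2 <- core_v[j + 1]
      if (abs(v1 - v2) < 1e-9) next
      t1 <- anchors[1, j]; p1 <- anchors[2, j]
      t2 <- anchors[1, j + 1]; p2 <- anchors[2, j + 1]
      t_star <- (p2 - p1 + v1 * t1 - v2 * t2) / (v1 - v2)
      grid_t <- t[ends[j] + 1L]
      dt_here <- max(dt[max(ends[j], 1L)], dt[min(ends[j] + 1L, n - 1L)])
      if (abs(t_star - grid_t) <= dt_here &&
          t_star > b_t[j] && t_star < b_t[j + 2]) {
        b_t[j + 1] <- t_star
        b_p[j + 1] <- p1 + v1 * (t_star - t1)
      }
    }
  }
  t_start <- b_t[seq_len(k)]
  t_end <- b_t[seq_len(k) + 1L]
  d_start <- b_p[seq_len(k)]
  d_end <- b_p[seq_len(k) + 1L]
  out <- data.frame(
    t_start_s = as.numeric(t_start), t_end_s = as.numeric(t_end),
    d_start_um = as.numeric(d_start), d_end_um = as.numeric(d_end),
    speed_um_s = as.numeric((d_end - d_start) / (t_end - t_start)),
    kind = as.character(kind)
  )
  if ("track_id" %in% names(track))
    out <- cbind(track_id = track$track_id[1], out)
  rownames(out) <- NULL
  class(out) <- c("track_segments", "data.frame")
  attr(out, "short_track") <- short_track
  out
}

#' Reconstruct the piecewise-constant-speed track implied by a segmentation
#'
#' Inverse of [segment_track()] up to within-segment detail: positions sampled
#' at `frame_interval` move at each segment's constant speed. Useful for
#' idempotence checks and for rendering idealized kymographs.
#'
#' @param segments A `track_segments` data frame.
#' @param frame_interval Sampling interval, s.
#' @return Data frame `time_s`, `pos_um`.
#' @export
reconstruct_track <- function(segments, frame_interval = 1) {
  stopifnot(inherits(segments, "track_segments") || is.data.frame(segments))
  t0 <- segments$t_start_s[1]
  t1 <- segments$t_end_s[nrow(segments)]
  times <- seq(t0, t1, by = frame_interval)
  node_t <- c(segments$t_start_s, t1)
  node_p <- c(segments$d_start_um, segments$d_end_um[nrow(segments)])
  data.frame(time_s = times,
             pos_um = stats::approx(node_t, node_p, xout = times)$y)
}

#' Flag tracks with no appreciable net movement
#'
#' Organelles that do not move in the observation window are excluded from run
#' analysis; the criterion is net displacement below a threshold.
#'
#' @param track Data frame with `time_s` and either `pos_um` (1D) or
#'   `x_um`,`y_um` (2D).
#' @param min_net_displacement Threshold, um (default 1).
#' @return TRUE if the track is immobile.
#' @export
classify_immobile <- function(track, min_net_displacement = 1) {
  stopifnot(is.data.frame(track))
  n <- nrow(track)
  disp <- if (all(c("x_um", "y_um") %in% names(track))) {
    sqrt((track$x_um[n] - track$x_um[1])^2 +
           (track$y_um[n] - track$y_um[1])^2)
  } else if ("pos_um" %in% names(track)) {
    abs(track$pos_um[n] - track$pos_um[1])
  } else {
    stop("track must have `pos_um` or `x_um`,`y_um`", call. = FALSE)
  }
  disp < min_net_displacement
}
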