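#' Run-speed statistics of a segmented track
#'
#' Each run segment contributes its run speed s = l / t, with run length l the
#' unsigned net displacement and t the segment duration; runs are weighted
#' equally in the mean.
#'
#' @param segments A `track_segments` data frame from [segment_track()].
#' @return List with `mean_run_speed` (um/s, NA if no runs), `n_runs`, and
#'   `has_runs`.
#' @export
run_speed_stats <- function(segments) {
  runs <- segments[segments$kind == "run", , drop = FALSE]
  if (nrow(runs) == 0)
    return(list(mean_run_speed = NA_real_, n_runs = 0L, has_runs = FALSE))
  sp <- abs(runs$d_end_um - runs$d_start_um) /
    (runs$t_end_s - runs$t_start_s)
  list(mean_run_speed = mean(sp), n_runs = nrow(runs), has_runs = TRUE)
}

#' Pause statistics of a segmented track
#'
#' A pause is a segment moving slower than the pause threshold (0.1 um/s by
#' default in [segmentation_params()]). Frequency is events per minute of
#' observed time; the observed time is the full track duration, pauses
#' included.
#'
#' @param segments A `track_segments` data frame.
#' @param observed_time_s Observation window; defaults to the segmented span.
#' @return List with `pause_count`, `pause_freq_per_min`,
#'   `mean_pause_duration_s` (NA if no pauses).
#' @export
pause_stats <- function(segments, observed_time_s = NULL) {
  if (is.null(observed_time_s))
    observed_time_s <- segments$t_end_s[nrow(segments)] - segments$t_start_s[1]
  pauses <- segments[segments$kind == "pause", , drop = FALSE]
  n <- nrow(pauses)
  list(
    pause_count = n,
    pause_freq_per_min = n / (observed_time_s / 60),
    mean_pause_duration_s = if (n > 0)
      mean(pauses$t_end_s - pauses$t_start_s) else NA_real_
  )
}

#' Switch statistics of a segmented track
#'
#' A pause-or-speed switch is any change in speed along a track, i.e. every
#' boundary between consecutive segments (run-to-run speed change,
#' run-to-pause, pause-to-run), so `switch_count = n_segments - 1` exactly.
#'
#' @inheritParams pause_stats
#' @return List with `switch_count` and `switch_freq_per_min`.
#' @export
switch_stats <- function(segments, observed_time_s = NULL) {
  if (is.null(observed_time_s))
    observed_time_s <- segments$t_end_s[nrow(segments)] - segments$t_start_s[1]
  n <- nrow(segments) - 1L
  list(switch_count = n, switch_freq_per_min = n / (observed_time_s / 60))
}

# mean-displacement direction of a segment on the 2D track, looked up at the
# frames nearest the segment boundaries; NULL when degenerate
segment_direction <- function(track2d, t_start, t_end) {
  i0 <- which.min(abs(track2d$time_s - t_start))
  i1 <- which.min(abs(track2d$time_s - t_end))
  v <- c(track2d$x_um[i1] - track2d$x_um[i0],
         track2d$y_um[i1] - track2d$y_um[i0])
  if (sqrt(sum(v^2)) < 1e-12) return(NULL)
  v
}

#' Sharp-turn statistics of a 2D track
#'
#' A sharp turn is a post-pause resumption of movement at an angle exceeding
#' `angle_threshold` (default 90 degrees) to the previous run, the signature
#' of an organelle switching onto a crossing microtubule. For each pause
#' flanked by runs, the angle between the mean displacement directions of the
#' preceding and following runs is computed from the 2D trajectory; pauses at
#' a track boundary are not evaluable and are skipped. Optionally run-to-run
#' boundaries are evaluated too (off by default: directional changes are
#' scored at pauses).
#'
#' @param track2d Data frame `time_s`, `x_um`, `y_um`.
#' @param segments The `track_segments` of the same track's 1D reduction.
#' @param angle_threshold Degrees; angles strictly greater count as turns.
#' @param observed_time_s Observation window; defaults to the segmented span.
#' @param include_run_run Also evaluate run-to-run boundaries.
#' @return List with `sharp_turn_count`, `sharp_turn_freq_per_min`,
#'   `evaluable_count`, and `turn_angles_deg`.
#' @export
sharp_turn_stats <- function(track2d, segments, angle_threshold = 90,
                             observed_time_s = NULL,
                             include_run_run = FALSE) {
  stopifnot(all(c("time_s", "x_um", "y_um") %in% names(track2d)))
  if (is.null(observed_time_s))
    observed_time_s <- segments$t_end_s[nrow(segments)] - segments$t_start_s[1]
  n <- nrow(segments)
  angles <- numeric(0)
  if (n >= 3) {
    for (j in 2:(n - 1)) {
      is_pause_gap <- segments$kind[j] == "pause" &&
        segments$kind[j - 1] == "run" && segments$kind[j + 1] == "run"
      if (!is_pause_gap && !include_run_run) next
      if (!is_pause_gap) {
        if (!(segments$kind[j] == "run" && segments$kind[j - 1] == "run"))
          next
      }
      pre_j <- if (is_pause_gap) j - 1 else j - 1
      post_j <- if (is_pause_gap) j + 1 else j
      v1 <- segment_direction(track2d, segments$t_start_s[pre_j],
                              segments$t_end_s[pre_j])
      v2 <- segment_direction(track2d, segments$t_start_s[post_j],
                              segments$t_end_s[post_j])
      if (is.null(v1) || is.null(v2)) next
      cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
      angles <- c(angles, acos(pmin(pmax(cosang, -1), 1)) * 180 / pi)
    }
  }
  count <- sum(angles > angle_threshold)
  list(sharp_turn_count = count,
       sharp_turn_freq_per_min = count / (observed_time_s / 60),
       evaluable_count = length(angles),
       turn_angles_deg = angles)
}

#' Per-track motility statistics
#'
#' Convenience wrapper running the full per-track pipeline: 2D tracks are
#' reduced to 1D by arc length ([track_arc_length()]), segmented
#' ([segment_track()]), and summarized with run-speed, pause, switch and (2D
#' only) sharp-turn statistics. Immobile tracks (net displacement below
#' `min_net_displacement`) are flagged and their run statistics withheld.
#'
#' @param track One track: `time_s` plus `pos_um` or `x_um`,`y_um`.
#' @param params A [segmentation_params()].
#' @param angle_threshold Sharp-turn angle threshold, degrees.
#' @param min_net_displacement Immobility threshold, um.
#' @return One-row data frame with the fields of the per-track statistics,
#'   `observed_time_min`, `immobile` and `low_confidence` (observation window
#'   shorter than 30 s).
#' @export
track_stats <- function(track, params = segmentation_params(),
                        angle_threshold = 90, min_net_displacement = 1) {
  is2d <- all(c("x_um", "y_um") %in% names(track))
  tr1 <- if (is2d) {
    track_arc_length(track, smoothing_window = params$smoothing_window)
  } else {
    track
  }
  seg <- segment_track(tr1, params)
  dur <- seg$t_end_s[nrow(seg)] - seg$t_start_s[1]
  immobile <- classify_immobile(track, min_net_displacement)
  rs <- run_speed_stats(seg)
  ps <- pause_stats(seg, dur)
  sw <- switch_stats(seg, dur)
  st <- if (is2d) sharp_turn_stats(track, seg, angle_threshold, dur) else
    list(sharp_turn_count = NA_integer_, sharp_turn_freq_per_min = NA_real_,
         evaluable_count = NA_integer_)
  data.frame(
    track_id = if ("track_id" %in% names(track)) track$track_id[1] else NA,
    mean_run_speed = if (immobile) NA_real_ else rs$mean_run_speed,
    n_runs = rs$n_runs,
    pause_count = ps$pause_count,
    pause_freq = ps$pause_freq_per_min,
    mean_pause_duration = ps$mean_pause_duration_s,
    switch_count = sw$switch_count,
    switch_freq = sw$switch_freq_per_min,
    sharp_turn_count = st$sharp_turn_count,
    sharp_turn_freq = st$sharp_turn_freq_per_min,
    evaluable_pauses = st$evaluable_count,
    observed_time_min = dur / 60,
    immobile = immobile,
    low_confidence = dur < 30
  )
}

#' Aggregate per-track statistics to per-cell and per-condition summaries
#'
#' Cells contribute unweighted means over their tracks; conditions report the
#' grand mean and SEM over cells. Cells with fewer than `min_tracks` tracks
#' are excluded with a warning.
#'
#' @param stats Data frame of per-track statistics with columns `cell_id`,
#'   `condition`, and the numeric statistic columns to aggregate.
#' @param columns Character vector of statistic columns; defaults to all
#'   numeric columns except identifiers.
#' @param min_tracks Minimum tracks per cell (default 4).
#' @return List with `per_cell` (cell means) and `per_condition` (mean, sem,
#'   n_cells per condition and statistic, long format).
#' @export
aggregate_by_condition <- function(stats, columns = NULL, min_tracks = 4) {
  stopifnot(all(c("cell_id", "condition") %in% names(stats)))
  if (is.null(columns)) {
    columns <- setdiff(names(stats)[vapply(stats, is.numeric, logical(1))],
                       c("cell_id", "track_id"))
  }
  counts <- table(stats$cell_id)
  bad <- names(counts)[counts < min_tracks]
  if (length(bad)) {
    warning(sprintf("excluding %d cell(s) with < %d tracks: %s",
                    length(bad), min_tracks, paste(bad, collapse = ", ")),
            call. = FALSE)
    stats <- stats[!stats$cell_id %in% bad, , drop = FALSE]
  }
  if (!nrow(stats)) stop("no cells left after the minimum-track filter",
                         call. = FALSE)
  per_cell <- stats::aggregate(
    stats[columns], by = list(condition = stats$condition,
                              cell_id = stats$cell_id),
    FUN = function(x) mean(x, na.rm = TRUE))
  rows <- lapply(columns, function(col) {
    by_cond <- split(per_cell[[col]], per_cell$condition)
    do.call(rbind, lapply(names(by_cond), function(cond) {
      v <- by_cond[[cond]]
      v <- v[is.finite(v)]
      data.frame(condition = cond, statistic = col,
                 mean = mean(v), sem = stats::sd(v) / sqrt(length(v)),
                 n_cells = length(v))
    }))
  })
  list(per_cell = per_cell, per_condition = do.call(rbind, rows))
}

#' Percent change of a treated mean relative to control
#'
#' Reported so that a decrease is positive: 100 (control - treated) / control.
#'
#' @param control_mean,treated_mean Group means; control must be nonzero.
#' @return Percent change.
#' @examples
#' percent_change(0.70, 0.50)  # 29% speed decrease
#' @export
percent_change <- function(control_mean, treated_mean) {
  if (any(control_mean == 0)) stop("control mean must be nonzero",
                                   call. = FALSE)
  100 * (control_mean - treated_mean) / control_mean
}

#' Fold change of a treated mean over control
#' @inheritParams percent_change
#' @return treated / control.
#' @export
fold_change <- function(treated_mean, control_mean) {
  if (any(control_mean == 0)) stop("control mean must be nonzero",
                                   call. = FALSE)
  treated_mean / control_mean
}
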