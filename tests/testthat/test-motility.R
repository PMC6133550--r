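make_segments <- function(t0, t1, speed, kind) {
  d <- cumsum(c(0, speed * (t1 - t0)))
  out <- data.frame(t_start_s = t0, t_end_s = t1,
                    d_start_um = d[-length(d)], d_end_um = d[-1],
                    speed_um_s = speed, kind = kind)
  class(out) <- c("track_segments", "data.frame")
  out
}

test_that("run speed is l/t and runs are weighted equally", {
  one <- make_segments(0, 60, 0.5, "run")
  expect_equal(run_speed_stats(one)$mean_run_speed, 0.5)
  two <- make_segments(c(0, 30), c(30, 60), c(0.4, 0.6), c("run", "run"))
  expect_equal(run_speed_stats(two)$mean_run_speed, 0.5)
  expect_equal(run_speed_stats(two)$n_runs, 2)
  none <- make_segments(0, 60, 0.01, "pause")
  expect_false(run_speed_stats(none)$has_runs)
  expect_true(is.na(run_speed_stats(none)$mean_run_speed))
})

test_that("pause statistics count, rate and average pause segments", {
  const <- make_segments(0, 60, 0.5, "run")
  ps <- pause_stats(const)
  expect_equal(ps$pause_count, 0)
  expect_equal(ps$pause_freq_per_min, 0)
  expect_true(is.na(ps$mean_pause_duration_s))
  seg <- make_segments(c(0, 20, 30, 45, 55), c(20, 30, 45, 55, 60),
                       c(0.5, 0, 0.6, 0, 0.4),
                       c("run", "pause", "run", "pause", "run"))
  ps2 <- pause_stats(seg)
  expect_equal(ps2$pause_count, 2)
  expect_equal(ps2$pause_freq_per_min, 2)   # 2 pauses in a 60 s track
  expect_equal(ps2$mean_pause_duration_s, 10)
})

test_that("every segment boundary is a switch: count = n_segments - 1", {
  expect_equal(switch_stats(make_segments(0, 60, 0.5, "run"))$switch_count, 0)
  seg3 <- make_segments(c(0, 20, 40), c(20, 40, 60), c(0.6, 0.2, 0.6),
                        c("run", "run", "run"))
  expect_equal(switch_stats(seg3)$switch_count, 2)
  # invariant across random segmentations of simulated tracks
  cfg <- transport_sim_config(n_tracks = 10, dimensionality = 1, seed = 33)
  ts <- simulate_transport_tracks(cfg)
  for (id in 1:10) {
    seg <- segment_track(ts$tracks[ts$tracks$track_id == id, ])
    expect_equal(switch_stats(seg)$switch_count, nrow(seg) - 1)
  }
})

test_that("frequencies are invariant to the time unit used internally", {
  seg <- make_segments(c(0, 20, 30), c(20, 30, 60), c(0.5, 0, 0.4),
                       c("run", "pause", "run"))
  ps <- pause_stats(seg, observed_time_s = 60)
  expect_equal(ps$pause_freq_per_min, ps$pause_count / (60 / 60))
  sw <- switch_stats(seg, observed_time_s = 90)
  expect_equal(sw$switch_freq_per_min, sw$switch_count / 1.5)
})

test_that("turn angles classify collinear vs reversal resumptions", {
  seg <- make_segments(c(0, 20, 30), c(20, 30, 50), c(0.5, 0, 0.5),
                       c("run", "pause", "run"))
  straight <- data.frame(time_s = 0:50,
                         x_um = c(seq(0, 10, by = 0.5), rep(10, 10),
                                  10 + seq(0.5, 10, by = 0.5)),
                         y_um = 0)
  st <- sharp_turn_stats(straight, seg)
  expect_equal(st$evaluable_count, 1)
  expect_equal(st$sharp_turn_count, 0)
  expect_lt(max(st$turn_angles_deg), 1)
  reversal <- data.frame(time_s = 0:50,
                         x_um = c(seq(0, 10, by = 0.5), rep(10, 10),
                                  10 - seq(0.5, 10, by = 0.5)),
                         y_um = 0)
  st2 <- sharp_turn_stats(reversal, seg)
  expect_equal(st2$sharp_turn_count, 1)
  expect_gt(min(st2$turn_angles_deg), 179)
})

test_that("a pause at the track boundary is skipped, not counted", {
  seg <- make_segments(c(0, 20), c(20, 30), c(0.5, 0), c("run", "pause"))
  tr <- data.frame(time_s = 0:30,
                   x_um = c(seq(0, 10, by = 0.5), rep(10, 10)), y_um = 0)
  st <- sharp_turn_stats(tr, seg)
  expect_equal(st$evaluable_count, 0)
  expect_equal(st$sharp_turn_count, 0)
})

test_that("simulated sharp-turn fraction is recovered among evaluable pauses", {
  cfg <- transport_sim_config(sharp_turn_prob = 0.5, n_tracks = 200,
                              speed_switch_rate = 0, seed = 61)
  ts <- simulate_transport_tracks(cfg)
  totals <- c(turns = 0, evaluable = 0)
  for (id in unique(ts$tracks$track_id)) {
    tr <- ts$tracks[ts$tracks$track_id == id, ]
    st <- track_stats(tr)
    totals["turns"] <- totals["turns"] + st$sharp_turn_count
    totals["evaluable"] <- totals["evaluable"] + st$evaluable_pauses
  }
  frac <- totals[["turns"]] / totals[["evaluable"]]
  expect_equal(frac, 0.5, tolerance = 0.14)  # 0.5 +/- 0.07 absolute
})

test_that("aggregation gives cell means then condition mean with SEM over cells", {
  stats <- data.frame(
    cell_id = rep(c("c1", "c2"), each = 4),
    condition = "ctrl",
    pause_freq = c(1, 3, 2, 2, 4, 4, 4, 4)
  )
  agg <- aggregate_by_condition(stats, columns = "pause_freq")
  expect_equal(sort(agg$per_cell$pause_freq), c(2, 4))
  expect_equal(agg$per_condition$mean, 3)
  expect_equal(agg$per_condition$sem, 1)
  expect_equal(agg$per_condition$n_cells, 2)
})

test_that("aggregation matches a hand-computed three-cell fixture", {
  stats <- data.frame(
    cell_id = rep(c("a", "b", "c"), times = c(4, 5, 4)),
    condition = rep(c("ctrl", "ctrl", "map7"), times = c(4, 5, 4)),
    speed = c(0.6, 0.8, 0.7, 0.5, 0.4, 0.5, 0.6, 0.5, 0.5, 0.3, 0.4, 0.35, 0.35)
  )
  agg <- aggregate_by_condition(stats, columns = "speed")
  ctrl <- agg$per_condition[agg$per_condition$condition == "ctrl", ]
  # cell means: a = 0.65, b = 0.5 -> mean 0.575, sem = sd/sqrt(2)
  expect_equal(ctrl$mean, mean(c(0.65, 0.5)))
  expect_equal(ctrl$sem, stats::sd(c(0.65, 0.5)) / sqrt(2))
  map7 <- agg$per_condition[agg$per_condition$condition == "map7", ]
  expect_equal(map7$mean, mean(c(0.3, 0.4, 0.35, 0.35)))
  expect_equal(map7$n_cells, 1)
})

test_that("cells below the minimum track count are excluded with a warning", {
  stats <- data.frame(cell_id = c(rep("ok", 4), rep("thin", 2)),
                      condition = "ctrl", speed = c(1, 1, 1, 1, 9, 9))
  expect_warning(agg <- aggregate_by_condition(stats, columns = "speed"),
                 "thin")
  expect_equal(agg$per_condition$mean, 1)
})

test_that("percent and fold changes reproduce the published speed effects", {
  expect_equal(round(percent_change(0.70, 0.50)), 29)
  expect_equal(round(percent_change(0.55, 0.35)), 36)
  expect_equal(percent_change(0.4, 0.4), 0)
  expect_equal(fold_change(2.44, 1.39), 2.44 / 1.39)
  expect_error(percent_change(0, 1), "nonzero")
  expect_error(fold_change(1, 0), "nonzero")
})

test_that("mean run speed over control-like tracks is recovered within 5%", {
  # clean regime: no localization noise, pauses well above the segmentation
  # floor, so s = l/t per detected run is an unbiased read of the draw
  cfg <- transport_sim_config(n_tracks = 200, localization_noise_sd = 0,
                              pause_duration_min = 6, dimensionality = 1,
                              seed = 88)
  ts <- simulate_transport_tracks(cfg)
  est <- mean(vapply(split(ts$tracks, ts$tracks$track_id), function(tr)
    run_speed_stats(segment_track(tr))$mean_run_speed, numeric(1)),
    na.rm = TRUE)
  expect_equal(est, 0.70, tolerance = 0.05)
})

test_that("estimated frequencies are concordant with generative rates on a 3x3 grid", {
  pause_rates <- c(1, 3, 6)
  switch_rates <- c(0.5, 2, 4)
  grid <- expand.grid(pr = pause_rates, sr = switch_rates)
  est <- t(vapply(seq_len(nrow(grid)), function(i) {
    # run speeds spread well clear of the 30% change criterion so that a
    # speed redraw is usually a resolvable event
    cfg <- transport_sim_config(pause_rate = grid$pr[i],
                                speed_switch_rate = grid$sr[i],
                                run_speed_sd = 0.3,
                                n_tracks = 160, dimensionality = 1,
                                seed = 7000 + i)
    ts <- simulate_transport_tracks(cfg)
    per <- vapply(split(ts$tracks, ts$tracks$track_id), function(tr) {
      seg <- segment_track(tr)
      c(pause_stats(seg)$pause_freq_per_min,
        switch_stats(seg)$switch_freq_per_min)
    }, numeric(2))
    rowMeans(per)
  }, numeric(2)))
  # pause frequency ordered by pause rate within every switch rate
  for (sr in switch_rates) {
    sel <- grid$sr == sr
    expect_equal(stats::cor(grid$pr[sel], est[sel, 1], method = "kendall"), 1)
  }
  # switch frequency ordered by switch rate within every pause rate
  for (pr in pause_rates) {
    sel <- grid$pr == pr
    expect_equal(stats::cor(grid$sr[sel], est[sel, 2], method = "kendall"), 1)
  }
})
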