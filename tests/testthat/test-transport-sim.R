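test_that("with no pauses or switches every track is one constant-speed run", {
  cfg <- transport_sim_config(pause_rate = 0, speed_switch_rate = 0,
                              localization_noise_sd = 0, n_tracks = 5,
                              dimensionality = 2, seed = 4)
  ts <- simulate_transport_tracks(cfg)
  for (id in 1:5) {
    tr <- ts$tracks[ts$tracks$track_id == id, ]
    ev <- ts$events[ts$events$track_id == id, ]
    v <- ev$speed_um_s[ev$event == "run_start"][1]
    disp <- sqrt((tr$x_um[nrow(tr)] - tr$x_um[1])^2 +
                   (tr$y_um[nrow(tr)] - tr$y_um[1])^2)
    expect_equal(disp, v * cfg$track_duration, tolerance = 1e-9)
    step <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2) / diff(tr$time_s)
    expect_equal(step, rep(v, nrow(tr) - 1), tolerance = 1e-9)
  }
})

test_that("mean ground-truth pause count follows the renewal expectation", {
  cfg <- transport_sim_config(pause_rate = 3, pause_duration_mean = 1,
                              track_duration = 120, n_tracks = 200,
                              speed_switch_rate = 0, seed = 21)
  ts <- simulate_transport_tracks(cfg)
  counts <- vapply(split(ts$events, ts$events$track_id),
                   function(e) sum(e$event == "pause_start"), numeric(1))
  # alternating renewal: cycle = Exp(1/20 s) run + Exp(1 s) pause
  expectation <- 120 / (60 / 3 + 1)
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expectation), 0.5 + 3 * se)
})

test_that("sharp turns occur only with nonzero sharp_turn_prob", {
  cfg0 <- transport_sim_config(sharp_turn_prob = 0, n_tracks = 40, seed = 9)
  ts0 <- simulate_transport_tracks(cfg0)
  ang0 <- ts0$events$turn_angle_deg[!is.na(ts0$events$turn_angle_deg)]
  expect_true(length(ang0) > 20)
  expect_true(all(ang0 <= 90))
  cfg1 <- transport_sim_config(sharp_turn_prob = 1, n_tracks = 40, seed = 9)
  ts1 <- simulate_transport_tracks(cfg1)
  ang1 <- ts1$events$turn_angle_deg[!is.na(ts1$events$turn_angle_deg)]
  expect_true(all(ang1 > 90))
})

test_that("identical seeds give identical track sets", {
  cfg <- transport_sim_config(n_tracks = 3, seed = 123)
  a <- simulate_transport_tracks(cfg)
  b <- simulate_transport_tracks(cfg)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$events, b$events)
})

test_that("invalid dimensionality is rejected", {
  expect_error(transport_sim_config(dimensionality = 3), "dimensionality")
})

test_that("1D tracks carry arc positions and no heading changes", {
  cfg <- transport_sim_config(n_tracks = 3, dimensionality = 1, seed = 6)
  ts <- simulate_transport_tracks(cfg)
  expect_true("pos_um" %in% names(ts$tracks))
  expect_false("x_um" %in% names(ts$tracks))
})

test_that("estimated pause frequency increases with the generative pause rate", {
  rates <- c(0.5, 2, 5)
  means <- vapply(rates, function(r) {
    cfg <- transport_sim_config(pause_rate = r, n_tracks = 60,
                                dimensionality = 1, seed = 300 + round(10 * r))
    ts <- simulate_transport_tracks(cfg)
    mean(vapply(split(ts$tracks, ts$tracks$track_id), function(tr) {
      pause_stats(segment_track(tr))$pause_freq_per_min
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  # rank correlation against per-track rates, strict at p < 0.01
  cfgs <- rep(rates, each = 60)
  vals <- unlist(lapply(rates, function(r) {
    cfg <- transport_sim_config(pause_rate = r, n_tracks = 60,
                                dimensionality = 1, seed = 300 + round(10 * r))
    ts <- simulate_transport_tracks(cfg)
    vapply(split(ts$tracks, ts$tracks$track_id), function(tr) {
      pause_stats(segment_track(tr))$pause_freq_per_min
    }, numeric(1))
  }))
  ct <- suppressWarnings(stats::cor.test(cfgs, vals, method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("noise-free segmentation recovers resolvable event counts on >= 95% of tracks", {
  # rates well separated from the segmentation thresholds: pauses at least
  # three times the minimum segment duration, no speed switches, no noise
  cfg <- transport_sim_config(pause_rate = 2, pause_duration_mean = 20,
                              pause_duration_min = 6, speed_switch_rate = 0,
                              localization_noise_sd = 0, n_tracks = 100,
                              dimensionality = 1, seed = 14)
  ts <- simulate_transport_tracks(cfg)
  res <- resolvable_events(ts, segmentation_params())
  # upper bound: every ground-truth pause of resolvable duration, counting
  # pauses separated by sub-floor runs individually (the detector may or may
  # not split those; both readings are consistent with the data)
  upper <- vapply(split(ts$events, ts$events$track_id), function(e) {
    e <- e[order(e$time_s), ]
    st <- which(e$event == "pause_start")
    sum(vapply(st, function(s) {
      nxt <- e$time_s[e$time_s > e$time_s[s] &
                        e$event %in% c("pause_end", "track_end")]
      length(nxt) > 0 && min(nxt) - e$time_s[s] >= 2
    }, logical(1)))
  }, numeric(1))
  hits <- vapply(seq_len(cfg$n_tracks), function(id) {
    tr <- ts$tracks[ts$tracks$track_id == id, ]
    est <- pause_stats(segment_track(tr))$pause_count
    est >= res$pause_count[res$track_id == id] && est <= upper[id]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
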