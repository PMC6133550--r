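straight_arbor <- function(len = 500, step = 5) {
  n <- len / step + 1
  arbor(data.frame(id = 1:n, type = c(1L, rep(2L, n - 1)),
                   x = seq(0, len, by = step), y = 0, z = 0, radius = 0.5,
                   parent = c(-1L, 1:(n - 1))))
}

# trunk 100 um along x, then two limbs (300 and 200 um) from the fork
y_tree <- function() {
  nodes <- data.frame(id = 1:4, type = c(1L, 2L, 2L, 2L),
                      x = c(0, 100, 100 + 300 / sqrt(2), 100 + 200 / sqrt(2)),
                      y = c(0, 0, 300 / sqrt(2), -200 / sqrt(2)),
                      z = 0, radius = 0.5, parent = c(-1L, 1L, 2L, 2L))
  arbor(nodes)
}

test_that("main axon of a straight trace is the whole path", {
  ma <- main_axon(straight_arbor(500))
  expect_equal(ma$length, 500, tolerance = 1e-9)
  expect_equal(length(ma$node_ids), 101)
})

test_that("main axon of a Y-tree is trunk plus the longer limb", {
  ar <- y_tree()
  ma <- main_axon(ar)
  expect_equal(ma$length, 400, tolerance = 1e-9)
  expect_equal(ma$tip_id, 3)
  expect_equal(ma$length, oracle_longest_path(as.data.frame(ar)),
               tolerance = 1e-12)
})

test_that("main axon equals exhaustive path enumeration on random trees", {
  set.seed(19)
  for (rep in 1:8) {
    n <- sample(10:50, 1)
    nodes <- data.frame(id = 1, type = 1L, x = 0, y = 0, z = 0, radius = 0.5,
                        parent = -1L)
    for (i in 2:n) {
      nodes <- rbind(nodes, data.frame(
        id = i, type = 2L,
        x = stats::rnorm(1, 0, 30), y = stats::rnorm(1, 0, 30),
        z = stats::rnorm(1, 0, 5), radius = 0.5,
        parent = sample(i - 1, 1)))
    }
    ar <- arbor(nodes)
    expect_equal(main_axon(ar)$length, oracle_longest_path(nodes),
                 tolerance = 1e-9)
  }
})

test_that("simulated arbors recover requested branch counts and main axon length", {
  cfg <- arbor_sim_config(main_axon_length = 500,
                          interstitial_branch_count = 5,
                          terminal_branch_count = 2, seed = 11)
  ar <- simulate_arbor(cfg)
  ms <- morph_stats(ar)
  expect_equal(ms$main_axon_length_um, 500, tolerance = 1e-6)
  expect_equal(ms$n_interstitial, 5)
  expect_equal(ms$n_terminal, 2)
  truth <- attr(ar, "truth")
  recs <- ms$records[order(ms$records$origin_um), ]
  tt <- truth[order(truth$origin_um), ]
  expect_equal(recs$origin_um, tt$origin_um, tolerance = 1e-6)
  expect_equal(recs$length_um, tt$length_um, tolerance = 1e-6)
  expect_equal(recs$class, tt$label)
})

test_that("an unbranched simulated axon reports zero branches", {
  ar <- simulate_arbor(arbor_sim_config(interstitial_branch_count = 0,
                                        terminal_branch_count = 0, seed = 2))
  ms <- morph_stats(ar)
  expect_equal(ms$n_branches, 0)
  expect_equal(ms$n_interstitial, 0)
  expect_equal(ms$n_terminal, 0)
})

test_that("branches at or below the counting threshold are dropped", {
  # main axon 100 um with side branches of 8, 12 and 40 um
  base <- straight_arbor(100, step = 5)
  n0 <- nrow(base)
  extra <- data.frame(
    id = n0 + 1:3, type = 2L,
    x = c(20, 50, 80), y = c(40, 12, 8), z = 0, radius = 0.5,
    parent = c(which(base$x == 20), which(base$x == 50), which(base$x == 80)))
  ar <- arbor(rbind(as.data.frame(base), extra))
  recs <- enumerate_branches(ar, min_length = 10)
  expect_equal(nrow(recs), 2)
  expect_equal(sort(recs$length_um), c(12, 40), tolerance = 1e-9)
  # raising the threshold never increases the count
  counts <- vapply(c(5, 10, 15, 45), function(m)

    nrow(enumerate_branches(ar, min_length = m)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("terminal/interstitial split respects the distal-10% rule", {
  recs <- data.frame(branch_root_id = 1:3,
                     origin_um = c(0.5, 0.9, 0.95) * 500,
                     length_um = c(30, 30, 30), n_tips = 1L)
  cls <- classify_branches(recs, main_axon_length = 500)
  # exactly at the 90% boundary counts as interstitial
  expect_equal(cls$n_interstitial, 2)
  expect_equal(cls$n_terminal, 1)
  expect_equal(cls$records$class, c("interstitial", "interstitial",
                                    "terminal"))
})

test_that("branch length summary matches direct computation", {
  recs <- data.frame(branch_root_id = 1:2, origin_um = c(10, 20),
                     length_um = c(20, 40), n_tips = 1L)
  bl <- branch_length_stats(recs)
  expect_equal(bl$mean_um, 30)
  expect_equal(bl$sem_um, stats::sd(c(20, 40)) / sqrt(2))
  empty <- branch_length_stats(recs[0, ])
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$mean_um))
})

test_that("morphometry is invariant under rigid motion of the trace", {
  ar <- simulate_arbor(arbor_sim_config(seed = 23))
  ms <- morph_stats(ar)
  th <- 0.83
  rot <- as.data.frame(ar)
  x <- rot$x * cos(th) - rot$y * sin(th) + 42
  y <- rot$x * sin(th) + rot$y * cos(th) - 17
  rot$x <- x; rot$y <- y
  ms2 <- morph_stats(arbor(rot))
  expect_equal(ms2$main_axon_length_um, ms$main_axon_length_um,
               tolerance = 1e-9)
  expect_equal(ms2$n_interstitial, ms$n_interstitial)
  expect_equal(ms2$n_terminal, ms$n_terminal)
  expect_equal(sort(ms2$branch_lengths_um), sort(ms$branch_lengths_um),
               tolerance = 1e-9)
})

test_that("higher-order daughters contribute tips to their first-order branch", {
  base <- straight_arbor(100, step = 10)
  n0 <- nrow(base)
  # branch at x = 50 that bifurcates 15 um out into two 15 um daughters
  extra <- data.frame(
    id = n0 + 1:3, type = 2L,
    x = c(50, 65, 35), y = c(15, 30, 30), z = 0, radius = 0.5,
    parent = c(which(base$x == 50), n0 + 1, n0 + 1))
  ar <- arbor(rbind(as.data.frame(base), extra))
  recs <- enumerate_branches(ar, min_length = 10)
  expect_equal(nrow(recs), 1)       # one first-order branch
  expect_equal(recs$n_tips, 2)      # two qualifying tips
  cls <- classify_branches(recs, main_axon(ar)$length)
  expect_equal(cls$n_branches, 2)
})

test_that("line-scan analysis recovers peak-over-background ratios", {
  flat <- data.frame(position = 1:50, intensity = rep(100, 50))
  expect_equal(line_scan_peak_ratio(flat)$ratio, 1)
  pr <- simulate_line_scan(peak_height = 150, baseline = 100, noise_sd = 0,
                           length = 120, seed = 8)
  res <- line_scan_peak_ratio(pr, smoothing_window = 1)
  expect_equal(res$ratio, 2.5, tolerance = 1e-6)
  expect_equal(res$ratio, attr(pr, "truth")$ratio, tolerance = 1e-6)
  # peak equal to baseline doubles the signal
  pr2 <- simulate_line_scan(peak_height = 100, baseline = 100, noise_sd = 0,
                            length = 120, seed = 9)
  expect_equal(line_scan_peak_ratio(pr2, smoothing_window = 1)$ratio, 2,
               tolerance = 1e-6)
  # absent peak: ratio 1 by ground truth
  pr3 <- simulate_line_scan(peak_height = 0, baseline = 80, noise_sd = 0,
                            length = 60, seed = 10)
  expect_equal(attr(pr3, "truth")$ratio, 1)
  expect_equal(line_scan_peak_ratio(pr3, smoothing_window = 1)$ratio, 1)
})

test_that("malformed arbors are rejected", {
  expect_error(arbor(data.frame(id = 1:2, type = 2L, x = 0, y = 0, z = 0,
                                radius = 0.5, parent = c(-1L, 5L))),
               "unknown parent")
  expect_error(arbor(data.frame(id = 1:2, type = 2L, x = 0, y = 0, z = 0,
                                radius = 0.5, parent = c(2L, 1L))),
               "root")
})
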