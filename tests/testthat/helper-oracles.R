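# Independent oracles used across the suite. These deliberately use naive
# exhaustive algorithms so they share no code with the package's estimators.

# exhaustive minimum-cost change-point search on a 1D track: tries every
# placement of 0..max_breaks breakpoints between frame intervals and returns
# the boundary frame indices of the smallest model (fewest segments) whose
# duration-weighted residual of interval speeds is below eps
oracle_changepoints <- function(time_s, pos_um, max_breaks = 2, eps = 1e-9) {
  dt <- diff(time_s)
  v <- diff(pos_um) / dt
  m <- length(v)
  seg_cost <- function(a, b) {
    idx <- a:b
    vbar <- sum(v[idx] * dt[idx]) / sum(dt[idx])
    sum(dt[idx] * (v[idx] - vbar)^2)
  }
  for (k in 0:max_breaks) {
    best <- NULL
    best_cost <- Inf
    combs <- if (k == 0) list(integer(0)) else
      utils::combn(seq_len(m - 1), k, simplify = FALSE)
    for (br in combs) {
      bounds <- c(0, br, m)
      cost <- sum(vapply(seq_len(length(bounds) - 1), function(i)
        seg_cost(bounds[i] + 1, bounds[i + 1]), numeric(1)))
      if (cost < best_cost) {
        best_cost <- cost
        best <- br
      }
    }
    if (best_cost < eps) return(list(breaks = best, cost = best_cost))
  }
  list(breaks = best, cost = best_cost)
}

# exhaustive soma-to-tip path enumeration over an SWC-style node table;
# returns the maximum cumulative path length over all tips
oracle_longest_path <- function(nodes) {
  pidx <- match(nodes$parent, nodes$id)
  tips <- which(!(nodes$id %in% nodes$parent))
  best <- 0
  for (tip in tips) {
    len <- 0
    j <- tip
    while (!is.na(pidx[j])) {
      p <- pidx[j]
      len <- len + sqrt((nodes$x[j] - nodes$x[p])^2 +
                          (nodes$y[j] - nodes$y[p])^2 +
                          (nodes$z[j] - nodes$z[p])^2)
      j <- p
    }
    best <- max(best, len)
  }
  best
}

# two-sided permutation p-value for a difference in means
oracle_permutation_p <- function(a, b, n_perm = 20000, seed = 99) {
  set.seed(seed)
  obs <- abs(mean(a) - mean(b))
  pooled <- c(a, b)
  na <- length(a)
  hits <- 0
  for (i in seq_len(n_perm)) {
    idx <- sample(length(pooled), na)
    d <- abs(mean(pooled[idx]) - mean(pooled[-idx]))
    if (d >= obs - 1e-12) hits <- hits + 1
  }
  hits / n_perm
}

# piecewise-constant-speed 1D track builder: phases = data.frame(speed, dur)
make_phase_track <- function(phases, frame_interval = 1, t0 = 0) {
  node_t <- c(0, cumsum(phases$dur))
  node_p <- c(0, cumsum(phases$speed * phases$dur))
  times <- seq(0, sum(phases$dur), by = frame_interval)
  data.frame(time_s = t0 + times,
             pos_um = stats::approx(node_t, node_p, xout = times)$y)
}
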