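#' Configuration for a simulated neuronal arbor
#'
#' Generates a rooted tree emulating a cultured sensory neuron: one main axon
#' (soma to growth cone), interstitial branches attaching uniformly along the
#' proximal 90% of the main axon, and terminal branches along the distal 10%.
#' Branch lengths are drawn from a truncated normal bounded below by
#' `min_branch_length` and above so that no branch path overtakes the main
#' axon.
#'
#' @param main_axon_length Length of the main axon, um.
#' @param interstitial_branch_count,terminal_branch_count Branch counts.
#' @param branch_length_mean,branch_length_sd Branch length distribution, um.
#' @param min_branch_length Lower bound on branch lengths, um (default 12,
#'   above the 10 um counting threshold so requested branches are countable).
#' @param node_spacing Spacing of trace nodes along neurites, um.
#' @param seed Integer seed.
#' @return An object of class `arbor_sim_config`.
#' @export
arbor_sim_config <- function(main_axon_length = 500,
                             interstitial_branch_count = 5,
                             terminal_branch_count = 2,
                             branch_length_mean = 40,
                             branch_length_sd = 15,
                             min_branch_length = 12,
                             node_spacing = 5,
                             seed = 1L) {
  stopifnot(main_axon_length > 0, interstitial_branch_count >= 0,
            terminal_branch_count >= 0, branch_length_mean > 0,
            branch_length_sd >= 0, min_branch_length > 0, node_spacing > 0)
  structure(list(main_axon_length = main_axon_length,
                 interstitial_branch_count =
                   as.integer(interstitial_branch_count),
                 terminal_branch_count = as.integer(terminal_branch_count),
                 branch_length_mean = branch_length_mean,
                 branch_length_sd = branch_length_sd,
                 min_branch_length = min_branch_length,
                 node_spacing = node_spacing,
                 seed = as.integer(seed)),
            class = "arbor_sim_config")
}

#' Simulate a traced neuronal arbor with ground-truth branch labels
#'
#' The main axon runs along +x from the soma at the origin. Interstitial
#' branch origins are uniform on (0, 0.9 L); terminal branch origins are
#' uniform on (0.9 L, L). A node is inserted on the main axon at every branch
#' origin so origin arc positions are exact. Branches extend straight at a
#' random oblique angle; their lengths are truncated-normal draws capped so
#' the soma-to-tip path through any branch stays shorter than the main axon
#' (the main axon remains the longest path by construction).
#'
#' @param config An [arbor_sim_config()].
#' @return An `arbor` (SWC-style data frame, see [arbor()]) with attribute
#'   `truth`: the per-branch origin arc positions, lengths and
#'   interstitial/terminal labels.
#' @export
simulate_arbor <- function(config) {
  stopifnot(inherits(config, "arbor_sim_config"))
  set.seed(config$seed)
  L <- config$main_axon_length

  n_int <- config$interstitial_branch_count
  n_term <- config$terminal_branch_count
  # terminal origins stay proximal enough that a minimum-length branch still
  # fits without the soma-to-branch-tip path overtaking the main axon
  term_hi <- max(0.9 * L + 2e-6, L - config$min_branch_length - 1)
  origins <- c(if (n_int > 0) stats::runif(n_int, 1e-3, 0.9 * L),
               if (n_term > 0) stats::runif(n_term, 0.9 * L + 1e-6, term_hi))
  labels <- c(rep("interstitial", n_int), rep("terminal", n_term))

  # main-axon node arc positions: regular spacing plus exact branch origins
  arcs <- sort(unique(c(seq(0, L, by = config$node_spacing), L, origins)))
  n_axon <- length(arcs)
  nodes <- data.frame(
    id = seq_len(n_axon),
    type = c(1L, rep(2L, n_axon - 1)),
    x = arcs, y = 0, z = 0, radius = 0.5,
    parent = c(-1L, seq_len(n_axon - 1))
  )
  next_id <- n_axon

  lengths <- numeric(length(origins))
  for (b in seq_along(origins)) {
    o <- origins[b]
    # cap so soma->branch-tip (= o + len) stays strictly below L
    cap <- L - o - 1e-3
    len <- NA_real_
    for (try in 1:200) {
      cand <- stats::rnorm(1, config$branch_length_mean,
                           config$branch_length_sd)
      if (cand >= config$min_branch_length && cand < cap) {
        len <- cand
        break
      }
    }
    if (is.na(len)) len <- max(config$min_branch_length, min(cap * 0.9, 1e-3))
    lengths[b] <- len
    attach_id <- nodes$id[match(o, nodes$x[seq_len(n_axon)])]
    ang <- stats::runif(1, 30, 150) * sample(c(-1, 1), 1) * pi / 180
    n_seg <- max(1L, ceiling(len / config$node_spacing))
    step <- len / n_seg
    parent <- attach_id
    for (s in seq_len(n_seg)) {
      next_id <- next_id + 1L
      nodes <- rbind(nodes, data.frame(
        id = next_id, type = 2L,
        x = o + s * step * cos(ang),
        y = s * step * sin(ang), z = 0, radius = 0.5,
        parent = parent))
      parent <- next_id
    }
  }

  ar <- arbor(nodes)
  attr(ar, "truth") <- data.frame(
    origin_um = origins, length_um = lengths, label = labels,
    stringsAsFactors = FALSE
  )
  ar
}
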