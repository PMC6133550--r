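#' Traced neuronal arbor
#'
#' SWC-style rooted tree: one row per trace node with 3D position (um) and a
#' parent pointer; the root (parent -1) is the soma. Edge lengths are the
#' Euclidean distances between a node and its parent.
#'
#' @param nodes Data frame with columns `id`, `type`, `x`, `y`, `z`, `radius`,
#'   `parent`. Exactly one root (`parent == -1`); every other parent must be a
#'   known id; no cycles (validated).
#' @return An object of class `arbor` (a validated data frame).
#' @export
arbor <- function(nodes) {
  req <- c("id", "type", "x", "y", "z", "radius", "parent")
  stopifnot(is.data.frame(nodes), all(req %in% names(nodes)))
  nodes <- nodes[req]
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  roots <- which(nodes$parent == -1)
  if (length(roots) != 1)
    stop("arbor must have exactly one root (parent -1)", call. = FALSE)
  known <- nodes$parent %in% c(-1, nodes$id)
  if (!all(known))
    stop("unknown parent id(s): ", paste(nodes$parent[!known], collapse = ", "),
         call. = FALSE)
  # cycle/connectivity check: walk to root from every node
  pidx <- match(nodes$parent, nodes$id)
  n <- nrow(nodes)
  for (i in seq_len(n)) {
    j <- i; steps <- 0
    while (!is.na(pidx[j])) {
      j <- pidx[j]; steps <- steps + 1
      if (steps > n) stop("cycle detected in arbor", call. = FALSE)
    }
    if (j != roots) stop("arbor is not connected to the root", call. = FALSE)
  }
  class(nodes) <- c("arbor", "data.frame")
  nodes
}

# per-node cumulative path length from the root, plus helper indices
arbor_geometry <- function(ar) {
  pidx <- match(ar$parent, ar$id)
  edge_len <- ifelse(is.na(pidx), 0,
                     sqrt((ar$x - ar$x[pidx])^2 + (ar$y - ar$y[pidx])^2 +
                            (ar$z - ar$z[pidx])^2))
  # accumulate root-down: process nodes in order of increasing depth
  n <- nrow(ar)
  depth <- integer(n)
  for (i in seq_len(n)) {
    j <- i; d <- 0
    while (!is.na(pidx[j])) { j <- pidx[j]; d <- d + 1 }
    depth[i] <- d
  }
  ord <- order(depth)
  dist_root <- numeric(n)
  for (i in ord) {
    dist_root[i] <- if (is.na(pidx[i])) 0 else dist_root[pidx[i]] + edge_len[i]
  }
  is_tip <- !(ar$id %in% ar$parent)
  list(pidx = pidx, edge_len = edge_len, dist_root = dist_root,
       is_tip = is_tip, root = which(ar$parent == -1))
}

path_to_root <- function(geom, i) {
  path <- i
  while (!is.na(geom$pidx[i])) {
    i <- geom$pidx[i]
    path <- c(path, i)
  }
  rev(path)
}

#' Main axon of an arbor
#'
#' The main axon is the longest path from the cell body (soma, the root) to a
#' growth cone (a tip), by cumulative trace length. Ties are broken toward the
#' smallest tip id so the result is deterministic.
#'
#' @param ar An [arbor()].
#' @return List with `node_ids` (soma to tip), `length` (um) and
#'   `tip_id`.
#' @export
main_axon <- function(ar) {
  stopifnot(inherits(ar, "arbor"))
  geom <- arbor_geometry(ar)
  tips <- which(geom$is_tip)
  if (!length(tips)) stop("arbor has no tips", call. = FALSE)
  best_len <- max(geom$dist_root[tips])
  cand <- tips[geom$dist_root[tips] == best_len]
  tip <- cand[which.min(ar$id[cand])]
  path <- path_to_root(geom, tip)
  list(node_ids = ar$id[path], length = best_len, tip_id = ar$id[tip])
}

#' Enumerate first-order branches off the main axon
#'
#' A branch is the maximal subtree rooted at a child of a main-axon node that
#' is itself off the main axon; its origin is the arc position of the
#' attachment node along the main axon, its length the longest path from the
#' attachment to any of its tips, and its tip count the number of subtree tips
#' farther than `min_length` from the attachment (higher-order daughters
#' contribute tips to their first-order branch rather than forming new
#' records). Records whose length does not exceed `min_length` (branches not
#' longer than 10 um, by default) are dropped.
#'
#' @param ar An [arbor()].
#' @param min_length Minimum branch length, um (default 10).
#' @return Data frame with one row per qualifying branch: `branch_root_id`,
#'   `origin_um` (arc position of the attachment on the main axon),
#'   `length_um`, `n_tips`.
#' @export
enumerate_branches <- function(ar, min_length = 10) {
  stopifnot(inherits(ar, "arbor"), min_length >= 0)
  geom <- arbor_geometry(ar)
  ma <- main_axon(ar)
  on_axon <- ar$id %in% ma$node_ids
  axon_idx <- which(on_axon)
  # children of main-axon nodes that are off the axon
  child_of_axon <- which(!is.na(geom$pidx) & on_axon[geom$pidx] & !on_axon)
  if (!length(child_of_axon)) {
    return(data.frame(branch_root_id = integer(0), origin_um = numeric(0),
                      length_um = numeric(0), n_tips = integer(0)))
  }
  # subtree membership: first-order branch root reached on the walk to root
  branch_of <- rep(NA_integer_, nrow(ar))
  for (i in seq_len(nrow(ar))) {
    j <- i
    while (!is.na(geom$pidx[j]) && !on_axon[j]) {
      if (j %in% child_of_axon) break
      j <- geom$pidx[j]
    }
    if (!on_axon[i] && j %in% child_of_axon) branch_of[i] <- j
  }
  recs <- lapply(child_of_axon, function(b) {
    members <- which(branch_of == b)
    attach <- geom$pidx[b]
    tips <- members[geom$is_tip[members]]
    tip_dist <- geom$dist_root[tips] - geom$dist_root[attach]
    data.frame(branch_root_id = ar$id[b],
               origin_um = geom$dist_root[attach],
               length_um = max(tip_dist),
               n_tips = sum(tip_dist > min_length))
  })
  recs <- do.call(rbind, recs)
  recs <- recs[recs$length_um > min_length, , drop = FALSE]
  rownames(recs) <- NULL
  recs
}

#' Classify branches as terminal or interstitial
#'
#' Branches emerging from the distal 10% of the main axon are terminal; those
#' from the proximal 90% are interstitial (collateral). A branch exactly at
#' the 90% boundary counts as interstitial. Counts are in qualifying tips, so
#' a bifurcated branch contributes each of its tips.
#'
#' @param records Branch records from [enumerate_branches()].
#' @param main_axon_length Main axon length, um.
#' @return List with `n_terminal`, `n_interstitial`, `n_branches`
#'   (their sum), and the `records` with a `class` column added.
#' @export
classify_branches <- function(records, main_axon_length) {
  stopifnot(main_axon_length > 0)
  if (!nrow(records)) {
    return(list(n_terminal = 0L, n_interstitial = 0L, n_branches = 0L,
                records = cbind(records, class = character(0))))
  }
  cls <- ifelse(records$origin_um > 0.9 * main_axon_length,
                "terminal", "interstitial")
  records$class <- cls
  list(n_terminal = sum(records$n_tips[cls == "terminal"]),
       n_interstitial = sum(records$n_tips[cls == "interstitial"]),
       n_branches = sum(records$n_tips),
       records = records)
}

#' Branch length summary
#'
#' Mean, SEM and n of qualifying branch lengths (branches longer than the
#' counting threshold, as filtered by [enumerate_branches()]).
#'
#' @param records Branch records from [enumerate_branches()].
#' @return List with `mean_um`, `sem_um`, `n`; all NA with `n = 0` when no
#'   branch qualifies.
#' @export
branch_length_stats <- function(records) {
  n <- nrow(records)
  if (!n) return(list(mean_um = NA_real_, sem_um = NA_real_, n = 0L))
  list(mean_um = mean(records$length_um),
       sem_um = if (n > 1) stats::sd(records$length_um) / sqrt(n) else
         NA_real_,
       n = n)
}

#' Full morphometry of an arbor
#'
#' @param ar An [arbor()].
#' @param min_branch_length Counting threshold, um.
#' @return List of class `morph_stats`: `main_axon_length_um`, `n_branches`,
#'   `n_terminal`, `n_interstitial`, `branch_lengths_um`, and the branch
#'   `records`.
#' @export
morph_stats <- function(ar, min_branch_length = 10) {
  ma <- main_axon(ar)
  recs <- enumerate_branches(ar, min_branch_length)
  cls <- classify_branches(recs, ma$length)
  structure(list(main_axon_length_um = ma$length,
                 n_branches = cls$n_branches,
                 n_terminal = cls$n_terminal,
                 n_interstitial = cls$n_interstitial,
                 branch_lengths_um = recs$length_um,
                 records = cls$records),
            class = "morph_stats")
}

#' @export
print.morph_stats <- function(x, ...) {
  cat(sprintf("arbor morphometry: main axon %.1f um; %d branches (%d interstitial, %d terminal)\n",
              x$main_axon_length_um, x$n_branches, x$n_interstitial,
              x$n_terminal))
  invisible(x)
}
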