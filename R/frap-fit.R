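#' Raw three-region FRAP trace
#'
#' Container for per-frame mean intensities of the bleached region, an
#' unbleached reference region and a background region around a bleach event.
#' The first post-bleach frame defines t = 0; pre-bleach frames have negative
#' times.
#'
#' @param times Frame times in seconds, strictly increasing; exactly
#'   `n_pre_frames` of them are negative.
#' @param f_bleached,f_unbleached,f_background Per-frame mean intensities
#'   (a.u.), same length as `times`.
#' @param n_pre_frames Number of pre-bleach frames (>= 1).
#' @param exclude_mask Logical per-frame mask; `TRUE` flags out-of-focus frames
#'   that are dropped from normalization and fitting.
#' @return A data frame of class `frap_trace` with columns `time_s`,
#'   `f_bleached`, `f_unbleached`, `f_background`, `is_prebleach`, `exclude`.
#' @export
frap_trace <- function(times, f_bleached, f_unbleached, f_background,
                       n_pre_frames, exclude_mask = NULL) {
  n <- length(times)
  if (n < 2 || any(diff(times) <= 0))
    stop("`times` must be strictly increasing with >= 2 frames", call. = FALSE)
  if (length(f_bleached) != n || length(f_unbleached) != n ||
      length(f_background) != n)
    stop("all three intensity series must match `times` in length",
         call. = FALSE)
  n_pre_frames <- as.integer(n_pre_frames)
  if (n_pre_frames < 1) stop("`n_pre_frames` must be >= 1", call. = FALSE)
  if (is.null(exclude_mask)) exclude_mask <- rep(FALSE, n)
  stopifnot(is.logical(exclude_mask), length(exclude_mask) == n)
  is_pre <- seq_len(n) <= n_pre_frames
  n_post_included <- sum(!is_pre & !exclude_mask)
  if (n_post_included < 3)
    stop("need at least 3 included post-bleach frames", call. = FALSE)
  out <- data.frame(
    time_s = as.numeric(times),
    f_bleached = as.numeric(f_bleached),
    f_unbleached = as.numeric(f_unbleached),
    f_background = as.numeric(f_background),
    is_prebleach = is_pre,
    exclude = exclude_mask
  )
  class(out) <- c("frap_trace", "data.frame")
  out
}

#' Normalize a FRAP trace to a percent recovery curve
#'
#' Applies the standard double-normalization: the background signal is
#' subtracted from the bleached and unbleached signals of the same frame, the
#' corrected bleached signal is divided by the corrected unbleached reference,
#' and the resulting ratio C(t) is mapped to percent recovery
#' \deqn{recovery(t) = 100 \, (C(t) - F_0) / (F_{pre} - F_0)}
#' where \eqn{F_{pre}} is the mean of C over the pre-bleach frames and
#' \eqn{F_0} is C at the first included post-bleach frame (the fluorescence
#' immediately after photobleaching, t = 0). Frames flagged in the exclude
#' mask (out-of-focus) are dropped before any of this.
#'
#' @param trace A [frap_trace()].
#' @return A data frame of class `recovery_curve` with columns `t` (seconds
#'   since bleach) and `recovery` (percent); `recovery[t == 0]` is 0 by
#'   construction.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  keep <- !trace$exclude
  tr <- trace[keep, , drop = FALSE]
  ref <- tr$f_unbleached - tr$f_background
  if (any(ref <= 0))
    stop("corrected unbleached reference is non-positive; bad reference region",
         call. = FALSE)
  corrected <- (tr$f_bleached - tr$f_background) / ref
  pre <- tr$is_prebleach
  f_pre <- mean(corrected[pre])
  post_idx <- which(!pre)
  f0 <- corrected[post_idx[1]]
  denom <- f_pre - f0
  if (!is.finite(denom) || abs(denom) < 1e-12)
    stop("no bleach detected: pre-bleach and post-bleach signals coincide",
         call. = FALSE)
  t0 <- tr$time_s[post_idx[1]]
  out <- data.frame(
    t = tr$time_s[post_idx] - t0,
    recovery = 100 * (corrected[post_idx] - f0) / denom
  )
  class(out) <- c("recovery_curve", "data.frame")
  out
}

#' Fit the single-exponential recovery model to a recovery curve
#'
#' Least-squares fit of \eqn{R(t) = A (1 - e^{-k_{off} t})} with the initial
#' recovery fixed at 0 for t = 0 and the plateau bounded above by the maximum
#' recovery of 100 (0 < A <= 100, k_off > 0), as appropriate for a
#' diffusion-uncoupled binding reaction. A is reported as the total recovery
#' (mobile fraction); the half-life is the exact identity t1/2 = ln 2 / k_off.
#' Standard errors come from the curvature of the least-squares surface;
#' optionally a seeded residual bootstrap replaces them when the curvature is
#' ill-conditioned.
#'
#' @param curve A `recovery_curve` from [normalize_trace()], or any data frame
#'   with columns `t` (>= 0, seconds) and `recovery` (percent).
#' @param bootstrap_se Either `FALSE` (default: curvature-based standard
#'   errors) or an integer number of residual-bootstrap replicates.
#' @param seed Seed used only for the bootstrap.
#' @return An object of class `frap_fit`: a list with elements `k_off`,
#'   `t_half`, `total_recovery`, `se_k_off`, `se_total_recovery`, `rss`,
#'   `n_points`, `converged`.
#' @examples
#' t <- 0:40
#' curve <- data.frame(t = t, recovery = 74 * (1 - exp(-0.27 * t)))
#' fit <- fit_recovery(curve)
#' c(fit$k_off, fit$total_recovery, fit$t_half)
#' @export
fit_recovery <- function(curve, bootstrap_se = FALSE, seed = 1L) {
  stopifnot(is.data.frame(curve), all(c("t", "recovery") %in% names(curve)))
  t <- curve$t
  y <- curve$recovery
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 3) stop("need >= 3 points to fit", call. = FALSE)
  if (any(t < 0)) stop("recovery-curve times must be >= 0", call. = FALSE)
  if (all(abs(y) < 1e-12))
    stop("all-zero recovery curve: nothing to fit", call. = FALSE)

  # initial guesses: plateau from the tail, rate from the time to half-plateau
  a0 <- min(max(y[which.max(t)], 1), 100)
  half_idx <- which(y >= a0 / 2 & t > 0)
  k0 <- if (length(half_idx)) log(2) / t[min(half_idx)] else 1 / max(t)
  k0 <- max(k0, 1e-6)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * (1 - exp(-k * t)),
      start = list(A = a0, k = k0),
      lower = c(A = 1e-8, k = 1e-10),
      upper = c(A = 100, k = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )

  if (is.null(fit)) {
    out <- list(k_off = NA_real_, t_half = NA_real_,
                total_recovery = NA_real_, se_k_off = NA_real_,
                se_total_recovery = NA_real_, rss = NA_real_,
                n_points = length(t), converged = FALSE)
    class(out) <- "frap_fit"
    return(out)
  }

  est <- stats::coef(fit)
  ses <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(NA, NA))
  if (!isFALSE(bootstrap_se) || any(!is.finite(ses))) {
    n_boot <- if (isFALSE(bootstrap_se)) 500L else as.integer(bootstrap_se)
    if (n_boot > 0 && (!isFALSE(bootstrap_se) || any(!is.finite(ses)))) {
      ses <- boot_se_recovery(t, y, est, n_boot, seed)
    }
  }
  rss <- sum(stats::resid(fit)^2)
  out <- list(
    k_off = unname(est["k"]),
    t_half = log(2) / unname(est["k"]),
    total_recovery = unname(est["A"]),
    se_k_off = unname(ses[2]),
    se_total_recovery = unname(ses[1]),
    rss = rss,
    n_points = length(t),
    converged = fit$convInfo$isConv
  )
  class(out) <- "frap_fit"
  out
}

# residual bootstrap (A, k) SEs; returns c(se_A, se_k)
boot_se_recovery <- function(t, y, est, n_boot, seed) {
  set.seed(seed)
  fitted <- est["A"] * (1 - exp(-est["k"] * t))
  res <- y - fitted
  reps <- matrix(NA_real_, n_boot, 2)
  for (b in seq_len(n_boot)) {
    yb <- fitted + sample(res, length(res), replace = TRUE)
    fb <- tryCatch(
      minpack.lm::nlsLM(yb ~ A * (1 - exp(-k * t)),
                        start = list(A = unname(est["A"]), k = unname(est["k"])),
                        lower = c(A = 1e-8, k = 1e-10), upper = c(A = 100, k = Inf)),
      error = function(e) NULL
    )
    if (!is.null(fb)) reps[b, ] <- stats::coef(fb)
  }
  apply(reps, 2, stats::sd, na.rm = TRUE)
}

#' @export
print.frap_fit <- function(x, ...) {
  cat("FRAP fit (single-site binding):\n")
  cat(sprintf("  k_off          %.4g 1/s (SE %.3g)\n", x$k_off, x$se_k_off))
  cat(sprintf("  t_half         %.4g s\n", x$t_half))
  cat(sprintf("  total recovery %.3g %% (SE %.3g)\n",
              x$total_recovery, x$se_total_recovery))
  cat(sprintf("  rss %.4g on %d points; converged: %s\n",
              x$rss, x$n_points, x$converged))
  invisible(x)
}

#' Recovery half-life from a dissociation rate constant
#'
#' For a diffusion-uncoupled binding reaction the FRAP recovery half-life and
#' the dissociation rate constant are tied by t1/2 = ln 2 / k_off; the map is
#' its own inverse (k_off = ln 2 / t1/2).
#'
#' @param k_off Dissociation rate constant(s), 1/s, positive.
#' @return Half-life in seconds (or k_off if given a half-life; the identity
#'   is symmetric).
#' @examples
#' t_half_from_koff(0.27)        # ~2.6 s
#' t_half_from_koff(log(2))      # 1 s
#' @export
t_half_from_koff <- function(k_off) {
  if (!is.numeric(k_off) || any(!is.finite(k_off)) || any(k_off <= 0))
    stop("`k_off` must be positive and finite", call. = FALSE)
  log(2) / k_off
}
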