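#' Simulate a line-scan intensity profile with one peak over baseline
#'
#' A flat baseline plus a single Gaussian peak at a random position (kept away
#' from the profile edges), with optional additive Gaussian noise. Emulates a
#' fluorescence intensity profile read along a line drawn across a
#' microtubule: the peak is the decorated microtubule, the baseline the
#' cytoplasmic signal.
#'
#' @param peak_height Peak amplitude above baseline, a.u. (>= 0).
#' @param baseline Baseline intensity, a.u. (> 0).
#' @param noise_sd Additive Gaussian noise, a.u.
#' @param length Number of samples (>= 5).
#' @param peak_sd Peak width (Gaussian sd) in samples.
#' @param seed Integer seed.
#' @return Data frame of class `intensity_profile` with columns `position`
#'   (sample index) and `intensity`; attribute `truth` holds the generating
#'   peak position and the ground-truth peak/background ratio
#'   `(baseline + peak_height) / baseline`.
#' @export
simulate_line_scan <- function(peak_height, baseline, noise_sd = 0,
                               length = 100, peak_sd = NULL, seed = 1L) {
  stopifnot(baseline > 0, peak_height >= 0, noise_sd >= 0, length >= 5)
  if (is.null(peak_sd)) peak_sd <- max(length / 25, 1.5)
  set.seed(seed)
  pos <- seq_len(length)
  center <- round(stats::runif(1, 0.2 * length, 0.8 * length))
  intensity <- baseline + peak_height * exp(-(pos - center)^2 / (2 * peak_sd^2))
  if (noise_sd > 0) intensity <- intensity + stats::rnorm(length, 0, noise_sd)
  out <- data.frame(position = pos, intensity = intensity)
  class(out) <- c("intensity_profile", "data.frame")
  attr(out, "truth") <- list(center = center,
                             ratio = (baseline + peak_height) / baseline)
  out
}

#' Peak-to-background ratio of a line-scan profile
#'
#' The profile is lightly boxcar-smoothed; the peak is its maximum, the
#' background the median of samples outside the peak's half-maximum support
#' (the contiguous region around the maximum where the smoothed profile stays
#' above half the peak value). A flat profile — no samples outside the
#' support — returns ratio 1.
#'
#' @param profile Data frame with columns `position` and `intensity`
#'   (>= 5 samples).
#' @param smoothing_window Boxcar width in samples (default 3; 1 disables).
#' @return List with `ratio`, `peak`, `background`, `peak_position`.
#' @export
line_scan_peak_ratio <- function(profile, smoothing_window = 3) {
  stopifnot(is.data.frame(profile),
            all(c("position", "intensity") %in% names(profile)),
            nrow(profile) >= 5)
  y <- boxcar(profile$intensity, smoothing_window)
  imax <- which.max(y)
  peak <- y[imax]
  # half-maximum measured above a preliminary baseline (the profile median),
  # i.e. half prominence, so a peak comparable to the baseline still has a
  # bounded support
  half <- stats::median(y) + (peak - stats::median(y)) / 2
  lo <- imax
  while (lo > 1 && y[lo - 1] >= half) lo <- lo - 1
  hi <- imax
  while (hi < length(y) && y[hi + 1] >= half) hi <- hi + 1
  outside <- setdiff(seq_along(y), lo:hi)
  if (!length(outside)) {
    return(list(ratio = 1, peak = peak, background = peak,
                peak_position = profile$position[imax]))
  }
  bg <- stats::median(y[outside])
  list(ratio = peak / bg, peak = peak, background = bg,
       peak_position = profile$position[imax])
}
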