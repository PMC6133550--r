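#' Configuration for a simulated FRAP experiment
#'
#' Bundles the ground-truth binding parameters and acquisition settings used by
#' [simulate_frap_trace()]. The underlying model is a diffusion-uncoupled
#' single-site binding reaction, for which the normalized recovery follows
#' \deqn{R(t) = A (1 - e^{-k_{off} t})}
#' with plateau `A` equal to the mobile fraction (in percent) and `k_off` the
#' dissociation rate constant of the bleached species.
#'
#' @param k_off_true Dissociation rate constant, 1/s. Must be positive.
#' @param mobile_fraction_true Mobile fraction in percent, in (0, 100]. The
#'   noiseless recovery curve plateaus at this value.
#' @param frame_interval Time between frames, s.
#' @param n_pre_frames Number of pre-bleach frames (>= 1).
#' @param n_post_frames Number of post-bleach frames (>= 2); the first
#'   post-bleach frame defines t = 0.
#' @param bleach_depth Fraction of the pre-bleach corrected signal destroyed by
#'   the bleach pulse, in (0, 1].
#' @param noise_sd Per-frame additive Gaussian noise, arbitrary units, applied
#'   independently to the bleached, unbleached and background raw signals.
#' @param background_level Constant camera background added to all regions, a.u.
#' @param acquisition_bleach_rate Rate (1/s) of whole-field acquisition
#'   photobleaching applied to the unbleached reference (and to the bleached
#'   region's binding-site pool), so the reference-normalization step is
#'   exercised. Default 0.
#' @param prebleach_intensity Corrected pre-bleach fluorescence of both regions
#'   above background, a.u. Sets the raw-signal scale; the dynamic range of the
#'   bleached-region signal is `prebleach_intensity * bleach_depth`.
#' @param seed Integer seed; every simulated trace is reproducible from it.
#' @return An object of class `frap_sim_config` (a validated list).
#' @seealso [simulate_frap_trace()]
#' @export
frap_sim_config <- function(k_off_true,
                            mobile_fraction_true,
                            frame_interval = 1,
                            n_pre_frames = 5,
                            n_post_frames = 60,
                            bleach_depth = 0.8,
                            noise_sd = 0,
                            background_level = 50,
                            acquisition_bleach_rate = 0,
                            prebleach_intensity = 1000,
                            seed = 1L) {
  stopifnot(
    is.numeric(k_off_true), length(k_off_true) == 1, k_off_true > 0,
    is.numeric(mobile_fraction_true), length(mobile_fraction_true) == 1,
    mobile_fraction_true > 0, mobile_fraction_true <= 100
  )
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("`frame_interval` must be positive", call. = FALSE)
  if (n_pre_frames < 1) stop("`n_pre_frames` must be >= 1", call. = FALSE)
  if (n_post_frames < 2) stop("`n_post_frames` must be >= 2", call. = FALSE)
  if (bleach_depth <= 0 || bleach_depth > 1)
    stop("`bleach_depth` must be in (0, 1]", call. = FALSE)
  stopifnot(noise_sd >= 0, background_level >= 0, acquisition_bleach_rate >= 0,
            prebleach_intensity > 0)
  structure(
    list(
      k_off_true = k_off_true,
      mobile_fraction_true = mobile_fraction_true,
      frame_interval = frame_interval,
      n_pre_frames = as.integer(n_pre_frames),
      n_post_frames = as.integer(n_post_frames),
      bleach_depth = bleach_depth,
      noise_sd = noise_sd,
      background_level = background_level,
      acquisition_bleach_rate = acquisition_bleach_rate,
      prebleach_intensity = prebleach_intensity,
      seed = as.integer(seed)
    ),
    class = "frap_sim_config"
  )
}

#' Simulate a three-region FRAP intensity trace
#'
#' Constructs raw per-frame mean intensities for a bleached region, an
#' unbleached reference region and a background region around a bleach event,
#' such that the standard normalization (background subtraction, reference
#' ratio, recovery equation; see [normalize_trace()]) recovers the latent
#' recovery curve \eqn{R(t) = A (1 - e^{-k_{off} t})} exactly in the
#' zero-noise limit.
#'
#' Time is indexed so that the first post-bleach frame is t = 0; pre-bleach
#' frames carry negative times. Acquisition photobleaching, when enabled,
#' decays both regions' binding-site pools identically and so cancels in the
#' reference ratio.
#'
#' @param config A [frap_sim_config()] object.
#' @return A [frap_trace()] object with attribute `truth` carrying the
#'   generating parameters.
#' @examples
#' cfg <- frap_sim_config(k_off_true = log(2), mobile_fraction_true = 100,
#'                        noise_sd = 0, seed = 7)
#' tr <- simulate_frap_trace(cfg)
#' curve <- normalize_trace(tr)
#' curve$recovery[curve$t == 1]  # 50% at one half-life
#' @export
simulate_frap_trace <- function(config) {
  stopifnot(inherits(config, "frap_sim_config"))
  set.seed(config$seed)
  n_pre <- config$n_pre_frames
  n_post <- config$n_post_frames
  dt <- config$frame_interval
  times <- c(seq(-n_pre, -1) * dt, seq(0, n_post - 1) * dt)
  n <- length(times)

  # latent corrected ratio C(t): 1 before the bleach, then recovery from the
  # post-bleach floor back toward 1 with plateau set by the mobile fraction
  post <- times >= 0
  f_pre_ratio <- 1
  f0_ratio <- f_pre_ratio * (1 - config$bleach_depth)
  recovery <- config$mobile_fraction_true *
    (1 - exp(-config$k_off_true * times[post])) / 100
  ratio <- rep(f_pre_ratio, n)
  ratio[post] <- f0_ratio + (f_pre_ratio - f0_ratio) * recovery

  # acquisition bleaching decays the reference pool from the first frame on
  elapsed <- times - times[1]
  reference <- config$prebleach_intensity *
    exp(-config$acquisition_bleach_rate * elapsed)

  bg <- rep(config$background_level, n)
  f_unbleached <- reference + bg
  f_bleached <- ratio * reference + bg

  if (config$noise_sd > 0) {
    f_bleached <- f_bleached + stats::rnorm(n, 0, config$noise_sd)
    f_unbleached <- f_unbleached + stats::rnorm(n, 0, config$noise_sd)
    bg <- bg + stats::rnorm(n, 0, config$noise_sd)
  }

  tr <- frap_trace(
    times = times,
    f_bleached = f_bleached,
    f_unbleached = f_unbleached,
    f_background = bg,
    n_pre_frames = n_pre
  )
  attr(tr, "truth") <- list(
    k_off = config$k_off_true,
    total_recovery = config$mobile_fraction_true,
    config = config
  )
  tr
}
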