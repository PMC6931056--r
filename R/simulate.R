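# Synthetic sagittal-plane gait signal generator.
#
# One stride = stance (quiet) + positive mid-swing lobe + sharp negative
# deceleration lobe. Only the deceleration minimum (value and timing) is
# contractual; the rest of the shape is a plausible stand-in for real ankle
# gyroscope morphology.

# stride layout as fractions of the stride duration
SWING_START <- 0.35
SWING_END   <- 0.65
DECEL_POS   <- 0.80
DECEL_FWHM  <- 0.080  # seconds; width of the deceleration lobe

#' Single synthetic stride waveform
#'
#' Builds one stride of sagittal angular velocity: zeros during stance, a
#' raised-cosine swing lobe of amplitude `swing_amp` peaking mid-stride, and
#' a Gaussian-shaped deceleration lobe (80 ms full width at half maximum)
#' centred at 80% of the stride whose minimum equals `peak_av` exactly at
#' the nearest sample.
#'
#' @param peak_av requested heel-strike peak angular velocity in deg/s
#'   (strictly negative).
#' @param stride_duration stride duration in seconds (> 0).
#' @param sample_rate sampling rate in Hz.
#' @param swing_amp amplitude of the positive swing lobe in deg/s.
#' @return Numeric vector of `round(stride_duration * sample_rate)` samples.
#'   The index of the deceleration minimum is attached as attribute
#'   `heel_strike_index`.
#' @export
#' @examples
#' w <- stride_waveform(-300, 1.2, 100)
#' length(w); min(w)
stride_waveform <- function(peak_av, stride_duration, sample_rate,
                            swing_amp = 200) {
  if (!is.numeric(peak_av) || length(peak_av) != 1 || peak_av >= 0) {
    gait_config_error("peak_av must be strictly negative (deceleration)")
  }
  if (!is.numeric(stride_duration) || stride_duration <= 0) {
    gait_config_error("stride_duration must be > 0")
  }
  n <- round(stride_duration * sample_rate)
  if (n < 4) gait_config_error("stride too short for the sample rate")
  i <- seq_len(n)
  f <- (i - 1) / n                         # fraction of stride, 0-based
  w <- numeric(n)
  sw <- f >= SWING_START & f <= SWING_END
  w[sw] <- swing_amp *
    0.5 * (1 - cos(2 * pi * (f[sw] - SWING_START) / (SWING_END - SWING_START)))
  centre <- max(2L, min(n, round(DECEL_POS * n)))
  sigma_samp <- (DECEL_FWHM / 2.3548) * sample_rate
  w <- w + peak_av * exp(-((i - centre)^2) / (2 * sigma_samp^2))
  attr(w, "heel_strike_index") <- centre
  w
}

#' Ground truth accompanying a simulated session
#'
#' @description Constructed by [simulate_session()]; fields:
#' `heel_strike_times` (s, strictly increasing), `true_peak_av` (deg/s, the
#' realized noise-free deceleration minima), `is_good` (logical; `TRUE` iff
#' the realized peak crosses the profile's classification threshold), and
#' `bout_intervals` (two-column matrix of walking-interval start/end in s).
#' @name gait_truth
NULL

#' Simulate a walking session with known ground truth
#'
#' Generates a full IMU recording following a [gait_profile()]: for each
#' bout in `bout_plan`, strides at the profile cadence (with Gaussian
#' stride-time jitter) are laid down until the walking interval is full,
#' then the rest interval contains sensor noise only. Per-step peaks are
#' drawn `Normal(av_mean, av_sd)` for good-morphology steps and attenuated
#' by `bad_attenuation` for bad ones; draws that come out non-negative are
#' clamped to -1 deg/s (a foot always decelerates a little). Ground-truth
#' `is_good` is recomputed from the realized peak against
#' `profile$threshold_av`, so the stored flags always satisfy the
#' classification rule.
#'
#' The generator owns a private random stream: it seeds from `profile$seed`,
#' consumes draws in a fixed order (per step: timing jitter, morphology
#' uniform, peak normal; then one noise draw per channel), and restores the
#' caller's RNG state on exit. Two calls with the same profile are
#' bitwise-identical.
#'
#' @param profile a [gait_profile()].
#' @param sample_rate sampling rate in Hz (default 100).
#' @return A list with elements `series` (an [imu_series()]) and `truth`
#'   (a `gait_truth` list, see [gait_truth]).
#' @export
#' @examples
#' sim <- simulate_session(gait_profile(bout_plan = list(c(30, 0)), seed = 7))
#' length(sim$truth$heel_strike_times)
simulate_session <- function(profile, sample_rate = 100) {
  stopifnot(inherits(profile, "gait_profile"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(profile$seed)

  fs <- sample_rate
  nominal <- 60 / profile$cadence
  segments <- list()
  hs_idx <- integer(0)
  peak <- numeric(0)
  bout_iv <- matrix(numeric(0), ncol = 2,
                    dimnames = list(NULL, c("start", "end")))
  offset <- 0L  # samples laid down so far

  for (b in profile$bout_plan) {
    n_walk <- round(b[1] * fs)
    n_rest <- round(b[2] * fs)
    walk <- numeric(n_walk)
    cum <- 0L
    repeat {
      dur <- nominal * (1 + stats::rnorm(1, 0, profile$stride_jitter_cv))
      dur <- max(dur, 0.5 * nominal)            # guard absurd jitter draws
      L <- round(dur * fs)
      if (cum + L > n_walk) break
      good_morph <- stats::runif(1) < profile$p_good
      p <- stats::rnorm(1, profile$av_mean, profile$av_sd)
      if (!good_morph) p <- p * profile$bad_attenuation
      if (p >= 0) p <- -1
      w <- stride_waveform(p, L / fs, fs, swing_amp = profile$swing_amp)
      walk[(cum + 1):(cum + L)] <- w
      hs_idx <- c(hs_idx, offset + cum + attr(w, "heel_strike_index"))
      peak <- c(peak, p)
      cum <- cum + L
    }
    segments[[length(segments) + 1]] <- walk
    bout_iv <- rbind(bout_iv, c(offset / fs, (offset + n_walk) / fs))
    offset <- offset + n_walk
    if (n_rest > 0) {
      segments[[length(segments) + 1]] <- numeric(n_rest)
      offset <- offset + n_rest
    }
  }

  av <- unlist(segments, use.names = FALSE)
  n <- length(av)
  gyro <- cbind(
    x = 0.20 * av + stats::rnorm(n, 0, profile$noise_sd),
    y = av + stats::rnorm(n, 0, profile$noise_sd),
    z = 0.10 * av + stats::rnorm(n, 0, profile$noise_sd)
  )
  # accelerometer channels are plausible filler only (no ground-truth contract)
  accel <- cbind(
    x = 0.010 * abs(av) + stats::rnorm(n, 0, 0.2),
    y = 9.81 + 0.005 * abs(av) + stats::rnorm(n, 0, 0.2),
    z = 0.005 * av + stats::rnorm(n, 0, 0.2)
  )

  truth <- structure(
    list(heel_strike_times = (hs_idx - 1) / fs,
         true_peak_av = peak,
         is_good = peak <= profile$threshold_av,
         bout_intervals = bout_iv),
    class = "gait_truth"
  )
  list(series = imu_series(gyro, accel, fs), truth = truth)
}
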