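#' Generative profile for synthetic walking
#'
#' Bundles the parameters of the synthetic sagittal-plane gait simulator.
#' Each step contributes one stride waveform: a quiet stance phase, a
#' positive mid-swing lobe, and a sharp negative deceleration lobe whose
#' minimum is the step's heel-strike angular-velocity peak. Steps are
#' generated "good" (full deceleration, peak drawn from
#' `Normal(av_mean, av_sd)`) with probability `p_good`, otherwise "bad"
#' (foot-flat morphology: the same draw attenuated by `bad_attenuation`).
#'
#' @param cadence steps per minute (> 0). One stride waveform per step.
#' @param av_mean mean heel-strike peak angular velocity in deg/s; must be
#'   negative (deceleration).
#' @param av_sd between-step SD of the peak in deg/s (>= 0).
#' @param p_good probability that a step is generated with good (heel-first)
#'   morphology, in [0, 1].
#' @param bad_attenuation factor in (0, 1] scaling the deceleration peak of
#'   bad (foot-flat) steps. Default 0.4: foot-flat contact still decelerates
#'   the foot, just weakly.
#' @param swing_amp amplitude of the positive mid-swing lobe in deg/s (> 0).
#' @param noise_sd SD of additive white sensor noise in deg/s (>= 0).
#' @param bout_plan list of `c(walk, rest)` durations in seconds; rest
#'   intervals contain noise only. Default: one 120 s walk, no rest.
#' @param threshold_av classification threshold used to label ground-truth
#'   steps, deg/s (negative). Default -90, matching [detection_config()].
#' @param stride_jitter_cv stride-to-stride timing jitter as a fraction of
#'   the stride duration (Gaussian, default 0.03), so cadence is recovered
#'   as an average rather than exactly.
#' @param seed integer seed for the simulator's private random stream.
#' @return A list of class `gait_profile`.
#' @seealso [simulate_session()], [profile_from_reference()]
#' @export
gait_profile <- function(cadence = 100, av_mean = -150, av_sd = 22.5,
                         p_good = 0.8, bad_attenuation = 0.4,
                         swing_amp = 200, noise_sd = 5,
                         bout_plan = list(c(120, 0)),
                         threshold_av = -90, stride_jitter_cv = 0.03,
                         seed = 1L) {
  if (!is.numeric(cadence) || cadence <= 0) gait_config_error("cadence must be > 0")
  if (!is.numeric(av_mean) || av_mean >= 0) gait_config_error("av_mean must be negative")
  if (!is.numeric(av_sd) || av_sd < 0) gait_config_error("av_sd must be >= 0")
  if (!is.numeric(p_good) || p_good < 0 || p_good > 1) gait_config_error("p_good must be in [0, 1]")
  if (!is.numeric(bad_attenuation) || bad_attenuation <= 0 || bad_attenuation > 1) {
    gait_config_error("bad_attenuation must be in (0, 1]")
  }
  if (!is.numeric(swing_amp) || swing_amp <= 0) gait_config_error("swing_amp must be > 0")
  if (!is.numeric(noise_sd) || noise_sd < 0) gait_config_error("noise_sd must be >= 0")
  if (!is.list(bout_plan) || length(bout_plan) == 0 ||
      !all(vapply(bout_plan, function(b) is.numeric(b) && length(b) == 2 &&
                    b[1] > 0 && b[2] >= 0, logical(1)))) {
    gait_config_error("bout_plan must be a non-empty list of c(walk > 0, rest >= 0) durations")
  }
  if (!is.numeric(threshold_av) || threshold_av >= 0) {
    gait_config_error("threshold_av must be negative")
  }
  structure(list(cadence = cadence, av_mean = av_mean, av_sd = av_sd,
                 p_good = p_good, bad_attenuation = bad_attenuation,
                 swing_amp = swing_amp, noise_sd = noise_sd,
                 bout_plan = bout_plan, threshold_av = threshold_av,
                 stride_jitter_cv = stride_jitter_cv,
                 seed = as.integer(seed)),
            class = "gait_profile")
}

#' Published single-subject gait observations
#'
#' Session summaries (percent good steps, cadence in steps/min, mean
#' heel-strike angular velocity in deg/s, and its coefficient of variation
#' in percent) for six older adults (A-F), each measured before and after
#' five days of auditory-feedback gait training, both with the per-step
#' feedback beep enabled and disabled. Used as realistic anchor points for
#' the simulator via [profile_from_reference()].
#'
#' @return A data.frame with columns `participant`, `timepoint`
#'   (`"pre"`/`"post"`), `feedback` (`"with"`/`"without"`), `pct_good`,
#'   `cadence`, `av_mean`, `av_cv`.
#' @export
reference_observations <- function() {
  p <- rep(LETTERS[1:6], times = 4)
  tp <- rep(c("pre", "pre", "post", "post"), each = 6)
  fb <- rep(c("without", "with", "without", "with"), each = 6)
  data.frame(
    participant = p, timepoint = tp, feedback = fb,
    pct_good = c(0, 43, 80, 84, 92, 93,
                 56, 82, 83, 97, 92, 99,
                 29, 80, 89, 97, 95, 99,
                 66, 90, 92, 94, 93, 100),
    cadence = c(70, 95, 97, 110, 113, 96,
                69, 102, 95, 95, 110, 95,
                77, 104, 100, 121, 105, 110,
                84, 96, 99, 122, 111, 109),
    av_mean = c(-48, -97, -147, -145, -165, -163,
                -102, -128, -157, -186, -173, -213,
                -80, -126, -163, -227, -176, -250,
                -102, -147, -159, -208, -173, -263),
    av_cv = c(59, 39, 40, 31, 24, 24,
              41, 33, 39, 17, 23, 14,
              52, 33, 24, 20, 17, 11,
              50, 21, 21, 24, 22, 10),
    stringsAsFactors = FALSE
  )
}

#' Simulator profile anchored to a published observation
#'
#' Looks up one participant/timepoint/feedback cell of
#' [reference_observations()] and returns a [gait_profile()] whose cadence,
#' mean peak angular velocity and fraction of good steps equal the printed
#' values; `av_sd` is derived from the printed coefficient of variation as
#' `|av_mean| * cv / 100`.
#'
#' @param participant `"A"` through `"F"`.
#' @param timepoint `"pre"` or `"post"` (before/after training).
#' @param feedback `"with"` or `"without"` (feedback beep on/off during the
#'   assessment walk).
#' @param ... further arguments passed to [gait_profile()] (e.g. `bout_plan`,
#'   `noise_sd`, `seed`).
#' @return A [gait_profile()].
#' @export
#' @examples
#' profile_from_reference("A", "pre", "without")$p_good  # 0
profile_from_reference <- function(participant, timepoint = c("pre", "post"),
                                   feedback = c("without", "with"), ...) {
  obs <- reference_observations()
  if (!is.character(participant) || length(participant) != 1 ||
      !participant %in% obs$participant) {
    gait_lookup_error("unknown participant (expected one of A-F)")
  }
  if (length(timepoint) != 1 || !timepoint %in% c("pre", "post")) {
    timepoint <- tryCatch(match.arg(timepoint),
                          error = function(e) gait_lookup_error("timepoint must be \"pre\" or \"post\""))
  }
  if (length(feedback) != 1 || !feedback %in% c("without", "with")) {
    feedback <- tryCatch(match.arg(feedback),
                         error = function(e) gait_lookup_error("feedback must be \"with\" or \"without\""))
  }
  row <- obs[obs$participant == participant & obs$timepoint == timepoint &
               obs$feedback == feedback, ]
  if (nrow(row) != 1) gait_lookup_error("unknown participant/timepoint/feedback combination")
  gait_profile(cadence = row$cadence, av_mean = row$av_mean,
               av_sd = abs(row$av_mean) * row$av_cv / 100,
               p_good = row$pct_good / 100, ...)
}
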