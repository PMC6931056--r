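#' Heel-strike detection configuration
#'
#' @description Parameters of the stride detector. A stride is accepted when
#' the smoothed sagittal trace rises above `swing_min_amp` (the mid-swing
#' lobe), and the deceleration minimum that follows the swing peak within
#' `search_window` seconds is negative. The step is classified *good* when
#' that minimum is at or below (more negative than) `threshold_av` — the
#' condition that triggers the feedback beep on the wearable.
#'
#' @param threshold_av classification threshold in deg/s (negative). Default
#'   -90: separates weak foot-flat contact (around -20 to -60 deg/s) from
#'   heel-first contact (-100 deg/s and beyond in the populations this tool
#'   targets). Fully configurable; devices expose low/medium/high variants.
#' @param swing_min_amp minimum mid-swing positive peak in deg/s to accept a
#'   stride (default 50).
#' @param search_window seconds after the swing peak in which the
#'   deceleration minimum is sought (default 0.40).
#' @param refractory minimum spacing between accepted heel strikes in
#'   seconds (default 0.40; on conflict the earlier event is kept).
#' @param smoothing_cutoff low-pass corner frequency in Hz applied before
#'   peak search (default 15; gait energy lives well below this).
#' @param rebound confirmation rise in deg/s used by the streaming detector
#'   and its batch twin: a pending minimum is confirmed as soon as the trace
#'   rebounds this far above it (default 10).
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(threshold_av = -90, swing_min_amp = 50,
                             search_window = 0.40, refractory = 0.40,
                             smoothing_cutoff = 15, rebound = 10) {
  if (!is.numeric(threshold_av) || threshold_av >= 0) {
    gait_config_error("threshold_av must be negative (deg/s)")
  }
  if (!is.numeric(search_window) || search_window <= 0) {
    gait_config_error("search_window must be > 0")
  }
  if (!is.numeric(refractory) || refractory <= 0) {
    gait_config_error("refractory must be > 0")
  }
  if (!is.numeric(swing_min_amp) || swing_min_amp <= 0) {
    gait_config_error("swing_min_amp must be > 0")
  }
  if (!is.numeric(smoothing_cutoff) || smoothing_cutoff <= 0) {
    gait_config_error("smoothing_cutoff must be > 0")
  }
  if (!is.numeric(rebound) || rebound <= 0) {
    gait_config_error("rebound must be > 0")
  }
  structure(list(threshold_av = as.numeric(threshold_av),
                 swing_min_amp = as.numeric(swing_min_amp),
                 search_window = as.numeric(search_window),
                 refractory = as.numeric(refractory),
                 smoothing_cutoff = as.numeric(smoothing_cutoff),
                 rebound = as.numeric(rebound)),
            class = "detection_config")
}

#' Classify a step from its deceleration peak
#'
#' A step is *good* (heel-first) when its post-heel-strike angular-velocity
#' minimum is at or below the threshold; the boundary counts as good.
#'
#' @param peak_av post-heel-strike peak angular velocity in deg/s (may be a
#'   vector).
#' @param threshold_av classification threshold in deg/s (negative).
#' @return Logical, `TRUE` for good steps.
#' @export
#' @examples
#' classify_step(c(-102, -48, -90), -90)  # TRUE FALSE TRUE
classify_step <- function(peak_av, threshold_av = -90) {
  if (!is.numeric(threshold_av) || length(threshold_av) != 1 || threshold_av >= 0) {
    gait_config_error("threshold_av must be a single negative number")
  }
  peak_av <= threshold_av
}

# Low-pass smoothing. Batch default: zero-phase 2nd-order Butterworth
# (applied forward and backward, so no group delay and no peak shift).
# Causal: single-pole RC low-pass at the same corner, the filter a streaming
# device can actually run; it delays and slightly attenuates the peaks, which
# is why the streaming/batch equivalence contract is defined with both paths
# on the causal filter.
smooth_trace <- function(av, sample_rate, cutoff, method = c("zero_phase", "causal")) {
  method <- match.arg(method)
  if (sample_rate < 2 * cutoff) {
    gait_config_error(sprintf(
      "sample_rate (%g Hz) must be at least twice smoothing_cutoff (%g Hz)",
      sample_rate, cutoff))
  }
  n <- length(av)
  if (n == 0) return(av)
  if (method == "zero_phase") {
    if (n < 12) return(av)   # too short for stable edge handling; gait needs none
    bf <- signal::butter(2, cutoff / (sample_rate / 2), type = "low")
    as.numeric(signal::filtfilt(bf, av))
  } else {
    causal_lowpass(av, sample_rate, cutoff)
  }
}

causal_lowpass <- function(av, sample_rate, cutoff, y0 = 0) {
  alpha <- lowpass_alpha(sample_rate, cutoff)
  # y[i] = y[i-1] + alpha * (x[i] - y[i-1]); stats::filter runs the recursion
  n <- length(av)
  if (n == 0) return(av)
  y <- stats::filter(alpha * av, filter = 1 - alpha, method = "recursive",
                     init = y0)
  as.numeric(y)
}

lowpass_alpha <- function(sample_rate, cutoff) {
  dt <- 1 / sample_rate
  rc <- 1 / (2 * pi * cutoff)
  dt / (rc + dt)
}

#' Detect heel strikes in a sagittal trace
#'
#' Batch detector. The trace is low-pass smoothed, contiguous regions where
#' it exceeds `swing_min_amp` are taken as mid-swing lobes, and after each
#' swing peak the deceleration minimum is sought within `search_window`
#' seconds by a sequential scan: the running minimum is frozen as soon as
#' the trace rebounds `rebound` deg/s above it, when the window expires,
#' when the next swing lobe completes, or at end of trace. A candidate
#' yields an event only if its minimum is negative. Events closer than
#' `refractory` to an accepted predecessor are dropped (earlier event wins),
#' and each event is classified with [classify_step()].
#'
#' @param trace a [sagittal_trace()].
#' @param config a [detection_config()].
#' @param smoothing `"zero_phase"` (default; no group delay, for offline
#'   analysis) or `"causal"` (the streaming-equivalent single-pole filter).
#' @return A data.frame of class `step_events` with columns `t` (heel-strike
#'   time, s), `peak_av` (deg/s) and `good` (logical), ordered in time.
#' @export
detect_heel_strikes <- function(trace, config = detection_config(),
                                smoothing = c("zero_phase", "causal")) {
  stopifnot(inherits(trace, "sagittal_trace"), inherits(config, "detection_config"))
  smoothing <- match.arg(smoothing)
  s <- smooth_trace(trace$av, trace$sample_rate, config$smoothing_cutoff,
                    smoothing)
  n <- length(s)
  fs <- trace$sample_rate
  empty <- step_events(numeric(0), numeric(0), logical(0))
  if (n == 0) return(empty)

  above <- s >= config$swing_min_amp
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  reg_start <- starts[r$values]
  reg_end <- ends[r$values]
  n_reg <- length(reg_start)
  if (n_reg == 0) return(empty)

  n_win <- round(config$search_window * fs)
  cand_t <- numeric(0); cand_v <- numeric(0); cand_i <- integer(0)

  for (k in seq_len(n_reg)) {
    seg <- s[reg_start[k]:reg_end[k]]
    p <- reg_start[k] - 1L + which.max(seg)      # earliest tie wins
    from <- reg_end[k] + 1L
    # the scan is cut short where the *next* region completes: at that point
    # the streaming detector hands over to the next pending search
    lim <- if (k < n_reg) reg_end[k + 1L] else n
    to <- min(p + n_win, lim, n)
    if (from > to) next
    idx <- from:to
    seg2 <- s[idx]
    m_run <- cummin(seg2)
    j <- length(seg2)                             # default: window end
    if (length(seg2) > 1) {
      reb <- which(seg2[-1] >= m_run[-length(seg2)] + config$rebound &
                     m_run[-length(seg2)] < 0)
      if (length(reb) > 0) j <- reb[1]            # freeze before the rebound sample
    }
    m_val <- m_run[j]
    if (m_val >= 0) next
    m_idx <- idx[which.max(seg2[1:j] == m_val)]   # earliest index attaining it
    cand_t <- c(cand_t, trace$t0 + (m_idx - 1) / fs)
    cand_v <- c(cand_v, m_val)
    cand_i <- c(cand_i, m_idx)
  }
  if (length(cand_t) == 0) return(empty)

  ord <- order(cand_t)
  cand_t <- cand_t[ord]; cand_v <- cand_v[ord]; cand_i <- cand_i[ord]
  keep <- logical(length(cand_t))
  last_t <- -Inf
  for (i in seq_along(cand_t)) {
    if (cand_t[i] - last_t >= config$refractory) {
      keep[i] <- TRUE
      last_t <- cand_t[i]
    }
  }
  peak <- vapply(which(keep), function(i) {
    refine_peak(trace$av, cand_i[i], n, cand_v[i])
  }, numeric(1))
  step_events(cand_t[keep], peak, classify_step(peak, config$threshold_av))
}

# Parabolic vertex refinement of a deceleration minimum, computed on the
# *raw* trace: the low-pass filter attenuates the narrow deceleration lobe
# by 2-3%, so the reported peak is the vertex of a least-squares quadratic
# through the five raw samples around the detected minimum (standard peak
# interpolation). Falls back to the raw centre sample, then to the smoothed
# minimum, whenever the fit is not a credible negative minimum. Batch and
# streaming paths share this routine sample-for-sample.
refine_peak <- function(raw, i, n_avail, smoothed_min) {
  lo <- max(1L, i - 2L)
  hi <- min(n_avail, i + 2L)
  fallback <- if (raw[i] < 0) raw[i] else smoothed_min
  if (hi - lo < 2L) return(fallback)
  jrel <- (lo:hi) - i
  y <- raw[lo:hi]
  vertex_refine(y, jrel, fallback)
}

vertex_refine <- function(y, jrel, fallback) {
  f <- stats::lm.fit(cbind(1, jrel, jrel^2), y)$coefficients
  a <- f[[3]]; b <- f[[2]]; c0 <- f[[1]]
  # the |vertex offset| <= 2.5 sample constraint bounds the correction, so no
  # further guard is needed on the vertex depth
  if (is.finite(a) && a > 0 && abs(-b / (2 * a)) <= 2.5) {
    v <- c0 - b^2 / (4 * a)
    if (is.finite(v) && v < 0) return(v)
  }
  # degenerate or off-centre fit: the fit's value at the detected minimum is
  # still a 5-point smoothed estimate, far more noise-robust than one sample
  if (is.finite(c0) && c0 < 0) return(c0)
  fallback
}

step_events <- function(t, peak_av, good) {
  structure(data.frame(t = t, peak_av = peak_av, good = good),
            class = c("step_events", "data.frame"))
}

#' Segment detected steps into walking bouts
#'
#' Splits a time-ordered step sequence into maximal runs whose consecutive
#' inter-step gaps are all below `gap_limit`. Each bout is padded by half
#' the median within-bout stride time on either side, so a bout's duration
#' approximates the walking time it covers (a lone step falls back to a
#' 0.5 s half-stride).
#'
#' @param events a `step_events` data.frame (or anything with a numeric `t`
#'   column, time-ordered).
#' @param gap_limit gap in seconds that terminates a bout (default 10; a
#'   rest shorter than this does not split a bout).
#' @return A data.frame of class `gait_bouts` with columns `start`, `end`
#'   (s), `first_step`, `last_step` (indices into `events`), `n_steps`.
#' @export
segment_bouts <- function(events, gap_limit = 10) {
  if (!is.numeric(gap_limit) || gap_limit <= 0) {
    gait_config_error("gap_limit must be > 0")
  }
  t <- events$t
  empty <- structure(
    data.frame(start = numeric(0), end = numeric(0), first_step = integer(0),
               last_step = integer(0), n_steps = integer(0)),
    class = c("gait_bouts", "data.frame"))
  if (length(t) == 0) return(empty)
  if (is.unsorted(t, strictly = FALSE)) {
    gait_validation_error("step events must be time-ordered")
  }
  breaks <- which(diff(t) >= gap_limit)
  first <- c(1L, breaks + 1L)
  last <- c(breaks, length(t))
  half <- vapply(seq_along(first), function(k) {
    if (last[k] > first[k]) stats::median(diff(t[first[k]:last[k]])) / 2 else 0.5
  }, numeric(1))
  structure(
    data.frame(start = t[first] - half, end = t[last] + half,
               first_step = first, last_step = last,
               n_steps = last - first + 1L),
    class = c("gait_bouts", "data.frame"))
}
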