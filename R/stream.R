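#' Create a real-time feedback stream
#'
#' Emulates the on-device feedback loop: samples are pushed one at a time
#' (or in chunks) through a causal single-pole low-pass filter and a stride
#' state machine, and a feedback event (the "beep") is emitted as soon as a
#' good step is confirmed. Confirmation happens at the first sample that
#' rebounds `rebound` deg/s above the pending deceleration minimum, at
#' window expiry, or when the next swing lobe completes — whichever comes
#' first — so the emission latency is bounded by
#' `search_window + one sample period`.
#'
#' The stream applies exactly the same rule set as
#' `detect_heel_strikes(smoothing = "causal")`; for any trace the two paths
#' produce the same step set.
#'
#' @param config a [detection_config()].
#' @param sample_rate sampling rate in Hz of the samples that will be pushed.
#' @return An object of class `feedback_stream` (stateful; treat as opaque).
#' @seealso [push_sample()], [push_samples()], [finalize_stream()]
#' @export
feedback_stream <- function(config = detection_config(), sample_rate = 100) {
  stopifnot(inherits(config, "detection_config"))
  if (sample_rate < 2 * config$smoothing_cutoff) {
    gait_config_error("sample_rate must be at least twice smoothing_cutoff")
  }
  e <- new.env(parent = emptyenv())
  e$config <- config
  e$fs <- sample_rate
  e$alpha <- lowpass_alpha(sample_rate, config$smoothing_cutoff)
  e$n_win <- round(config$search_window * sample_rate)
  e$y_prev <- 0            # causal filter memory
  e$buf_n <- e$n_win + 8L  # raw-sample ring buffer (for peak refinement)
  e$rawbuf <- numeric(e$buf_n)
  e$queue <- list()        # confirmed minima awaiting refinement/emission
  e$k <- 0L                # sample counter
  e$t_prev <- -Inf
  e$in_region <- FALSE
  e$peak_idx <- NA_integer_
  e$peak_val <- -Inf
  e$pending <- FALSE       # active minimum search
  e$p_idx <- NA_integer_   # swing peak index of the pending search
  e$m_val <- Inf           # running minimum (Inf = no candidate yet)
  e$m_idx <- NA_integer_
  e$last_step_t <- -Inf    # refractory clock
  e$steps_t <- numeric(0)  # all accepted steps (good and bad)
  e$steps_v <- numeric(0)
  e$steps_good <- logical(0)
  e$finalized <- FALSE
  class(e) <- "feedback_stream"
  e
}

# close the pending search; a credible (negative) minimum is queued for
# peak refinement, which needs raw samples up to two past the minimum
confirm_pending <- function(e) {
  e$pending <- FALSE
  if (!is.finite(e$m_val) || e$m_val >= 0) return(invisible())
  e$queue[[length(e$queue) + 1L]] <- list(i = e$m_idx, v = e$m_val)
  invisible()
}

ring_get <- function(e, idx) e$rawbuf[((idx - 1L) %% e$buf_n) + 1L]

# emit queued steps whose refinement window (min index + 2) is complete;
# `final` forces emission with whatever samples exist. Applies the
# refractory rule, vertex peak refinement and classification in heel-strike
# order, mirroring the batch path exactly.
process_queue <- function(e, t_now, final = FALSE) {
  out <- list()
  while (length(e$queue) > 0) {
    q <- e$queue[[1]]
    if (!final && q$i + 2L > e$k) break
    e$queue <- e$queue[-1]
    t_hs <- (q$i - 1) / e$fs
    if (t_hs - e$last_step_t < e$config$refractory) next
    e$last_step_t <- t_hs
    lo <- max(1L, q$i - 2L)
    hi <- min(e$k, q$i + 2L)
    raw_c <- ring_get(e, q$i)
    fallback <- if (raw_c < 0) raw_c else q$v
    peak <- if (hi - lo < 2L) fallback else
      vertex_refine(ring_get(e, lo:hi), (lo:hi) - q$i, fallback)
    good <- classify_step(peak, e$config$threshold_av)
    e$steps_t <- c(e$steps_t, t_hs)
    e$steps_v <- c(e$steps_v, peak)
    e$steps_good <- c(e$steps_good, good)
    if (good) {
      out[[length(out) + 1L]] <-
        data.frame(t_emit = t_now, t_heel_strike = t_hs, peak_av = peak)
    }
  }
  out
}

#' Push one sample into a feedback stream
#'
#' @param stream a [feedback_stream()].
#' @param t sample time in seconds; must be strictly greater than the
#'   previously pushed time.
#' @param av sagittal angular velocity in deg/s.
#' @return A data.frame of feedback events emitted by this sample (usually
#'   zero rows): columns `t_emit`, `t_heel_strike`, `peak_av`.
#' @export
push_sample <- function(stream, t, av) {
  push_samples(stream, t, av)
}

#' Push a vector of samples into a feedback stream
#'
#' Equivalent to pushing each sample individually (the state machine is
#' strictly incremental); provided so long replays do not pay one R call
#' per sample.
#'
#' @param stream a [feedback_stream()].
#' @param t strictly increasing sample times in seconds.
#' @param av sagittal angular velocity samples in deg/s, same length as `t`.
#' @return A data.frame of all feedback events emitted, in emission order.
#' @export
push_samples <- function(stream, t, av) {
  e <- stream
  stopifnot(inherits(e, "feedback_stream"))
  if (e$finalized) gait_sequence_error("stream is finalized; no more samples accepted")
  if (length(t) != length(av)) gait_sequence_error("t and av must have equal length")
  if (length(t) == 0) return(empty_feedback_events())
  if (any(diff(c(e$t_prev, t)) <= 0)) {
    gait_sequence_error("sample times must be strictly increasing")
  }
  out <- list()
  cfg <- e$config
  for (i in seq_along(t)) {
    e$t_prev <- t[i]
    e$k <- e$k + 1L
    j <- e$k
    e$rawbuf[((j - 1L) %% e$buf_n) + 1L] <- av[i]
    s <- e$y_prev + e$alpha * (av[i] - e$y_prev)
    e$y_prev <- s

    # a completed swing lobe hands over: force-confirm the previous search
    region_ended <- e$in_region && s < cfg$swing_min_amp
    if (region_ended) {
      e$in_region <- FALSE
      if (e$pending) confirm_pending(e)
      e$pending <- TRUE
      e$p_idx <- e$peak_idx
      e$m_val <- Inf
      e$m_idx <- NA_integer_
    }

    if (e$pending) {
      if (j > e$p_idx + e$n_win) {
        confirm_pending(e)                        # window expired before j
      } else if (is.finite(e$m_val) && e$m_val < 0 &&
                 s >= e$m_val + cfg$rebound) {
        confirm_pending(e)                        # rebound confirmation
      } else if (s < e$m_val) {                   # strict: earliest tie wins
        e$m_val <- s
        e$m_idx <- j
      }
    }

    if (s >= cfg$swing_min_amp) {
      if (!e$in_region) {
        e$in_region <- TRUE
        e$peak_idx <- j
        e$peak_val <- s
      } else if (s > e$peak_val) {
        e$peak_idx <- j
        e$peak_val <- s
      }
    }

    out <- c(out, process_queue(e, t[i]))
  }
  if (length(out) == 0) empty_feedback_events() else do.call(rbind, out)
}

#' Finalize a feedback stream
#'
#' Flushes the pending deceleration minimum, if any (a stream truncated
#' mid-rebound still rewards its last confirmed-quality step), and closes
#' the stream: subsequent pushes or a second finalize raise a sequencing
#' error.
#'
#' @param stream a [feedback_stream()].
#' @return A data.frame of any remaining feedback events.
#' @export
finalize_stream <- function(stream) {
  e <- stream
  stopifnot(inherits(e, "feedback_stream"))
  if (e$finalized) gait_sequence_error("stream already finalized")
  e$finalized <- TRUE
  if (e$pending) confirm_pending(e)
  out <- process_queue(e, if (is.finite(e$t_prev)) e$t_prev else 0,
                       final = TRUE)
  if (length(out) == 0) empty_feedback_events() else do.call(rbind, out)
}

#' Steps accepted so far by a feedback stream
#'
#' All confirmed steps, good and bad, in heel-strike-time order — the
#' streaming counterpart of the [detect_heel_strikes()] result.
#'
#' @param stream a [feedback_stream()].
#' @return A `step_events` data.frame with columns `t`, `peak_av`, `good`.
#' @export
stream_steps <- function(stream) {
  stopifnot(inherits(stream, "feedback_stream"))
  step_events(stream$steps_t, stream$steps_v, stream$steps_good)
}

empty_feedback_events <- function() {
  data.frame(t_emit = numeric(0), t_heel_strike = numeric(0),
             peak_av = numeric(0))
}
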