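#' Coefficient of variation of per-step peak angular velocity
#'
#' `100 * sd(values) / |mean(values)|`, with the sample (n-1) SD. Lower CV
#' means more consistent stepping; values under 10% are typical of regular
#' gait.
#'
#' @param values numeric vector with at least two values and non-zero mean.
#' @return CV in percent.
#' @export
#' @examples
#' coefficient_of_variation(c(-90, -110))  # 14.14
coefficient_of_variation <- function(values) {
  if (!is.numeric(values) || length(values) < 2) {
    gait_stat_error("coefficient of variation needs at least 2 values")
  }
  m <- mean(values)
  if (m == 0) gait_stat_error("coefficient of variation undefined for zero mean")
  100 * stats::sd(values) / abs(m)
}

#' Session-level gait quality metrics
#'
#' Summarises a detected session: proportion of good steps, cadence over
#' walking time, total walking time, and the mean/SD/CV of per-step peak
#' angular velocity (over *all* steps, good and bad). Cadence divides steps
#' by time spent inside walking bouts, not by elapsed session time, so
#' rests do not deflate it.
#'
#' @param events a `step_events` data.frame from [detect_heel_strikes()] or
#'   [stream_steps()].
#' @param bouts a `gait_bouts` data.frame from [segment_bouts()]; every
#'   event must fall inside a bout.
#' @return A list of class `gait_metrics`: `pct_good`, `cadence` (steps/min),
#'   `total_walk_time` (s), `av_mean`, `av_sd` (deg/s), `av_cv` (%), `n_steps`,
#'   `n_good`, `bouts`, `n_bouts_ge_10min`, and `empty_session` (flag set when
#'   there are no steps; the percentage fields are then 0/NA by convention).
#' @export
compute_metrics <- function(events, bouts) {
  n <- nrow(events)
  if (n > 0) {
    inside <- vapply(events$t, function(tt) {
      any(tt >= bouts$start & tt <= bouts$end)
    }, logical(1))
    if (!all(inside)) {
      gait_validation_error("every step event must lie inside a walking bout")
    }
  }
  total_walk <- if (nrow(bouts) > 0) sum(bouts$end - bouts$start) else 0
  n_good <- if (n > 0) sum(events$good) else 0L
  res <- list(
    pct_good = if (n > 0) 100 * n_good / n else 0,
    cadence = if (total_walk > 0) 60 * n / total_walk else 0,
    total_walk_time = total_walk,
    av_mean = if (n > 0) mean(events$peak_av) else NA_real_,
    av_sd = if (n >= 2) stats::sd(events$peak_av) else NA_real_,
    av_cv = if (n >= 2 && mean(events$peak_av) != 0)
      coefficient_of_variation(events$peak_av) else NA_real_,
    n_steps = n,
    n_good = as.integer(n_good),
    bouts = bouts,
    n_bouts_ge_10min = if (nrow(bouts) > 0)
      sum(bouts$end - bouts$start >= 600) else 0L,
    empty_session = n == 0
  )
  class(res) <- "gait_metrics"
  res
}

#' @export
print.gait_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("<gait_metrics> %d steps (%.1f%% good), cadence %.1f steps/min,\n",
           "  walking time %.1f s in %d bout(s) (%d of >= 10 min),\n",
           "  peak AV mean %.1f deg/s, SD %.1f, CV %.1f%%%s\n"),
    x$n_steps, x$pct_good, x$cadence, x$total_walk_time, nrow(x$bouts),
    x$n_bouts_ge_10min, x$av_mean, x$av_sd, x$av_cv,
    if (x$empty_session) " [empty session]" else ""))
  invisible(x)
}

# direction: +1 if larger raw values are better, -1 if smaller are better.
# av_mean improves as it becomes more negative; av_cv improves downward.
change_directions <- c(pct_good = 1, cadence = 1, av_mean = -1, av_cv = -1)

#' Pre/post change report with the 10% clinical-importance rule
#'
#' For each gait parameter the percent change from pre to post is computed
#' in its improving direction (good steps up, cadence up, peak angular
#' velocity more negative, CV down) relative to the magnitude of the pre
#' value; a change of at least +10% in the improving direction is flagged
#' as clinically important. A pre value of exactly 0 for the proportion of
#' good steps makes a ratio meaningless; the report then falls back to the
#' change in percentage points and flags the fallback.
#'
#' @param pre,post [compute_metrics()] results for the two sessions.
#' @param importance_threshold minimum improving-direction percent change
#'   counted as clinically important (default 10).
#' @return A list of class `change_report`: `parameters` (data.frame with
#'   `parameter`, `pre`, `post`, `pct_change` — signed, positive = improved —,
#'   `important`, `basis`) and `overall_important`.
#' @export
#' @examples
#' # proportion of good steps 43 -> 80: +86%, important
compare_sessions <- function(pre, post, importance_threshold = 10) {
  stopifnot(inherits(pre, "gait_metrics"), inherits(post, "gait_metrics"))
  rows <- lapply(names(change_directions), function(p) {
    a <- pre[[p]]; b <- post[[p]]
    dir <- change_directions[[p]]
    basis <- "percent"
    if (is.na(a) || is.na(b)) {
      chg <- NA_real_
    } else if (a == 0) {
      chg <- dir * (b - a)          # percentage-point fallback
      basis <- "percentage_points"
    } else {
      chg <- dir * 100 * (b - a) / abs(a)
    }
    data.frame(parameter = p, pre = a, post = b, pct_change = chg,
               important = !is.na(chg) && chg >= importance_threshold,
               basis = basis, stringsAsFactors = FALSE)
  })
  params <- do.call(rbind, rows)
  structure(list(parameters = params,
                 overall_important = any(params$important)),
            class = "change_report")
}

#' @export
print.change_report <- function(x, ...) {
  p <- x$parameters
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-8s %8.1f -> %8.1f   %+6.1f%s %s\n",
                p$parameter[i], p$pre[i], p$post[i], p$pct_change[i],
                if (p$basis[i] == "percent") "%" else "pp",
                if (isTRUE(p$important[i])) "  ** important" else ""))
  }
  cat(if (x$overall_important) "=> clinically important change\n"
      else "=> no clinically important change\n")
  invisible(x)
}

#' Physical-activity guideline check
#'
#' Moderate-intensity walking guidelines for seniors count walking at a
#' cadence of at least 100 steps/min accumulated in bouts of at least 10
#' minutes. A session meets the guideline pattern when its average cadence
#' is >= 100 and it contains at least one bout of 10 minutes or more.
#'
#' @param metrics a [compute_metrics()] result.
#' @return `TRUE` or `FALSE`.
#' @export
meets_guideline <- function(metrics) {
  stopifnot(inherits(metrics, "gait_metrics"))
  metrics$cadence >= 100 && metrics$n_bouts_ge_10min >= 1
}
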