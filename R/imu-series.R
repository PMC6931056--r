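#' Uniformly sampled 6-axis IMU recording
#'
#' Container for an ankle-worn inertial sensor trace: a 3-axis gyroscope
#' (deg/s) and a 3-axis accelerometer (m/s^2) sampled at a fixed rate.
#' Timestamps are implicit and session-relative: `t_i = t0 + (i - 1) / sample_rate`.
#' By mounting convention the gyroscope y axis carries the sagittal-plane
#' (foot pitch) rotation, but the axis is configurable everywhere it is used.
#'
#' @param gyro numeric matrix with columns `x`, `y`, `z`, angular velocity in
#'   deg/s; one row per sample.
#' @param accel numeric matrix with columns `x`, `y`, `z`, linear acceleration
#'   in m/s^2; same number of rows as `gyro`.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param t0 session-relative start time in seconds (default 0).
#'
#' @return An object of class `imu_series`: a list with elements
#'   `sample_rate`, `t0`, `gyro`, `accel`, `n_samples`.
#' @export
#' @examples
#' s <- imu_series(gyro = matrix(0, 3, 3), accel = matrix(0, 3, 3),
#'                 sample_rate = 100)
#' imu_time(s)
imu_series <- function(gyro, accel, sample_rate, t0 = 0) {
  gyro <- as_axis_matrix(gyro, "gyro")
  accel <- as_axis_matrix(accel, "accel")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || !is.finite(sample_rate) ||
      sample_rate <= 0) {
    gait_validation_error("sample_rate must be a single positive finite number")
  }
  if (!is.numeric(t0) || length(t0) != 1 || !is.finite(t0)) {
    gait_validation_error("t0 must be a single finite number")
  }
  if (nrow(gyro) != nrow(accel)) {
    gait_validation_error("gyro and accel must have the same number of samples")
  }
  if (anyNA(gyro) || anyNA(accel) || any(!is.finite(gyro)) || any(!is.finite(accel))) {
    gait_validation_error("IMU samples must be finite (no NA/NaN/Inf)")
  }
  structure(
    list(sample_rate = as.numeric(sample_rate), t0 = as.numeric(t0),
         gyro = gyro, accel = accel, n_samples = nrow(gyro)),
    class = "imu_series"
  )
}

as_axis_matrix <- function(m, what) {
  if (is.data.frame(m)) m <- as.matrix(m)
  if (!is.matrix(m) || ncol(m) != 3 || !is.numeric(m)) {
    gait_validation_error(sprintf("%s must be a numeric matrix with 3 columns (x, y, z)", what))
  }
  colnames(m) <- c("x", "y", "z")
  m
}

#' Implicit sample times of an IMU series
#'
#' @param series an [imu_series()].
#' @return Numeric vector of session-relative times in seconds.
#' @export
imu_time <- function(series) {
  stopifnot(inherits(series, "imu_series"))
  if (series$n_samples == 0) return(numeric(0))
  series$t0 + (seq_len(series$n_samples) - 1) / series$sample_rate
}

#' @export
print.imu_series <- function(x, ...) {
  cat(sprintf("<imu_series> %d samples @ %g Hz (%.2f s), t0 = %g s\n",
              x$n_samples, x$sample_rate, x$n_samples / x$sample_rate, x$t0))
  invisible(x)
}

#' Sagittal-plane angular velocity trace
#'
#' A single-channel view of an IMU recording: the angular velocity of the
#' foot/ankle segment in the sagittal plane, in deg/s. The sign convention is
#' fixed so that the sharp deceleration just after heel strike is a
#' *negative* excursion (the more negative, the stronger the heel-first
#' contact).
#'
#' @param av numeric vector of angular velocity in deg/s.
#' @param sample_rate sampling rate in Hz.
#' @param t0 start time in seconds.
#' @return An object of class `sagittal_trace`.
#' @export
sagittal_trace <- function(av, sample_rate, t0 = 0) {
  if (!is.numeric(av) || anyNA(av) || any(!is.finite(av))) {
    gait_validation_error("av must be a finite numeric vector")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    gait_validation_error("sample_rate must be a single positive number")
  }
  structure(list(av = as.numeric(av), sample_rate = as.numeric(sample_rate),
                 t0 = as.numeric(t0), n_samples = length(av)),
            class = "sagittal_trace")
}

#' @export
print.sagittal_trace <- function(x, ...) {
  cat(sprintf("<sagittal_trace> %d samples @ %g Hz (%.2f s)\n",
              x$n_samples, x$sample_rate, x$n_samples / x$sample_rate))
  invisible(x)
}

#' Extract the sagittal-plane channel from an IMU series
#'
#' Selects one gyroscope axis and applies a sign so that post-heel-strike
#' deceleration is negative. Sensors mounted mirror-wise on the other ankle
#' (or upside down) are accommodated with `sign = -1`.
#'
#' @param series an [imu_series()].
#' @param axis gyroscope axis carrying sagittal rotation: `"x"`, `"y"` or `"z"`.
#' @param sign `+1` or `-1` applied to every sample.
#' @return A [sagittal_trace()] with the same length and rate as `series`.
#' @export
extract_sagittal <- function(series, axis = "y", sign = 1) {
  stopifnot(inherits(series, "imu_series"))
  if (!is.character(axis) || length(axis) != 1 || !axis %in% c("x", "y", "z")) {
    gait_config_error("axis must be one of \"x\", \"y\", \"z\"")
  }
  if (!sign %in% c(-1, 1)) {
    gait_config_error("sign must be +1 or -1")
  }
  sagittal_trace(sign * series$gyro[, axis], series$sample_rate, series$t0)
}
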