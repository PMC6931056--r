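#' I/O configuration for IMU CSV files
#'
#' @param axis gyroscope axis mapped to the sagittal plane (default `"y"`).
#' @param sign sagittal sign convention, `+1` or `-1` (default `+1`; see
#'   [extract_sagittal()]).
#' @param sample_rate optional sampling rate in Hz. When `NULL` the rate is
#'   inferred from the file timestamps as `1 / median(diff(time_s))`. Allowed
#'   range 25-500 Hz.
#' @return A list of class `io_config`.
#' @export
io_config <- function(axis = "y", sign = 1, sample_rate = NULL) {
  if (!axis %in% c("x", "y", "z")) gait_config_error("axis must be x, y or z")
  if (!sign %in% c(-1, 1)) gait_config_error("sign must be +1 or -1")
  if (!is.null(sample_rate)) {
    if (!is.numeric(sample_rate) || length(sample_rate) != 1 ||
        sample_rate < 25 || sample_rate > 500) {
      gait_config_error("sample_rate must be in [25, 500] Hz")
    }
  }
  structure(list(axis = axis, sign = sign, sample_rate = sample_rate),
            class = "io_config")
}

imu_csv_columns <- c("time_s", "gyro_x", "gyro_y", "gyro_z",
                     "accel_x", "accel_y", "accel_z")

#' Read an IMU recording from CSV
#'
#' The dialect is fixed: comma-separated, `.` decimal, a mandatory header row
#' `time_s,gyro_x,gyro_y,gyro_z,accel_x,accel_y,accel_z`, no comment lines.
#' Gyroscope columns are in deg/s, accelerometer columns in m/s^2, `time_s`
#' in session-relative seconds. Timestamps must be strictly increasing and
#' uniform: every interval must be within 1% (relative) of the median
#' interval, otherwise validation fails.
#'
#' @param source path to a CSV file, or a connection.
#' @param config an [io_config()].
#' @return An [imu_series()]. `t0` is the first timestamp in the file.
#' @export
read_imu_csv <- function(source, config = io_config()) {
  stopifnot(inherits(config, "io_config"))
  df <- tryCatch(
    utils::read.csv(source, header = TRUE, colClasses = "numeric",
                    check.names = TRUE),
    error = function(e) gait_format_error(paste0("cannot parse IMU CSV: ",
                                                 conditionMessage(e)))
  )
  missing <- setdiff(imu_csv_columns, names(df))
  if (length(missing) > 0) {
    gait_format_error(paste0("IMU CSV is missing required column(s): ",
                             paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) gait_empty_error("IMU CSV has a header but no data rows")
  t <- df$time_s
  if (anyNA(df) || any(!sapply(df[imu_csv_columns], is.finite))) {
    gait_validation_error("IMU CSV contains missing or non-finite values")
  }
  if (nrow(df) >= 2) {
    dt <- diff(t)
    if (any(dt <= 0)) {
      bad <- which(dt <= 0)[1] + 1
      gait_validation_error(sprintf(
        "time_s must be strictly increasing (violation at data row %d)", bad))
    }
    med <- stats::median(dt)
    if (any(abs(dt - med) > 0.01 * med)) {
      bad <- which(abs(dt - med) > 0.01 * med)[1] + 1
      gait_validation_error(sprintf(
        "non-uniform sampling: interval at data row %d deviates more than 1%% from the median",
        bad))
    }
    rate <- if (is.null(config$sample_rate)) 1 / med else config$sample_rate
  } else {
    rate <- if (is.null(config$sample_rate)) 100 else config$sample_rate
  }
  imu_series(
    gyro = as.matrix(df[, c("gyro_x", "gyro_y", "gyro_z")]),
    accel = as.matrix(df[, c("accel_x", "accel_y", "accel_z")]),
    sample_rate = rate, t0 = t[1]
  )
}

#' Write an IMU recording to CSV
#'
#' Emits exactly the dialect [read_imu_csv()] accepts; values are written
#' with 15 significant digits so a read/write round trip preserves them to
#' better than 1e-9 deg/s.
#'
#' @param series an [imu_series()].
#' @param sink output path or connection.
#' @return `sink`, invisibly.
#' @export
write_imu_csv <- function(series, sink) {
  stopifnot(inherits(series, "imu_series"))
  lines <- paste(imu_csv_columns, collapse = ",")
  if (series$n_samples > 0) {
    m <- cbind(imu_time(series), series$gyro, series$accel)
    rows <- apply(m, 1, function(r) paste(sprintf("%.15g", r), collapse = ","))
    lines <- c(lines, rows)
  }
  tryCatch(writeLines(lines, sink),
           error = function(e) abort_gait(paste0("cannot write IMU CSV: ",
                                                 conditionMessage(e)),
                                          "gait_io_error"))
  invisible(sink)
}
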