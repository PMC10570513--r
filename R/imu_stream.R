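#' IMU time series container
#'
#' One inertial sensor's synchronized recording: timestamps, 3-axis angular
#' rate (rad/s) and 3-axis specific force (m/s^2), optionally the device
#' orientation as unit quaternions (w, x, y, z; local-to-global).
#'
#' @param time numeric vector of timestamps in seconds, strictly increasing
#'   and approximately uniform.
#' @param gyro N x 3 matrix of angular rates in rad/s.
#' @param accel N x 3 matrix of specific force in m/s^2 (a static sensor
#'   reads +9.81 along the axis pointing up).
#' @param quat optional N x 4 matrix of unit quaternions (w, x, y, z).
#' @param rate nominal sampling rate in Hz; defaults to the reciprocal of the
#'   median sampling period.
#'
#' @return An object of class `imu_stream`: a list with elements `time`,
#'   `gyro`, `accel`, `quat` (possibly `NULL`), `rate` and `dt`.
#' @export
imu_stream <- function(time, gyro, accel, quat = NULL, rate = NULL) {
  time <- as.numeric(time)
  gyro <- as.matrix(gyro); accel <- as.matrix(accel)
  n <- length(time)
  if (n < 2) stop("an imu_stream needs at least 2 samples")
  if (nrow(gyro) != n || nrow(accel) != n)
    stop("time, gyro and accel must have equal lengths")
  if (ncol(gyro) != 3 || ncol(accel) != 3)
    stop("gyro and accel must have 3 columns")
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (!is.null(quat)) {
    quat <- as.matrix(quat)
    if (nrow(quat) != n || ncol(quat) != 4)
      stop("quat must be an N x 4 matrix (w, x, y, z)")
  }
  med_dt <- stats::median(dt)
  if (max(abs(dt - med_dt)) > 0.01 * med_dt)
    stop("sampling must be uniform within 1%")
  if (is.null(rate)) rate <- 1 / med_dt
  if (rate <= 0) stop("rate must be positive")
  if (anyNA(gyro) || anyNA(accel))
    stop("NaN/NA samples in gyro or accel; clean the stream first")
  structure(list(time = time, gyro = gyro, accel = accel, quat = quat,
                 rate = rate, dt = med_dt),
            class = "imu_stream")
}

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf("<imu_stream> %d samples @ %.1f Hz (%.1f s)%s\n",
              length(x$time), x$rate, diff(range(x$time)),
              if (is.null(x$quat)) "" else ", with orientation"))
  invisible(x)
}

#' @export
length.imu_stream <- function(x) length(x$time)

# internal: check two streams are time-aligned and equally long
check_aligned <- function(s1, s2) {
  if (length(s1$time) != length(s2$time))
    stop("streams have different lengths")
  if (max(abs(s1$time - s2$time)) > 0.5 * s1$dt)
    stop("streams are not time-aligned")
  invisible(TRUE)
}
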