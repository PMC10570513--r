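# Flexion/extension angle estimation from a calibrated sensor pair.
#
# Two independent angle sources are fused: integration of the angular-rate
# difference about the joint axis (smooth, drifts with gyro bias) and the
# angle between the joint-plane projections of the shifted accelerations
# (drift-free, noisy). A complementary filter blends them.

#' Joint angle by gyroscope integration
#'
#' Cumulative trapezoidal integral of `g1 . j1 - g2 . j2`, starting at 0.
#'
#' @param stream1,stream2 time-aligned [imu_stream] objects.
#' @param j1,j2 unit joint axes in the two local frames.
#' @return numeric vector, angle in degrees.
#' @export
gyro_angle <- function(stream1, stream2, j1, j2) {
  check_aligned(stream1, stream2)
  d <- drop(stream1$gyro %*% j1) - drop(stream2$gyro %*% j2)
  cumtrapz1(stream1$time, d) * DEG
}

#' Shift measured accelerations to the joint centre
#'
#' Removes the sensor's own rotational acceleration about the joint centre:
#' `a_tilde = a - Gamma_g(o)`. What remains is the joint-centre acceleration
#' expressed in the local frame.
#'
#' @param stream an [imu_stream].
#' @param o sensor offset from the joint centre, m (local frame).
#' @param gdot optional angular-rate derivative (defaults to central
#'   differences of the gyro).
#' @return N x 3 matrix of shifted accelerations, m/s^2.
#' @export
shift_accelerations <- function(stream, o, gdot = NULL) {
  if (is.null(gdot)) gdot <- central_diff(stream$gyro, stream$time)
  stream$accel - gamma_accel(stream$gyro, gdot, o)
}

#' Joint-plane basis for one sensor frame
#'
#' `x = j x c`, `y = j x x`: an orthogonal basis of the plane perpendicular
#' to the joint axis. `c` may be any vector not parallel to `j`; with
#' `c = "auto"` the standard basis vector with the smallest `|j . e|` is
#' used (best conditioning).
#'
#' @param j unit joint axis.
#' @param c reference 3-vector, or `"auto"`.
#' @return list with 3-vectors `x`, `y` and the `c` used.
#' @export
joint_plane_axes <- function(j, c = "auto") {
  j <- normalize3(j)
  if (identical(c, "auto")) {
    c <- diag(3)[, which.min(abs(j))]
  }
  x <- cross3(j, c)
  if (sqrt(sum(x^2)) < 1e-8)
    stop("degenerate plane reference: c is parallel to the joint axis; ",
         "use c = \"auto\"")
  y <- cross3(j, x)
  list(x = x, y = y, c = c)
}

#' Joint angle from shifted accelerations
#'
#' The signed angle between the joint-plane projections of the two shifted
#' accelerations, oriented so that it shares the [gyro_angle()] convention.
#' Samples where either projection is degenerate (joint-centre acceleration
#' nearly parallel to the axis) are returned as `NA`; the complementary
#' filter propagates through them on the gyro alone.
#'
#' @param atilde1,atilde2 N x 3 shifted accelerations (see
#'   [shift_accelerations()]).
#' @param j1,j2 unit joint axes.
#' @param c joint-plane reference vector or `"auto"` (see
#'   [joint_plane_axes()]).
#' @param min_projection minimum projection norm (m/s^2) below which a sample
#'   is marked invalid.
#' @return numeric vector of angles in degrees (unwrapped, continuous), with
#'   `NA` at degenerate samples.
#' @export
accel_angle <- function(atilde1, atilde2, j1, j2, c = "auto",
                        min_projection = 1e-6) {
  p1 <- joint_plane_axes(j1, c)
  p2 <- joint_plane_axes(j2, c)
  u1 <- drop(atilde1 %*% p1$x); v1 <- drop(atilde1 %*% p1$y)
  u2 <- drop(atilde2 %*% p2$x); v2 <- drop(atilde2 %*% p2$y)
  bad <- (u1^2 + v1^2) < min_projection^2 | (u2^2 + v2^2) < min_projection^2
  ang <- atan2(v2, u2) - atan2(v1, u1)
  ang[bad] <- NA_real_
  ok <- !is.na(ang)
  ang[ok] <- unwrap_rad(ang[ok])
  ang * DEG
}

#' Complementary-filter fusion of the two angle sources
#'
#' `alpha(t) = lambda * alpha_acc(t) +
#'   (1 - lambda) * (alpha(t - dt) + alpha_gyr(t) - alpha_gyr(t - dt))`:
#' the drift-free accelerometer angle corrects the smooth gyro-integrated
#' angle with weight `lambda` per sample. Initialized at the first valid
#' accelerometer angle. At samples where `alpha_acc` is `NA` the filter
#' propagates on the gyro increment alone.
#'
#' @param alpha_acc accelerometer angle, degrees (may contain `NA`).
#' @param alpha_gyr gyro-integrated angle, degrees.
#' @param lambda filter weight in `[0, 1]`; 0.02 suits 60 Hz gait data.
#' @param dt sample period, s (recorded in the result attributes only; the
#'   recursion itself is index-based).
#' @return fused angle, degrees.
#' @export
fuse_angles <- function(alpha_acc, alpha_gyr, lambda = 0.02, dt = 0.016) {
  if (length(alpha_acc) != length(alpha_gyr))
    stop("alpha_acc and alpha_gyr must have equal lengths")
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  if (dt <= 0) stop("dt must be positive")
  n <- length(alpha_gyr)
  out <- numeric(n)
  first <- which(!is.na(alpha_acc))[1]
  if (is.na(first)) stop("alpha_acc has no valid samples")
  out[1] <- if (first == 1) alpha_acc[1] else alpha_acc[first]
  for (k in 2:n) {
    pred <- out[k - 1] + alpha_gyr[k] - alpha_gyr[k - 1]
    out[k] <- if (is.na(alpha_acc[k])) pred
              else lambda * alpha_acc[k] + (1 - lambda) * pred
  }
  out
}

#' Angular velocity of an angle series
#'
#' Zero-phase low-pass filtering (second-order Butterworth applied forward
#' and backward, 6 Hz default cutoff) followed by central differences.
#'
#' @param angle angle series in degrees.
#' @param rate sampling rate, Hz.
#' @param cutoff low-pass cutoff, Hz.
#' @return angular velocity in deg/s.
#' @export
angular_velocity <- function(angle, rate, cutoff = 6) {
  sm <- lowpass_zero_phase(angle, rate, cutoff)
  central_diff(sm, seq_along(sm) / rate)
}

#' Gravity-free vertical acceleration from an oriented IMU
#'
#' Rotates the specific force to the global frame with the device
#' orientation quaternions, removes gravity, and returns the vertical (Z)
#' component. A stationary sensor reads 0; a free-falling one reads -9.81.
#'
#' @param stream an [imu_stream] with an orientation (`quat`) channel.
#' @return list of class `vertical_accel_series` with `time` (s) and
#'   `a_vert` (m/s^2).
#' @export
vertical_acceleration <- function(stream) {
  if (is.null(stream$quat))
    stop("stream has no orientation channel; vertical acceleration needs ",
         "device quaternions")
  glob <- quat_rotate_rows(stream$quat, stream$accel)
  # specific force f = R^T (a - g); hence a_z = (R f)_z + g_z = (R f)_z - 9.81
  structure(list(time = stream$time, a_vert = glob[, 3] + GRAVITY[3]),
            class = "vertical_accel_series")
}

#' Full flexion/extension angle chain for a calibrated joint
#'
#' Runs gyro integration, acceleration shifting, accelerometer-angle
#' computation and complementary-filter fusion for one sensor pair.
#'
#' @param stream1,stream2 time-aligned [imu_stream] objects.
#' @param geometry a [calibrate_joint()] result (or any list with `j1`,
#'   `j2`, `o1`, `o2`).
#' @param lambda,dt complementary-filter parameters (see [fuse_angles()]).
#' @param c joint-plane reference vector or `"auto"`.
#' @param velocity_cutoff low-pass cutoff (Hz) for [angular_velocity()].
#' @return An object of class `angle_series`: `time`, `alpha_gyr`,
#'   `alpha_acc`, `alpha` (fused) in degrees, `angular_velocity` in deg/s,
#'   and the `joint` label.
#' @export
joint_angles <- function(stream1, stream2, geometry, lambda = 0.02,
                         dt = NULL, c = "auto", velocity_cutoff = 6) {
  check_aligned(stream1, stream2)
  if (is.null(dt)) dt <- stream1$dt
  ag <- gyro_angle(stream1, stream2, geometry$j1, geometry$j2)
  at1 <- shift_accelerations(stream1, geometry$o1)
  at2 <- shift_accelerations(stream2, geometry$o2)
  aa <- accel_angle(at1, at2, geometry$j1, geometry$j2, c = c)
  al <- fuse_angles(aa, ag, lambda = lambda, dt = dt)
  av <- angular_velocity(al, stream1$rate, cutoff = velocity_cutoff)
  structure(list(time = stream1$time, alpha_gyr = ag, alpha_acc = aa,
                 alpha = al, angular_velocity = av,
                 joint = geometry$joint %||% "joint"),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series> %s: %d samples, fused range [%.1f, %.1f] deg\n",
              x$joint, length(x$time), min(x$alpha), max(x$alpha)))
  invisible(x)
}

#' Align an estimated angle series to a reference convention
#'
#' The hinge constraint identifies the joint axis only up to sign, and the
#' accelerometer angle only up to a constant mounting offset, so an
#' estimated flexion/extension series matches its reference up to sign and
#' offset. This helper resolves both (sign by correlation, offset by mean
#' difference), the standard step before computing validation errors against
#' a reference system.
#'
#' @param estimate,reference angle series in degrees (equal length).
#' @return the aligned estimate, degrees.
#' @export
align_angle_convention <- function(estimate, reference) {
  s <- if (stats::cor(estimate, reference) < 0) -1 else 1
  est <- s * estimate
  est - mean(est - reference)
}
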