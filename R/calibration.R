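# Joint-geometry identification from raw gyro/accel streams.
#
# A hinge constrains the two sensors' angular rates: their components
# orthogonal to the joint axis have equal magnitude at every instant. The
# axis directions (j1, j2, one per local frame) are found by minimizing the
# sum of squared differences of those magnitudes over a spherical
# parameterization. The joint-centre offsets (o1, o2) are found from the
# rigid-body constraint that both sensors, once their own rotational
# acceleration about the centre is removed, see the same joint-centre
# acceleration magnitude.

#' Unit vector from spherical coordinates (inclination, azimuth)
#'
#' @param phi inclination in radians (angle from the xy-plane).
#' @param theta azimuth in radians.
#' @return unit 3-vector `(cos(phi)cos(theta), cos(phi)sin(theta), sin(phi))`.
#' @export
spherical_to_unit <- function(phi, theta) {
  c(cos(phi) * cos(theta), cos(phi) * sin(theta), sin(phi))
}

#' Spherical coordinates (inclination, azimuth) of a unit vector
#' @param j unit 3-vector.
#' @return named vector `c(phi, theta)` in radians.
#' @export
unit_to_spherical <- function(j) {
  j <- normalize3(j)
  c(phi = asin(max(-1, min(1, j[3]))), theta = atan2(j[2], j[1]))
}

#' Rigid-body acceleration of a point offset from a rotation centre
#'
#' The radial plus tangential acceleration `g x (g x o) + gdot x o` of a
#' sensor located at offset `o` from the joint centre, given the local
#' angular rate `g` and its derivative `gdot`.
#'
#' @param g angular rate, rad/s: 3-vector or N x 3 matrix.
#' @param g_dot angular acceleration, rad/s^2: same shape as `g`.
#' @param o offset from the joint centre to the sensor, m (3-vector).
#' @return acceleration in m/s^2, same shape as `g`.
#' @export
gamma_accel <- function(g, g_dot, o) {
  cross3(g, cross3(g, o)) + cross3(g_dot, o)
}

#' Per-sample residuals of the hinge gyroscope constraint
#'
#' `||g1 x j1|| - ||g2 x j2||` with axes given in spherical coordinates.
#'
#' @param stream1,stream2 time-aligned [imu_stream] objects.
#' @param phi1,theta1,phi2,theta2 spherical coordinates of the two axes (rad).
#' @return numeric vector of residuals in rad/s, one per sample.
#' @export
axis_residuals <- function(stream1, stream2, phi1, theta1, phi2, theta2) {
  check_aligned(stream1, stream2)
  j1 <- spherical_to_unit(phi1, theta1)
  j2 <- spherical_to_unit(phi2, theta2)
  row_norms(cross3(stream1$gyro, j1)) - row_norms(cross3(stream2$gyro, j2))
}

#' Per-sample residuals of the joint-centre constraint
#'
#' `||a1 - Gamma_g1(o1)|| - ||a2 - Gamma_g2(o2)||`: once each sensor's own
#' rotational acceleration about the joint centre is removed, both should see
#' the joint-centre acceleration, whose magnitude is frame-independent.
#'
#' @param stream1,stream2 time-aligned [imu_stream] objects.
#' @param o1,o2 sensor offsets from the joint centre in local frames (m).
#' @param gdot1,gdot2 optional angular-rate derivatives (N x 3, rad/s^2);
#'   computed by central differences of the gyro when omitted.
#' @return numeric vector of residuals in m/s^2, one per sample.
#' @export
center_residuals <- function(stream1, stream2, o1, o2,
                             gdot1 = NULL, gdot2 = NULL) {
  check_aligned(stream1, stream2)
  if (is.null(gdot1)) gdot1 <- central_diff(stream1$gyro, stream1$time)
  if (is.null(gdot2)) gdot2 <- central_diff(stream2$gyro, stream2$time)
  row_norms(stream1$accel - gamma_accel(stream1$gyro, gdot1, o1)) -
    row_norms(stream2$accel - gamma_accel(stream2$gyro, gdot2, o2))
}

# default deterministic optimizer starts for the 4-D axis problem
axis_fit_starts <- function() {
  list(c(0, 0), c(0, pi / 2), c(pi / 4, pi), c(-pi / 4, -pi / 2))
}

#' Identify the hinge axis directions from gyroscope data
#'
#' Minimizes the sum of squared [axis_residuals()] over the spherical
#' parameterization of both axes with the Levenberg-Marquardt least-squares
#' algorithm, restarted from four deterministic initial points (the objective
#' has mirror minima). Walking data with clear flexion/extension excitation
#' is the intended input.
#'
#' @param stream1,stream2 time-aligned [imu_stream] objects.
#' @param excitation_floor minimum standard deviation of the gyro magnitude
#'   (rad/s) required on both streams; static data is uninformative.
#' @param control optional [minpack.lm::nls.lm.control()] list.
#' @return list with unit vectors `j1`, `j2`, `axis_residual_rms` (rad/s),
#'   `spherical` (phi1, theta1, phi2, theta2) and `sse`.
#' @export
estimate_joint_axes <- function(stream1, stream2, excitation_floor = 0.2,
                                control = NULL) {
  check_aligned(stream1, stream2)
  sd1 <- stats::sd(row_norms(stream1$gyro))
  sd2 <- stats::sd(row_norms(stream2$gyro))
  if (min(sd1, sd2) <= excitation_floor)
    stop(sprintf(paste0("insufficient excitation: gyro-magnitude sd = %.3f ",
                        "rad/s (floor %.2f); record varied joint motion"),
                 min(sd1, sd2), excitation_floor))
  control <- control %||% minpack.lm::nls.lm.control(maxiter = 200)
  fn <- function(par) axis_residuals(stream1, stream2,
                                     par[1], par[2], par[3], par[4])
  best <- NULL
  for (st in axis_fit_starts()) {
    fit <- minpack.lm::nls.lm(par = c(st, st), fn = fn, control = control)
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  par <- best$fit$par
  res <- fn(par)
  list(j1 = spherical_to_unit(par[1], par[2]),
       j2 = spherical_to_unit(par[3], par[4]),
       axis_residual_rms = sqrt(mean(res^2)),
       spherical = c(phi1 = par[1], theta1 = par[2],
                     phi2 = par[3], theta2 = par[4]),
       sse = best$sse)
}

#' Identify the joint-centre offsets from accelerometer data
#'
#' Minimizes the sum of squared [center_residuals()] over (o1, o2) in R^6
#' with Levenberg-Marquardt. The component of each offset along its joint
#' axis is unobservable (translating a point along a hinge axis changes
#' nothing); it is projected out of the returned estimates.
#'
#' @param stream1,stream2 time-aligned [imu_stream] objects; arbitrary
#'   "circling" motion with rich angular acceleration is the intended input.
#' @param j1,j2 unit joint axes from [estimate_joint_axes()].
#' @param gdot1,gdot2 optional angular-rate derivatives (see
#'   [center_residuals()]).
#' @param excitation_floor minimum gyro-magnitude sd (rad/s).
#' @param control optional [minpack.lm::nls.lm.control()] list.
#' @return list with `o1`, `o2` (m, axis component removed),
#'   `center_residual_rms` (m/s^2) and `sse`.
#' @export
estimate_joint_centers <- function(stream1, stream2, j1, j2,
                                   gdot1 = NULL, gdot2 = NULL,
                                   excitation_floor = 0.2, control = NULL) {
  check_aligned(stream1, stream2)
  sdm <- min(stats::sd(row_norms(stream1$gyro)),
             stats::sd(row_norms(stream2$gyro)))
  if (sdm <= excitation_floor)
    stop(sprintf(paste0("insufficient excitation for centre identification ",
                        "(gyro-magnitude sd = %.3f rad/s): near-constant ",
                        "rotation makes the problem degenerate"), sdm))
  if (is.null(gdot1)) gdot1 <- central_diff(stream1$gyro, stream1$time)
  if (is.null(gdot2)) gdot2 <- central_diff(stream2$gyro, stream2$time)
  control <- control %||% minpack.lm::nls.lm.control(maxiter = 200)
  fn <- function(par) center_residuals(stream1, stream2,
                                       par[1:3], par[4:6], gdot1, gdot2)
  fit <- minpack.lm::nls.lm(par = rep(0, 6), fn = fn, control = control)
  o1 <- fit$par[1:3]; o2 <- fit$par[4:6]
  j1 <- normalize3(j1); j2 <- normalize3(j2)
  # the solution is identifiable only up to a common slide along the axis
  # (o1 + s*j1, o2 + s*j2); projecting each offset off its own axis is a
  # slide-invariant canonical representative for reporting
  o1 <- o1 - sum(o1 * j1) * j1
  o2 <- o2 - sum(o2 * j2) * j2
  res <- fit$fvec        # residuals at the optimum, before canonicalization
  list(o1 = o1, o2 = o2,
       center_residual_rms = sqrt(mean(res^2)), sse = sum(res^2))
}

#' Make estimated axis signs deterministic and mutually consistent
#'
#' The gyroscope objective is invariant to flipping either axis. The sign of
#' `j1` is fixed so its largest-magnitude component is positive; the sign of
#' `j2` is chosen so the axis-projected angular rates `g1 . j1` and
#' `g2 . j2` correlate non-negatively over the record (both sensors see the
#' same base rotation about the axis).
#'
#' @param j1,j2 estimated unit axes.
#' @param stream1,stream2 the streams the axes were estimated from.
#' @return list with sign-resolved `j1`, `j2`.
#' @export
resolve_axis_sign <- function(j1, j2, stream1, stream2) {
  if (j1[which.max(abs(j1))] < 0) j1 <- -j1
  p1 <- drop(stream1$gyro %*% j1)
  p2 <- drop(stream2$gyro %*% j2)
  r <- suppressWarnings(stats::cor(p1, p2))
  if (is.na(r) || abs(r) < 0.05) {
    warning("axis-projected rates are nearly uncorrelated; ",
            "sign of j2 left as estimated")
  } else if (r < 0) {
    j2 <- -j2
  }
  list(j1 = j1, j2 = j2)
}

#' Calibrate a hinge joint from walking and circling recordings
#'
#' Full joint-geometry identification: axis directions from a walking
#' segment (clear flexion/extension), centre offsets from a circling segment
#' (rich arbitrary motion), then axis-sign resolution on the walking data.
#'
#' @param walk1,walk2 [imu_stream] pair recorded while walking.
#' @param circle1,circle2 [imu_stream] pair recorded during arbitrary
#'   circling movements (defaults to the walking pair if omitted, with a
#'   warning: centre accuracy suffers without rich excitation).
#' @param gdot1,gdot2 optional analytic angular-rate derivatives for the
#'   circling pair.
#' @param joint optional label ("hip", "knee", "ankle", ...).
#' @return An object of class `joint_geometry`: unit axes `j1`, `j2`, centre
#'   offsets `o1`, `o2` (m; axis-parallel component removed), residual RMS
#'   values, spherical axis parameters, and the label.
#' @export
calibrate_joint <- function(walk1, walk2, circle1 = NULL, circle2 = NULL,
                            gdot1 = NULL, gdot2 = NULL, joint = "joint") {
  if (is.null(circle1) || is.null(circle2)) {
    warning("no circling segment supplied; using the walking segment for ",
            "centre identification")
    circle1 <- walk1; circle2 <- walk2
  }
  ax <- estimate_joint_axes(walk1, walk2)
  sg <- resolve_axis_sign(ax$j1, ax$j2, walk1, walk2)
  ce <- estimate_joint_centers(circle1, circle2, sg$j1, sg$j2,
                               gdot1 = gdot1, gdot2 = gdot2)
  structure(list(joint = joint, j1 = sg$j1, j2 = sg$j2,
                 o1 = ce$o1, o2 = ce$o2,
                 axis_residual_rms = ax$axis_residual_rms,
                 center_residual_rms = ce$center_residual_rms,
                 spherical = ax$spherical),
            class = "joint_geometry")
}

#' @export
print.joint_geometry <- function(x, ...) {
  cat(sprintf("<joint_geometry> %s\n", x$joint))
  cat(sprintf("  j1: [%s]   j2: [%s]\n",
              paste(sprintf("%+.4f", x$j1), collapse = " "),
              paste(sprintf("%+.4f", x$j2), collapse = " ")))
  cat(sprintf("  o1: [%s] m  o2: [%s] m\n",
              paste(sprintf("%+.4f", x$o1), collapse = " "),
              paste(sprintf("%+.4f", x$o2), collapse = " ")))
  cat(sprintf("  residual RMS: axis %.4g rad/s, centre %.4g m/s^2\n",
              x$axis_residual_rms, x$center_residual_rms))
  invisible(x)
}

#' @export
coef.joint_geometry <- function(object, ...) {
  c(object$spherical, o1 = object$o1, o2 = object$o2)
}
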