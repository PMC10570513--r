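# Synthetic rigid two-segment hinge with IMUs at arbitrary mounting pose.
#
# Construction: a "base" frame carries both segments. The hinge axis is e_z in
# the base frame; segment 1 is rigidly attached to the base, segment 2 rotates
# about the axis by the joint angle alpha(t). The whole base undergoes a
# smooth rotation B(t) (two-axis sinusoidal composition) and the joint centre
# translates along a smooth 3-D path. Sensor mounting rotations are chosen so
# the requested axis/centre coordinates are the exact local-frame geometry,
# and all angular velocities/accelerations are evaluated analytically, so the
# hinge constraints on the gyroscopes and the rigid-body accelerations hold to
# machine precision at zero noise.

#' Configuration for the hinge-joint simulator
#'
#' @param duration recording length in seconds.
#' @param rate sampling rate in Hz.
#' @param true_axis_1,true_axis_2 unit 3-vectors: the hinge axis expressed in
#'   each sensor's local frame (ground truth for calibration).
#' @param true_center_1,true_center_2 3-vectors (m): offset from each sensor's
#'   origin to the joint centre, in the local frame.
#' @param angle_waveform `"gait"` (two-harmonic flexion-like profile) or
#'   `"sinusoid"`.
#' @param amplitude_deg joint-angle amplitude in degrees.
#' @param frequency joint-angle fundamental frequency in Hz (one gait cycle
#'   per period for the gait-like profile).
#' @param motion `"walking"` (moderate base rotation, for axis calibration)
#'   or `"circling"` (rich arbitrary base rotation and translation, for
#'   centre calibration).
#' @param base_motion_amplitude translation amplitude of the joint centre (m).
#' @param gyro_noise_sd,accel_noise_sd additive white-noise standard
#'   deviations (rad/s, m/s^2).
#' @param gyro_bias constant bias of sensor 1's gyroscope, rad/s; scalar
#'   (applied to every axis) or per-axis 3-vector. Applied to one sensor
#'   because only the *relative* bias drifts the integrated joint angle; a
#'   common-mode bias largely cancels in the axis-projected difference.
#' @param gyro_bias_2 constant bias of sensor 2's gyroscope (default 0).
#' @param seed integer seed for the noise generator.
#' @return A list of class `hinge_sim_config`.
#' @export
hinge_sim_config <- function(duration = 60, rate = 60,
                             true_axis_1 = c(0, 0, 1),
                             true_axis_2 = c(1, 0, 0),
                             true_center_1 = c(0.15, 0.02, -0.03),
                             true_center_2 = c(-0.12, 0.04, 0.02),
                             angle_waveform = c("gait", "sinusoid"),
                             amplitude_deg = 50, frequency = 1,
                             motion = c("walking", "circling"),
                             base_motion_amplitude = 0.05,
                             gyro_noise_sd = 0, accel_noise_sd = 0,
                             gyro_bias = 0, gyro_bias_2 = 0, seed = NULL) {
  angle_waveform <- match.arg(angle_waveform)
  motion <- match.arg(motion)
  if (rate <= 0) stop("rate must be positive")
  if (duration <= 0) stop("duration must be positive")
  if (gyro_noise_sd < 0 || accel_noise_sd < 0)
    stop("noise standard deviations must be non-negative")
  for (ax in list(true_axis_1, true_axis_2)) {
    if (length(ax) != 3 || abs(sqrt(sum(ax^2)) - 1) > 1e-6)
      stop("joint axes must be unit 3-vectors")
  }
  if (length(gyro_bias) == 1) gyro_bias <- rep(gyro_bias, 3)
  if (length(gyro_bias_2) == 1) gyro_bias_2 <- rep(gyro_bias_2, 3)
  structure(list(duration = duration, rate = rate,
                 true_axis_1 = true_axis_1, true_axis_2 = true_axis_2,
                 true_center_1 = true_center_1, true_center_2 = true_center_2,
                 angle_waveform = angle_waveform,
                 amplitude_deg = amplitude_deg, frequency = frequency,
                 motion = motion,
                 base_motion_amplitude = base_motion_amplitude,
                 gyro_noise_sd = gyro_noise_sd,
                 accel_noise_sd = accel_noise_sd,
                 gyro_bias = gyro_bias, gyro_bias_2 = gyro_bias_2,
                 seed = seed),
            class = "hinge_sim_config")
}

# analytic waveform: value, first and second derivative (radians)
hinge_waveform <- function(type, amplitude_deg, f) {
  A <- amplitude_deg / DEG
  w <- 2 * pi * f
  if (type == "sinusoid") {
    list(f0 = function(t) A * sin(w * t),
         f1 = function(t) A * w * cos(w * t),
         f2 = function(t) -A * w^2 * sin(w * t))
  } else {
    # flexion-like double-harmonic profile: stays mostly one-sided with a
    # large swing peak, loosely shaped like a knee flexion curve
    list(f0 = function(t) A * (0.35 + 0.30 * sin(w * t) +
                                 0.25 * sin(2 * w * t + 1)),
         f1 = function(t) A * w * (0.30 * cos(w * t) +
                                     0.50 * cos(2 * w * t + 1)),
         f2 = function(t) -A * w^2 * (0.30 * sin(w * t) +
                                        1.00 * sin(2 * w * t + 1)))
  }
}

#' Simulate a rigid hinge joint observed by two IMUs
#'
#' Generates the exact angular rates and specific forces of two sensors
#' mounted on the segments of a hinge joint, plus ground truth for the joint
#' geometry and angle. At zero noise the gyroscope hinge constraint and the
#' shifted-acceleration constraint hold to machine precision at the true
#' parameters.
#'
#' @param config a [hinge_sim_config()].
#' @return A list of class `hinge_sim` with elements `stream1`, `stream2`
#'   ([imu_stream] objects) and `truth` (joint geometry, joint angle in
#'   degrees, angular velocity, mounting rotations and the noise-free
#'   signals).
#' @export
simulate_hinge <- function(config) {
  stopifnot(inherits(config, "hinge_sim_config"))
  n <- round(config$duration * config$rate)
  t <- seq(0, by = 1 / config$rate, length.out = n)
  nb <- c(0, 0, 1)                      # hinge axis in the base frame
  u2 <- c(1, 0, 0)                      # second base-rotation axis

  # base rotation amplitudes/frequencies per motion regime
  if (config$motion == "walking") {
    Ar <- c(0.35, 0.18); fr <- c(0.7, 0.9); ph <- c(0, 0.8)
    fp <- c(0.55, 0.75, 0.95)
  } else {
    Ar <- c(0.7, 0.55); fr <- c(0.45, 0.8); ph <- c(0.3, 1.7)
    fp <- c(0.4, 0.65, 0.9)
  }
  wr <- 2 * pi * fr
  a  <- Ar[1] * sin(wr[1] * t + ph[1]); ad  <- Ar[1] * wr[1] * cos(wr[1] * t + ph[1])
  add <- -Ar[1] * wr[1]^2 * sin(wr[1] * t + ph[1])
  b  <- Ar[2] * sin(wr[2] * t + ph[2]); bd  <- Ar[2] * wr[2] * cos(wr[2] * t + ph[2])
  bdd <- -Ar[2] * wr[2]^2 * sin(wr[2] * t + ph[2])

  wf <- hinge_waveform(config$angle_waveform, config$amplitude_deg,
                       config$frequency)
  alpha <- wf$f0(t); alphad <- wf$f1(t); alphadd <- wf$f2(t)

  # joint-centre translation and its second derivative
  wp <- 2 * pi * fp
  amp <- config$base_motion_amplitude
  p   <- cbind(amp * sin(wp[1] * t), amp * sin(wp[2] * t + 1),
               amp * sin(wp[3] * t + 2))
  pdd <- cbind(-amp * wp[1]^2 * sin(wp[1] * t),
               -amp * wp[2]^2 * sin(wp[2] * t + 1),
               -amp * wp[3]^2 * sin(wp[3] * t + 2))

  # mounting rotations: A_i maps the requested local axis onto nb
  A1 <- align_rotation(config$true_axis_1, nb)
  A2 <- align_rotation(config$true_axis_2, nb)

  # B(t) = Rot(nb, a) %*% Rot(u2, b); apply/invert via two Rodrigues passes
  B_apply <- function(v) rotate_rows(rotate_rows(v, u2, b), nb, a)
  B_inv   <- function(v) rotate_rows(rotate_rows(v, nb, -a), u2, -b)

  # angular velocity/acceleration of the base and of segment 2 (global frame)
  wvec  <- rotate_rows(u2, nb, a)                 # Rot(nb,a) u2, per sample
  OmB   <- outer(ad, nb) + wvec * bd
  OmBd  <- outer(add, nb) + wvec * bdd + cross3(outer(ad, nb), wvec) * bd
  ng    <- B_apply(matrix(nb, n, 3, byrow = TRUE)) # global hinge axis
  Om1   <- OmB
  Om1d  <- OmBd
  Om2   <- OmB - ng * alphad
  Om2d  <- OmBd - ng * alphadd - cross3(OmB, ng) * alphad

  # local gyro: g_i = R_i^T Omega_i ; R1 = B A1, R2 = B Rot(nb,-alpha) A2
  R1_inv <- function(v) t(t(A1) %*% t(B_inv(v)))
  R2_inv <- function(v) t(t(A2) %*% t(rotate_rows(B_inv(v), nb, alpha)))
  R1_fwd <- function(v_local) B_apply(t(A1 %*% t(v_local)))
  R2_fwd <- function(v_local) B_apply(rotate_rows(t(A2 %*% t(v_local)), nb, -alpha))

  g1 <- R1_inv(Om1)
  g2 <- R2_inv(Om2)

  # sensor positions r_i = p + R_i o_i (o_i is the sensor offset relative to
  # the joint centre, the convention under which a - Gamma(o) recovers the
  # joint-centre acceleration); accelerations analytically
  Ro1 <- R1_fwd(matrix(config$true_center_1, n, 3, byrow = TRUE))
  Ro2 <- R2_fwd(matrix(config$true_center_2, n, 3, byrow = TRUE))
  r1dd <- pdd + cross3(Om1d, Ro1) + cross3(Om1, cross3(Om1, Ro1))
  r2dd <- pdd + cross3(Om2d, Ro2) + cross3(Om2, cross3(Om2, Ro2))
  # The base frame is tilted ~80 deg w.r.t. the world so the hinge axis is
  # near-horizontal, as flexion/extension axes are during gait: gravity then
  # lies mostly in the joint plane and carries angle information. Only
  # gravity needs re-expressing; the dynamics above live in the base frame.
  W <- rot_axis_angle(c(1, 0, 0), 1.4)
  gmat <- matrix(drop(t(W) %*% GRAVITY), n, 3, byrow = TRUE)
  a1 <- R1_inv(r1dd - gmat)
  a2 <- R2_inv(r2dd - gmat)

  # analytic local gyro derivative: d/dt (R^T Omega) = R^T Omega_dot
  clean <- list(gyro1 = g1, gyro2 = g2, accel1 = a1, accel2 = a2,
                gyro_dot1 = R1_inv(Om1d), gyro_dot2 = R2_inv(Om2d))

  if (!is.null(config$seed)) set.seed(config$seed)
  noisy <- function(x, sd) if (sd > 0) x + matrix(stats::rnorm(3 * n, sd = sd), n, 3) else x
  g1n <- noisy(g1, config$gyro_noise_sd)
  g2n <- noisy(g2, config$gyro_noise_sd)
  if (any(config$gyro_bias != 0))
    g1n <- g1n + matrix(config$gyro_bias, n, 3, byrow = TRUE)
  if (any(config$gyro_bias_2 != 0))
    g2n <- g2n + matrix(config$gyro_bias_2, n, 3, byrow = TRUE)
  a1n <- noisy(a1, config$accel_noise_sd)
  a2n <- noisy(a2, config$accel_noise_sd)

  truth <- list(
    geometry = list(j1 = config$true_axis_1, j2 = config$true_axis_2,
                    o1 = config$true_center_1, o2 = config$true_center_2),
    angle_deg = alpha * DEG,
    angular_velocity_dps = alphad * DEG,
    time = t,
    mounting = list(A1 = A1, A2 = A2),
    clean = clean
  )
  structure(list(stream1 = imu_stream(t, g1n, a1n, rate = config$rate),
                 stream2 = imu_stream(t, g2n, a2n, rate = config$rate),
                 truth = truth, config = config),
            class = "hinge_sim")
}
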