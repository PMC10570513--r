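# Reproducible simulation experiments used for validating the angle chain.

# representative hinge geometries (axes/centre offsets in sensor frames) and
# gait-like waveform amplitudes for the three lower-limb joints
joint_experiment_presets <- function() {
  nz <- function(v) v / sqrt(sum(v^2))
  list(
    hip = list(j1 = nz(c(0.15, 0.95, 0.27)), j2 = nz(c(-0.20, 0.90, -0.37)),
               o1 = c(0.10, 0.03, -0.06), o2 = c(-0.05, 0.02, 0.22),
               amplitude_deg = 45),
    knee = list(j1 = nz(c(0.90, 0.30, 0.31)), j2 = nz(c(0.05, 0.99, -0.13)),
                o1 = c(0.06, -0.02, -0.21), o2 = c(0.04, 0.01, 0.23),
                amplitude_deg = 60),
    ankle = list(j1 = nz(c(0.30, -0.20, 0.93)), j2 = nz(c(0.70, 0.70, 0.14)),
                 o1 = c(0.04, 0.02, -0.24), o2 = c(0.09, -0.01, 0.06),
                 amplitude_deg = 30)
  )
}

#' Joint-angle accuracy experiment on simulated noisy hinge motion
#'
#' For each joint preset and seed: simulate noisy walking and circling
#' calibration recordings, identify the joint geometry, simulate an
#' independent noisy gait-like measurement recording, run the full angle
#' chain (gyro integration, acceleration shifting, accelerometer angle,
#' complementary-filter fusion), align the estimate to the ground-truth
#' convention, and report the RMSE of the fused angle alongside the
#' RMSEs of the two unfused sources over the evaluation window.
#'
#' @param n_seeds Monte-Carlo repetitions per joint.
#' @param joints subset of `c("hip", "knee", "ankle")` presets.
#' @param duration,rate measurement recording length (s) and rate (Hz).
#' @param gyro_noise_sd,accel_noise_sd,gyro_bias sensor imperfections
#'   (rad/s, m/s^2, rad/s).
#' @param calib_duration length of each calibration segment, s.
#' @param skip_initial evaluation starts after this many seconds (filter
#'   convergence excluded).
#' @param lambda,dt complementary-filter parameters.
#' @param seed base seed.
#' @return data frame with one row per joint x seed: `rmse_fused`,
#'   `rmse_gyro`, `rmse_acc` (degrees), plus axis errors (degrees).
#' @export
angle_accuracy_experiment <- function(n_seeds = 20,
                                      joints = c("hip", "knee", "ankle"),
                                      duration = 60, rate = 60,
                                      gyro_noise_sd = 0.01,
                                      accel_noise_sd = 0.1,
                                      gyro_bias = 0.005,
                                      calib_duration = 30,
                                      skip_initial = 10,
                                      lambda = 0.02, dt = 0.016,
                                      seed = 1) {
  presets <- joint_experiment_presets()[joints]
  rows <- list()
  for (j in names(presets)) {
    p <- presets[[j]]
    for (s in seq_len(n_seeds)) {
      sd0 <- (seed + 7919L * s + 104729L * match(j, names(presets))) %% 2000000000L
      base <- list(rate = rate, true_axis_1 = p$j1, true_axis_2 = p$j2,
                   true_center_1 = p$o1, true_center_2 = p$o2,
                   amplitude_deg = p$amplitude_deg,
                   gyro_noise_sd = gyro_noise_sd,
                   accel_noise_sd = accel_noise_sd, gyro_bias = gyro_bias)
      walk <- simulate_hinge(do.call(hinge_sim_config,
        c(base, list(duration = calib_duration, motion = "walking",
                     angle_waveform = "gait", seed = sd0 + 1))))
      circ <- simulate_hinge(do.call(hinge_sim_config,
        c(base, list(duration = calib_duration, motion = "circling",
                     angle_waveform = "gait", seed = sd0 + 2))))
      geo <- calibrate_joint(walk$stream1, walk$stream2,
                             circ$stream1, circ$stream2, joint = j)
      meas <- simulate_hinge(do.call(hinge_sim_config,
        c(base, list(duration = duration, motion = "walking",
                     angle_waveform = "gait", seed = sd0 + 3))))
      ang <- joint_angles(meas$stream1, meas$stream2, geo,
                          lambda = lambda, dt = dt)
      truth <- meas$truth$angle_deg
      keep <- meas$truth$time >= skip_initial
      er <- function(est, k = keep) {
        ok <- !is.na(est) & k
        a <- align_angle_convention(est[!is.na(est)], truth[!is.na(est)])
        full <- rep(NA_real_, length(est)); full[!is.na(est)] <- a
        sqrt(mean((full[ok] - truth[ok])^2))
      }
      ang_deg <- function(a, b) acos(min(1, abs(sum(a * b)))) * DEG
      rows[[length(rows) + 1]] <- data.frame(
        joint = j, seed = s,
        rmse_fused = er(ang$alpha),
        rmse_gyro = er(ang$alpha_gyr),
        rmse_acc = er(ang$alpha_acc),
        axis_err_1 = ang_deg(geo$j1, p$j1),
        axis_err_2 = ang_deg(geo$j2, p$j2))
    }
  }
  do.call(rbind, rows)
}
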