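# End-to-end synthetic study: simulate a cohort, calibrate every joint from
# dedicated walking/circling recordings, run the angle chain, detect events,
# build the cycle dataset, train both regressors under both feature sets,
# and evaluate.

# pair up IMU and force contact times recorded on a common clock
match_contact_times <- function(imu_times, grf_times, tol) {
  if (length(imu_times) == 0 || length(grf_times) == 0)
    return(list(imu = numeric(0), grf = numeric(0)))
  ki <- integer(0); kg <- integer(0)
  for (g in seq_along(grf_times)) {
    d <- abs(imu_times - grf_times[g])
    i <- which.min(d)
    if (d[i] <= tol && !(i %in% ki)) { ki <- c(ki, i); kg <- c(kg, g) }
  }
  list(imu = imu_times[ki], grf = grf_times[kg])
}

#' Extract the per-trial cycle dataset from one simulated gait trial
#'
#' Runs the measurement pipeline on a [simulate_gait_trial()] result: fused
#' joint angles from the calibrated geometries, angular velocities, C7
#' vertical acceleration, contact detection in both modalities,
#' cycle normalization and label assignment.
#'
#' @param trial a [simulate_gait_trial()] result.
#' @param geometries named list (`hip`, `knee`, `ankle`) of calibration
#'   results; defaults to the trial's ground-truth geometry.
#' @param subject,speed metadata for the rows.
#' @param grid_length cycle-grid length (101 = 0..100%).
#' @param lambda complementary-filter weight.
#' @param contact_source `"detected"` (both modalities detected and matched
#'   on the shared clock) or `"truth"` (simulator contact times, useful for
#'   isolating later stages).
#' @return a `cycle_dataset` data frame (possibly 0 rows).
#' @export
trial_cycle_dataset <- function(trial, geometries = NULL, subject = 1L,
                                speed = trial$speed, grid_length = 101,
                                lambda = 0.02, contact_source = "detected") {
  if (is.null(geometries)) geometries <- trial$truth$geometry
  st <- trial$streams
  rate <- st$hip$rate
  pairs <- list(hip = list(st$hip, st$thigh),
                knee = list(st$thigh, st$leg),
                ankle = list(st$leg, st$foot))
  ang <- lapply(names(pairs), function(j)
    joint_angles(pairs[[j]][[1]], pairs[[j]][[2]], geometries[[j]],
                 lambda = lambda))
  names(ang) <- names(pairs)
  va <- vertical_acceleration(st$c7)

  if (contact_source == "truth") {
    tc <- trial$truth$contacts
    ci <- tc; cg <- tc
  } else {
    ap_global <- quat_rotate_rows(st$hip$quat, st$hip$accel)[, 1]
    imu_c <- detect_contacts_imu(ap_global, rate)
    grf_c <- detect_contacts_grf(trial$force$vgrf, trial$force$time)
    if (length(grf_c$times) < 2 || length(imu_c$times) < 2)
      return(synchronize_cycles(list(), matrix(numeric(0), 0, grid_length),
                                seq(0, 100, length.out = grid_length),
                                subject, speed))
    tol <- 0.3 * stats::median(diff(grf_c$times))
    m <- match_contact_times(imu_c$times, grf_c$times, tol)
    ci <- m$imu; cg <- m$grf
  }
  if (length(ci) < 2)
    return(synchronize_cycles(list(), matrix(numeric(0), 0, grid_length),
                              seq(0, 100, length.out = grid_length),
                              subject, speed))

  seg <- function(x, tt, contacts)
    segment_and_normalize(tt, x, contacts, grid_length)
  imu_cycles <- list(
    hip_angle = seg(ang$hip$alpha, trial$time, ci)$cycles,
    knee_angle = seg(ang$knee$alpha, trial$time, ci)$cycles,
    ankle_angle = seg(ang$ankle$alpha, trial$time, ci)$cycles,
    hip_velocity = seg(ang$hip$angular_velocity, trial$time, ci)$cycles,
    knee_velocity = seg(ang$knee$angular_velocity, trial$time, ci)$cycles,
    ankle_velocity = seg(ang$ankle$angular_velocity, trial$time, ci)$cycles,
    a_vert = seg(va$a_vert, trial$time, ci)$cycles)
  sg <- seg(trial$force$vgrf, trial$force$time, cg)
  synchronize_cycles(imu_cycles, sg$cycles, sg$grid, subject, speed)
}

#' Simulate calibration recordings and calibrate one subject's joints
#'
#' For each joint, a walking-like and a circling hinge recording are
#' generated at the subject's true sensor geometry and passed through
#' [calibrate_joint()].
#'
#' @param geometry_truth per-joint true geometry
#'   (`subject_joint_geometry()` layout).
#' @param duration calibration segment length, s.
#' @param rate sampling rate, Hz.
#' @param gyro_noise_sd,accel_noise_sd,gyro_bias sensor imperfections.
#' @param seed integer seed.
#' @return named list of `joint_geometry` objects.
#' @export
calibrate_subject <- function(geometry_truth, duration = 30, rate = 60,
                              gyro_noise_sd = 0.005, accel_noise_sd = 0.05,
                              gyro_bias = 0.002, seed = 1) {
  out <- list()
  k <- 0
  for (j in names(geometry_truth)) {
    k <- k + 1
    g <- geometry_truth[[j]]
    base <- list(duration = duration, rate = rate,
                 true_axis_1 = g$j1, true_axis_2 = g$j2,
                 true_center_1 = g$o1, true_center_2 = g$o2,
                 gyro_noise_sd = gyro_noise_sd,
                 accel_noise_sd = accel_noise_sd, gyro_bias = gyro_bias)
    walk <- simulate_hinge(do.call(hinge_sim_config,
                                   c(base, list(motion = "walking",
                                                seed = seed + 2 * k))))
    circ <- simulate_hinge(do.call(hinge_sim_config,
                                   c(base, list(motion = "circling",
                                                seed = seed + 2 * k + 1))))
    out[[j]] <- calibrate_joint(walk$stream1, walk$stream2,
                                circ$stream1, circ$stream2, joint = j)
  }
  out
}

#' Run the full synthetic vGRF study
#'
#' Simulates a cohort, calibrates each subject's hip/knee/ankle geometry
#' from dedicated recordings, extracts cycle datasets through the full
#' measurement chain, splits intra/inter subjects, trains the requested
#' models under the requested feature sets, and evaluates each partition.
#'
#' @param config a [gait_sim_config()].
#' @param n_inter number of held-out (inter-participant) subjects.
#' @param models character subset of `c("rf", "fnn")`.
#' @param specs character subset of `c("kinematics", "c7")`.
#' @param rf an [rf_config()]; `fnn` an [fnn_config()].
#' @param fnn an [fnn_config()].
#' @param use_true_geometry skip sensor-to-segment calibration and use the
#'   simulator's exact joint geometry.
#' @param importance compute permutation feature importance on validation
#'   rows (for the models with the `c7` spec).
#' @param seed integer seed for splitting and training.
#' @return list of class `gait_study`: the assembled `dataset`, the split,
#'   per-model fits, predictions and `evaluation_report`s, and permutation
#'   importances.
#' @export
run_gait_study <- function(config = gait_sim_config(), n_inter = 2,
                           models = c("rf", "fnn"),
                           specs = c("kinematics", "c7"),
                           rf = rf_config(), fnn = fnn_config(),
                           use_true_geometry = FALSE, importance = TRUE,
                           seed = 1) {
  sim <- simulate_gait(config)
  datasets <- list()
  for (s in sim$subjects) {
    geo_truth <- subject_joint_geometry(s$params)
    geos <- if (use_true_geometry) {
      lapply(geo_truth, function(g) c(g, list(joint = "joint")))
    } else {
      calibrate_subject(geo_truth, seed = config$seed + 131 * s$id)
    }
    for (tr in s$trials) {
      datasets[[length(datasets) + 1]] <-
        trial_cycle_dataset(tr, geos, subject = s$id)
    }
  }
  dataset <- do.call(rbind, datasets)
  class(dataset) <- c("cycle_dataset", "data.frame")

  inter <- sort(unique(dataset$subject))
  inter <- utils::tail(inter, n_inter)
  split <- split_data(dataset, inter, seed = seed)

  results <- list()
  for (spn in specs) {
    sp <- feature_spec(spn)
    ft <- build_feature_table(dataset, sp)
    scaler <- fit_scaler(ft$X[split$train, , drop = FALSE])
    Xs <- apply_scaler(scaler, ft$X)
    for (mo in models) {
      fit <- if (mo == "rf") {
        train_grf_rf(Xs[split$train, ], ft$y[split$train], rf)
      } else {
        train_grf_fnn(Xs[split$train, ], ft$y[split$train], fnn,
                      X_val = Xs[split$validation, ],
                      y_val = ft$y[split$validation])
      }
      preds <- predict(fit, Xs)
      reports <- lapply(split, function(i)
        evaluate_vgrf(dataset[i, ], preds[i]))
      imp <- NULL
      if (importance && spn == "c7")
        imp <- permutation_importance(fit, Xs[split$validation, ],
                                      ft$y[split$validation], seed = seed)
      results[[paste(mo, spn, sep = "_")]] <-
        list(model = fit, scaler = scaler, spec = sp,
             predictions = preds, reports = reports, importance = imp)
    }
  }
  structure(list(dataset = dataset, split = split, inter_subjects = inter,
                 results = results, config = config),
            class = "gait_study")
}

#' @export
print.gait_study <- function(x, ...) {
  cat(sprintf("<gait_study> %d rows, %d subjects (%d held out), models: %s\n",
              nrow(x$dataset), length(unique(x$dataset$subject)),
              length(x$inter_subjects),
              paste(names(x$results), collapse = ", ")))
  for (nm in names(x$results)) {
    rep <- x$results[[nm]]$reports$validation
    g <- rep[rep$group == "global", ]
    cat(sprintf("  %-14s validation: RMSE %.3f BW, NRMSE %.4f, rho %.4f\n",
                nm, g$rmse_mean, g$nrmse, g$rho))
  }
  invisible(x)
}
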