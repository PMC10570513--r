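# Synthetic multi-speed treadmill gait with known ground truth.
#
# A planar sagittal chain (pelvis -> thigh -> shank -> foot, hinge axes
# mediolateral) walks at a configurable cadence. Joint-angle waveforms are
# smooth periodic splines over the gait cycle, loosely shaped like normal
# hip/knee/ankle flexion/extension curves and mildly speed-scaled. Five
# sensors (hip/pelvis, thigh, shank a.k.a. "leg", foot, C7) are mounted at
# per-subject randomized poses; gyro signals are analytic, specific forces
# come from the chain geometry. The right-foot vGRF is a double-bump
# template with configurable loading-peak (LP), mid-stance (MP) and
# terminal-stance (TP) anchors, exactly zero in swing. Global frame: X
# anteroposterior, Y mediolateral (hinge axes), Z up.

# per-speed defaults for cadence and vGRF peak anchors
gait_speed_defaults <- function(speeds) {
  ref <- data.frame(
    speed      = c(1.5, 2.5, 3.5, 4.5),
    cadence    = c(35, 42, 48, 53),          # strides/min
    lp         = c(1.02, 1.06, 1.10, 1.15),  # BW
    lp_t       = c(14, 14, 13, 13),          # % cycle
    mp         = c(0.88, 0.82, 0.76, 0.70),
    mp_t       = c(30, 30, 30, 30),
    tp         = c(1.00, 1.04, 1.08, 1.12),
    tp_t       = c(46, 46, 47, 47),
    stance_end = c(64, 63, 62, 61)
  )
  out <- do.call(rbind, lapply(speeds, function(s) {
    i <- which.min(abs(ref$speed - s))
    row <- ref[i, ]
    row$speed <- s
    row
  }))
  rownames(out) <- NULL
  out
}

#' Configuration for the gait simulator
#'
#' Defaults emulate the treadmill study design the package targets: 12
#' subjects, four speeds from 1.5 to 4.5 km/h, right-foot vGRF normalized to
#' body weight, IMUs at 60 Hz and the force plate at 100 Hz.
#'
#' @param n_subjects number of simulated subjects.
#' @param speeds gait speeds in km/h.
#' @param strides_per_speed strides recorded per subject and speed.
#' @param cadence strides/min, one per speed (defaults per speed).
#' @param peak_template data frame with one row per speed and columns
#'   `lp, lp_t, mp, mp_t, tp, tp_t, stance_end` (magnitudes in BW, timings
#'   in % cycle); defaults per speed.
#' @param vertical_accel_amplitude amplitude of the C7 vertical acceleration
#'   oscillation, m/s^2.
#' @param imu_rate,grf_rate sampling rates in Hz.
#' @param gyro_noise_sd,accel_noise_sd IMU noise levels (rad/s, m/s^2).
#' @param vgrf_noise_sd force-plate noise in BW, added during stance only
#'   (swing samples stay exactly 0).
#' @param seed integer seed.
#' @return list of class `gait_sim_config`.
#' @export
gait_sim_config <- function(n_subjects = 12,
                            speeds = c(1.5, 2.5, 3.5, 4.5),
                            strides_per_speed = 20,
                            cadence = NULL,
                            peak_template = NULL,
                            vertical_accel_amplitude = 1.5,
                            imu_rate = 60, grf_rate = 100,
                            gyro_noise_sd = 0.005, accel_noise_sd = 0.05,
                            vgrf_noise_sd = 0.01, seed = 1) {
  if (length(speeds) == 0) stop("speeds must be a non-empty list")
  if (imu_rate <= 0 || grf_rate <= 0) stop("rates must be positive")
  if (strides_per_speed < 2) stop("need at least 2 strides per speed")
  def <- gait_speed_defaults(speeds)
  if (is.null(cadence)) cadence <- def$cadence
  if (length(cadence) != length(speeds))
    stop("cadence must have one entry per speed")
  if (is.null(peak_template)) peak_template <- def
  with(peak_template, {
    if (any(!(0 < lp_t & lp_t < mp_t & mp_t < tp_t & tp_t < stance_end &
                stance_end <= 100)))
      stop("peak timings must satisfy 0 < LP < MP < TP < stance_end <= 100")
    if (any(c(lp, mp, tp) < 0)) stop("peak magnitudes must be >= 0")
    if (any(mp > pmin(lp, tp)))
      stop("MP must not exceed LP or TP (mid-stance is a local minimum)")
  })
  structure(list(n_subjects = n_subjects, speeds = speeds,
                 strides_per_speed = strides_per_speed, cadence = cadence,
                 peak_template = peak_template,
                 vertical_accel_amplitude = vertical_accel_amplitude,
                 imu_rate = imu_rate, grf_rate = grf_rate,
                 gyro_noise_sd = gyro_noise_sd,
                 accel_noise_sd = accel_noise_sd,
                 vgrf_noise_sd = vgrf_noise_sd, seed = seed),
            class = "gait_sim_config")
}

#' Double-bump vGRF waveform over the gait cycle
#'
#' Monotone cubic Hermite interpolation through (0, 0), LP, MP, TP and
#' (stance_end, 0), exactly zero in swing. The peak anchors carry zero slope
#' (they are turning points), the stance boundaries carry the adjacent
#' secant slope (crisp loading/unloading), and every segment satisfies the
#' Fritsch-Carlson monotonicity condition, so the configured peaks are the
#' only stance extrema and are attained exactly at the configured timings.
#'
#' @param cycle_pct evaluation points, % of gait cycle in `[0, 100]`.
#' @param peaks list or one-row data frame with `lp, lp_t, mp, mp_t, tp,
#'   tp_t` (BW, % cycle) and `stance_end` (% cycle).
#' @return vGRF in BW at `cycle_pct`.
#' @export
vgrf_template <- function(cycle_pct, peaks) {
  if (any(cycle_pct < 0 | cycle_pct > 100))
    stop("cycle_pct must lie in [0, 100]")
  p <- as.list(peaks)
  if (!(0 < p$lp_t && p$lp_t < p$mp_t && p$mp_t < p$tp_t &&
          p$tp_t < p$stance_end && p$stance_end <= 100))
    stop("peak timings must satisfy 0 < LP < MP < TP < stance_end <= 100")
  if (min(p$lp, p$mp, p$tp) < 0) stop("peak magnitudes must be >= 0")
  kx <- c(0, p$lp_t, p$mp_t, p$tp_t, p$stance_end)
  ky <- c(0, p$lp, p$mp, p$tp, 0)
  # anchor slopes: secant at the stance boundaries, 0 at the three peaks
  km <- c((ky[2] - ky[1]) / (kx[2] - kx[1]), 0, 0, 0,
          (ky[5] - ky[4]) / (kx[5] - kx[4]))
  out <- numeric(length(cycle_pct))
  st <- which(cycle_pct <= p$stance_end)
  if (length(st)) {
    seg <- pmin(findInterval(cycle_pct[st], kx, rightmost.closed = TRUE), 4L)
    h <- kx[seg + 1] - kx[seg]
    u <- (cycle_pct[st] - kx[seg]) / h
    h00 <- (1 + 2 * u) * (1 - u)^2; h10 <- u * (1 - u)^2
    h01 <- u^2 * (3 - 2 * u);       h11 <- u^2 * (u - 1)
    out[st] <- ky[seg] * h00 + h * km[seg] * h10 +
      ky[seg + 1] * h01 + h * km[seg + 1] * h11
  }
  out
}

# periodic joint-angle templates (degrees) as functions of cycle fraction
gait_angle_templates <- function() {
  per <- function(x, y) {
    f <- stats::splinefun(x / 100, y, method = "periodic")
    f
  }
  list(
    hip = per(c(0, 15, 35, 50, 65, 80, 90, 100),
              c(30, 18, -5, -12, 5, 28, 33, 30)),
    knee = per(c(0, 12, 30, 45, 55, 65, 75, 85, 100),
               c(6, 18, 8, 5, 12, 40, 63, 35, 6)),
    ankle = per(c(0, 8, 25, 45, 55, 62, 70, 82, 100),
                c(0, -6, 4, 10, 13, -10, -16, -6, 0))
  )
}

# fixed chain geometry (m), segment frames: origin at the proximal joint
gait_chain_geometry <- function() {
  list(
    d_hip_pelvis = c(0, 0, -0.10),    # hip joint in pelvis frame
    d_knee_thigh = c(0, 0, -0.42),    # knee joint in thigh frame
    d_ankle_shank = c(0, 0, -0.42),   # ankle joint in shank frame
    sensor_pelvis = c(-0.08, 0, 0.02),
    sensor_thigh = c(0.05, 0, -0.20),
    sensor_shank = c(0.04, 0, -0.25),
    sensor_foot = c(0.08, 0, -0.05),
    c7_offset = c(0, 0, 0.55),        # C7 above the pelvis origin
    pelvis_height = 1.0
  )
}

# small random mounting rotation (per subject, per sensor)
random_mounting <- function() {
  ax <- normalize3(stats::rnorm(3))
  rot_axis_angle(ax, stats::runif(1, -0.6, 0.6))
}

#' Simulate one subject's gait trial at one speed
#'
#' @param speed km/h (used to select templates; the treadmill speed itself is
#'   implicit in cadence and waveform scaling).
#' @param n_strides number of strides.
#' @param cadence strides/min.
#' @param peaks one-row peak template (see [gait_sim_config()]).
#' @param subject per-subject parameter list as drawn by [simulate_gait()]
#'   (mounting rotations, template scaling); `NULL` draws a fresh one.
#' @param config a [gait_sim_config()] for rates and noise.
#' @param seed integer seed for this trial's noise.
#' @return list with `streams` (named list of five [imu_stream]s: hip, thigh,
#'   leg, foot, c7), `force` (list: time, vgrf in BW), and `truth`
#'   (contacts, per-joint angle series, cycle percentage, vertical
#'   acceleration, per-sample vGRF labels at IMU times, per-stride peak sets,
#'   joint geometry per joint).
#' @export
simulate_gait_trial <- function(speed, n_strides, cadence, peaks,
                                subject = NULL, config = gait_sim_config(),
                                seed = 1) {
  set.seed(seed)
  if (is.null(subject)) subject <- draw_gait_subject()
  geom <- gait_chain_geometry()
  tmpl <- gait_angle_templates()
  Tst <- 60 / cadence                        # stride period, s
  dur <- n_strides * Tst
  n <- floor(dur * config$imu_rate)
  t <- seq(0, by = 1 / config$imu_rate, length.out = n)
  ph <- (t / Tst) %% 1                       # cycle fraction, right contact at 0
  cyc <- 100 * ph

  sc <- subject$amp_scale * (1 + 0.05 * (speed - 3))
  hip <- sc * tmpl$hip(ph) + subject$hip_offset
  knee <- sc * tmpl$knee(ph) + subject$knee_offset
  ankle <- sc * tmpl$ankle(ph) + subject$ankle_offset

  # planar segment orientations about +Y (radians)
  pelv <- 0.03 * sin(4 * pi * t / Tst + 0.5)
  phi_p <- pelv
  phi_t <- phi_p - hip / DEG                 # hip flexion tilts thigh forward
  phi_s <- phi_t + knee / DEG                # knee flexion bends shank back
  phi_f <- phi_s - ankle / DEG - 0.15

  # pelvis translation: AP with a contact-locked bump, vertical at 2/stride
  w <- 2 * pi / Tst
  a_amp <- config$vertical_accel_amplitude
  z_amp <- a_amp / (2 * w)^2
  ap_amp <- 1.2                              # m/s^2 of AP acceleration wave
  x_ap <- -(ap_amp / w^2) * cos(w * t) - (0.2 * ap_amp / (2 * w)^2) * cos(2 * w * t)
  z_osc <- -z_amp * cos(2 * w * t + 0.9)
  p0 <- cbind(x_ap, 0, geom$pelvis_height + z_osc)

  roty <- function(phi, v) rotate_rows(v, c(0, 1, 0), phi)
  hipj <- p0 + roty(phi_p, geom$d_hip_pelvis)
  kneej <- hipj + roty(phi_t, geom$d_knee_thigh)
  anklej <- kneej + roty(phi_s, geom$d_ankle_shank)

  # sensor world positions and local signals
  dphi <- list(p = central_diff(phi_p, t), t = central_diff(phi_t, t),
               s = central_diff(phi_s, t), f = central_diff(phi_f, t))
  mk_stream <- function(origin, phi, phid, mount, d_sensor, quat = FALSE) {
    pos <- origin + roty(phi, d_sensor)
    acc_g <- central_diff(central_diff(pos, t), t)
    gmat <- matrix(GRAVITY, n, 3, byrow = TRUE)
    # local = M^T Rot(y,-phi) applied to global rows
    to_local <- function(v) roty(-phi, v) %*% mount
    gyro <- to_local(outer(phid, c(0, 1, 0)))
    accel <- to_local(acc_g - gmat)
    if (config$gyro_noise_sd > 0)
      gyro <- gyro + matrix(stats::rnorm(3 * n, sd = config$gyro_noise_sd), n, 3)
    if (config$accel_noise_sd > 0)
      accel <- accel + matrix(stats::rnorm(3 * n, sd = config$accel_noise_sd), n, 3)
    q <- NULL
    if (quat) {
      qy <- cbind(cos(phi / 2), 0, sin(phi / 2), 0)
      q <- quat_multiply(qy, rotmat_to_quat(mount))
    }
    imu_stream(t, gyro, accel, quat = q, rate = config$imu_rate)
  }

  streams <- list(
    hip = mk_stream(p0, phi_p, dphi$p, subject$mount$pelvis,
                    geom$sensor_pelvis, quat = TRUE),
    thigh = mk_stream(hipj, phi_t, dphi$t, subject$mount$thigh,
                      geom$sensor_thigh),
    leg = mk_stream(kneej, phi_s, dphi$s, subject$mount$shank,
                    geom$sensor_shank),
    foot = mk_stream(anklej, phi_f, dphi$f, subject$mount$foot,
                     geom$sensor_foot),
    c7 = mk_stream(p0 + matrix(geom$c7_offset, n, 3, byrow = TRUE),
                   0.3 * phi_p, 0.3 * dphi$p, subject$mount$c7,
                   c(0, 0, 0), quat = TRUE)
  )

  # force plate: template over the cycle, stance-only noise, swing exactly 0
  ng <- floor(dur * config$grf_rate)
  tg <- seq(0, by = 1 / config$grf_rate, length.out = ng)
  cycg <- 100 * ((tg / Tst) %% 1)
  vgrf <- vgrf_template(cycg, peaks)
  if (config$vgrf_noise_sd > 0) {
    st <- vgrf > 0
    vgrf[st] <- pmax(0, vgrf[st] + stats::rnorm(sum(st),
                                                sd = config$vgrf_noise_sd))
  }

  contacts <- Tst * seq(0, n_strides - 1)
  truth <- list(
    contacts = contacts,
    stride_period = Tst,
    cycle_pct = cyc,
    angles = list(hip = hip, knee = knee, ankle = ankle),
    a_vert = central_diff(central_diff(p0[, 3], t), t),
    vgrf_at_imu = vgrf_template(cyc, peaks),
    peaks = peaks,
    geometry = subject_joint_geometry(subject, geom)
  )
  list(streams = streams, force = list(time = tg, vgrf = vgrf),
       truth = truth, speed = speed, time = t)
}

# draw per-subject mounting rotations and template variability
draw_gait_subject <- function() {
  list(mount = list(pelvis = random_mounting(), thigh = random_mounting(),
                    shank = random_mounting(), foot = random_mounting(),
                    c7 = random_mounting()),
       amp_scale = 1 + stats::rnorm(1, sd = 0.04),
       hip_offset = stats::rnorm(1, sd = 1.5),
       knee_offset = stats::rnorm(1, sd = 1.5),
       ankle_offset = stats::rnorm(1, sd = 1.0))
}

# exact joint geometry (axes + centre offsets) implied by a subject's mounts
subject_joint_geometry <- function(subject, geom = gait_chain_geometry()) {
  ey <- c(0, 1, 0)
  loc <- function(M, v) drop(t(M) %*% v)
  list(
    hip = list(j1 = loc(subject$mount$pelvis, ey),
               j2 = loc(subject$mount$thigh, ey),
               o1 = loc(subject$mount$pelvis,
                        geom$sensor_pelvis - geom$d_hip_pelvis),
               o2 = loc(subject$mount$thigh, geom$sensor_thigh)),
    knee = list(j1 = loc(subject$mount$thigh, ey),
                j2 = loc(subject$mount$shank, ey),
                o1 = loc(subject$mount$thigh,
                         geom$sensor_thigh - geom$d_knee_thigh),
                o2 = loc(subject$mount$shank, geom$sensor_shank)),
    ankle = list(j1 = loc(subject$mount$shank, ey),
                 j2 = loc(subject$mount$foot, ey),
                 o1 = loc(subject$mount$shank,
                          geom$sensor_shank - geom$d_ankle_shank),
                 o2 = loc(subject$mount$foot, geom$sensor_foot))
  )
}

#' Simulate a full multi-subject, multi-speed gait study
#'
#' @param config a [gait_sim_config()].
#' @return list of class `gait_sim` with `subjects`: per subject a list with
#'   the drawn `params` and `trials` (one [simulate_gait_trial()] result per
#'   speed), plus the `config`.
#' @export
simulate_gait <- function(config = gait_sim_config()) {
  stopifnot(inherits(config, "gait_sim_config"))
  set.seed(config$seed)
  subj_seeds <- sample.int(.Machine$integer.max / 2, config$n_subjects)
  subjects <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    set.seed(subj_seeds[i])
    params <- draw_gait_subject()
    trials <- vector("list", length(config$speeds))
    for (k in seq_along(config$speeds)) {
      trials[[k]] <- simulate_gait_trial(
        speed = config$speeds[k], n_strides = config$strides_per_speed,
        cadence = config$cadence[k], peaks = config$peak_template[k, ],
        subject = params, config = config,
        seed = subj_seeds[i] + 7919 * k)
    }
    names(trials) <- paste0("speed_", config$speeds)
    subjects[[i]] <- list(id = i, params = params, trials = trials)
  }
  structure(list(subjects = subjects, config = config), class = "gait_sim")
}
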