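# Foot-contact detection, stride segmentation, cycle-domain normalization
# and IMU/force synchronization.

#' Detect foot contacts from hip anteroposterior acceleration
#'
#' The hip acceleration is low-pass filtered at 2 Hz (zero-phase) and local
#' maxima of the filtered signal are taken as foot contacts, subject to a
#' minimum peak separation (a fraction of the median inter-peak interval).
#'
#' @param accel_ap anteroposterior hip acceleration, m/s^2.
#' @param rate sampling rate, Hz.
#' @param cutoff low-pass cutoff, Hz.
#' @param min_sep_factor minimum separation between accepted maxima as a
#'   fraction of the median raw inter-peak interval.
#' @param every_second keep every second maximum starting from the first
#'   (left/right alternation on real data, where both feet produce maxima;
#'   the simulator produces right-contact maxima only, so the default is
#'   `FALSE`).
#' @return list of class `contact_list`: `times` (s), `indices`, `source`.
#' @export
detect_contacts_imu <- function(accel_ap, rate, cutoff = 2,
                                min_sep_factor = 0.4, every_second = FALSE) {
  if (length(accel_ap) < 3 * rate)
    stop("need at least 3 s of data for contact detection")
  if (stats::sd(accel_ap) < 1e-9) {
    warning("no contact maxima found (constant signal)")
    return(structure(list(times = numeric(0), indices = integer(0),
                          source = "imu"), class = "contact_list"))
  }
  f <- lowpass_zero_phase(accel_ap, rate, cutoff)
  raw <- find_local_maxima(f)
  # contacts are the prominent positive peaks; reject filter ripple
  raw <- raw[f[raw] > mean(f) + 0.2 * stats::sd(f)]
  if (length(raw) == 0) {
    warning("no contact maxima found")
    return(structure(list(times = numeric(0), indices = integer(0),
                          source = "imu"), class = "contact_list"))
  }
  min_sep <- if (length(raw) > 1)
    max(1L, floor(min_sep_factor * stats::median(diff(raw)))) else 1L
  idx <- find_local_maxima(f, min_sep = min_sep)
  idx <- idx[f[idx] > mean(f) + 0.2 * stats::sd(f)]
  # drop maxima close to the record edges (zero-phase filter transients)
  if (length(raw) > 1) {
    gap <- stats::median(diff(raw))
    idx <- idx[idx > gap / 4 & idx < length(f) - gap / 4]
  }
  if (every_second && length(idx) > 1) idx <- idx[seq(1, length(idx), by = 2)]
  structure(list(times = (idx - 1) / rate, indices = idx, source = "imu"),
            class = "contact_list")
}

#' Detect foot contacts (and toe-offs) from the vGRF signal
#'
#' A contact is a rising crossing of the threshold sustained for at least
#' `sustain` samples; the following falling crossing is the toe-off.
#'
#' @param force vGRF series in BW (non-negative).
#' @param time timestamps, s (defaults to a unit-rate index).
#' @param threshold onset threshold in BW.
#' @param sustain number of consecutive supra-threshold samples required.
#' @return list of class `contact_list` with `times`, `indices`,
#'   `toeoff_times`, `toeoff_indices`, `source = "grf"`.
#' @export
detect_contacts_grf <- function(force, time = NULL, threshold = 0.03,
                                sustain = 3) {
  if (any(force < 0)) stop("vGRF must be non-negative")
  if (is.null(time)) time <- seq_along(force) - 1
  up <- force >= threshold
  n <- length(force)
  onsets <- integer(0); offs <- integer(0)
  k <- 1
  while (k <= n) {
    if (up[k] && (k == 1 || !up[k - 1])) {
      run_end <- k
      while (run_end < n && up[run_end + 1]) run_end <- run_end + 1
      if (run_end - k + 1 >= sustain) {
        onsets <- c(onsets, k)
        if (run_end < n) offs <- c(offs, run_end + 1L)
      }
      k <- run_end + 1
    } else k <- k + 1
  }
  structure(list(times = time[onsets], indices = onsets,
                 toeoff_times = time[offs], toeoff_indices = offs,
                 source = "grf"),
            class = "contact_list")
}

#' @export
print.contact_list <- function(x, ...) {
  cat(sprintf("<contact_list> %d contacts (%s)\n", length(x$times), x$source))
  invisible(x)
}

#' Segment a signal into strides and normalize to the gait-cycle domain
#'
#' Each inter-contact interval is mapped to a fixed percentage grid
#' (0..100%) by linear interpolation. Strides whose duration falls outside
#' the validation bounds are dropped (and counted).
#'
#' @param time timestamps of `x`, s.
#' @param x signal values.
#' @param contact_times stride onsets, s (strictly increasing).
#' @param grid_length number of grid points (101 gives 0, 1, ..., 100%).
#' @param bounds admissible stride duration, s.
#' @return list with `cycles` (strides x grid matrix), `grid` (% cycle),
#'   `stride_start` (s), `n_dropped`.
#' @export
segment_and_normalize <- function(time, x, contact_times, grid_length = 101,
                                  bounds = c(0.5, 3)) {
  if (length(contact_times) < 2)
    return(list(cycles = matrix(numeric(0), 0, grid_length),
                grid = seq(0, 100, length.out = grid_length),
                stride_start = numeric(0), n_dropped = 0L))
  if (any(diff(contact_times) <= 0))
    stop("contact times must be strictly increasing")
  grid <- seq(0, 100, length.out = grid_length)
  keep <- list(); starts <- numeric(0); dropped <- 0L
  for (k in seq_len(length(contact_times) - 1)) {
    t0 <- contact_times[k]; t1 <- contact_times[k + 1]
    if (t1 - t0 < bounds[1] || t1 - t0 > bounds[2]) { dropped <- dropped + 1L; next }
    tt <- t0 + (grid / 100) * (t1 - t0)
    keep[[length(keep) + 1]] <- stats::approx(time, x, xout = tt, rule = 2)$y
    starts <- c(starts, t0)
  }
  list(cycles = if (length(keep)) do.call(rbind, keep)
       else matrix(numeric(0), 0, grid_length),
       grid = grid, stride_start = starts, n_dropped = dropped)
}

#' Assemble a cycle-domain dataset joining IMU features with vGRF labels
#'
#' Both modalities are segmented from their own first detected contact and
#' matched stride by stride; every row of the result is one grid point of
#' one stride, carrying the six kinematic features, the C7 vertical
#' acceleration, the cycle percentage and the vGRF label.
#'
#' @param imu_cycles named list of stride x grid matrices (from
#'   [segment_and_normalize()]), e.g. `hip_angle`, `knee_angle`, ...,
#'   `a_vert`; all must have the same number of strides and grid.
#' @param grf_cycles a stride x grid matrix of vGRF in BW.
#' @param grid the percentage grid.
#' @param subject,speed metadata recycled onto every row.
#' @return data frame of class `cycle_dataset`.
#' @export
synchronize_cycles <- function(imu_cycles, grf_cycles, grid,
                               subject = 1L, speed = NA_real_) {
  ns_imu <- unique(vapply(imu_cycles, nrow, 1L))
  if (length(imu_cycles) == 0) ns_imu <- 0L
  if (length(ns_imu) != 1)
    stop("all IMU cycle matrices must have the same number of strides")
  ns <- min(ns_imu, nrow(grf_cycles))
  if (ns_imu == 0 || nrow(grf_cycles) == 0) ns <- 0L
  if (abs(ns_imu - nrow(grf_cycles)) > 1 && ns > 0)
    stop(sprintf("stride-count mismatch between modalities: %d IMU vs %d GRF",
                 ns_imu, nrow(grf_cycles)))
  if (ns == 0) {
    out <- data.frame(subject = integer(0), speed = numeric(0),
                      stride = integer(0), cycle_pct = numeric(0))
    for (nm in names(imu_cycles)) out[[nm]] <- numeric(0)
    out$vgrf <- numeric(0)
    class(out) <- c("cycle_dataset", "data.frame")
    return(out)
  }
  g <- length(grid)
  out <- data.frame(
    subject = rep(subject, ns * g),
    speed = rep(speed, ns * g),
    stride = rep(seq_len(ns), each = g),
    cycle_pct = rep(grid, ns))
  for (nm in names(imu_cycles))
    out[[nm]] <- as.vector(t(imu_cycles[[nm]][seq_len(ns), , drop = FALSE]))
  out$vgrf <- as.vector(t(grf_cycles[seq_len(ns), , drop = FALSE]))
  class(out) <- c("cycle_dataset", "data.frame")
  out
}
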