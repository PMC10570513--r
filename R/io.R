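# Plain-text readers and writers: CSV for time series, JSON for structured
# results. Column names carry units as suffixes.

#' Write / read an IMU stream as CSV
#'
#' Columns: `time_s, gx, gy, gz` (rad/s), `ax, ay, az` (m/s^2) and, when an
#' orientation channel exists, `qw, qx, qy, qz`.
#'
#' @param stream an [imu_stream].
#' @param path file path.
#' @export
write_imu_csv <- function(stream, path) {
  df <- data.frame(time_s = stream$time,
                   gx = stream$gyro[, 1], gy = stream$gyro[, 2],
                   gz = stream$gyro[, 3],
                   ax = stream$accel[, 1], ay = stream$accel[, 2],
                   az = stream$accel[, 3])
  if (!is.null(stream$quat)) {
    df$qw <- stream$quat[, 1]; df$qx <- stream$quat[, 2]
    df$qy <- stream$quat[, 3]; df$qz <- stream$quat[, 4]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_imu_csv
#' @return `read_imu_csv` returns an [imu_stream]; orientation is attached
#'   when quaternion columns are present.
#' @export
read_imu_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "gx", "gy", "gz", "ax", "ay", "az")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing columns in ", path, ": ", paste(missing, collapse = ", "))
  bad <- which(!stats::complete.cases(df[, need]))
  if (length(bad))
    stop("NaN/NA rows in ", path, ": rows ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (any(diff(df$time_s) <= 0))
    stop("time_s must be strictly increasing in ", path)
  quat <- NULL
  if (all(c("qw", "qx", "qy", "qz") %in% names(df)))
    quat <- as.matrix(df[, c("qw", "qx", "qy", "qz")])
  imu_stream(df$time_s, as.matrix(df[, c("gx", "gy", "gz")]),
             as.matrix(df[, c("ax", "ay", "az")]), quat = quat)
}

#' Write / read a force series as CSV (`time_s, vgrf_bw`)
#' @param time timestamps, s; `vgrf` force in BW.
#' @param vgrf numeric vector, BW.
#' @param path file path.
#' @export
write_force_csv <- function(time, vgrf, path) {
  utils::write.csv(data.frame(time_s = time, vgrf_bw = vgrf), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_force_csv
#' @export
read_force_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "vgrf_bw") %in% names(df)))
    stop("force CSV needs columns time_s, vgrf_bw")
  list(time = df$time_s, vgrf = df$vgrf_bw)
}

#' Write / read joint geometry as JSON
#' @param geometry a `joint_geometry` (see [calibrate_joint()]).
#' @param path file path.
#' @export
write_geometry_json <- function(geometry, path) {
  jsonlite::write_json(unclass(geometry), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(g, class = "joint_geometry")
}

#' Write / read a cycle dataset as CSV
#' @param dataset a `cycle_dataset` data frame.
#' @param path file path.
#' @export
write_cycle_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cycle_dataset
#' @export
read_cycle_dataset <- function(path) {
  df <- utils::read.csv(path)
  class(df) <- c("cycle_dataset", "data.frame")
  df
}
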