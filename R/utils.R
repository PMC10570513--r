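# Small numerical helpers shared across modules. All angle math is done in
# radians internally; user-facing angles are degrees.

DEG <- 180 / pi
GRAVITY <- c(0, 0, -9.81)  # global frame, Z up; accelerometers report specific force

#' Cross product of 3-vectors, row-wise
#'
#' @param a,b numeric 3-vectors or N x 3 matrices (recycled against each other).
#' @return N x 3 matrix (or 3-vector if both inputs are vectors).
#' @keywords internal
cross3 <- function(a, b) {
  av <- is.null(dim(a)); bv <- is.null(dim(b))
  if (av && bv) {
    return(c(a[2] * b[3] - a[3] * b[2],
             a[3] * b[1] - a[1] * b[3],
             a[1] * b[2] - a[2] * b[1]))
  }
  if (av) a <- matrix(a, nrow(b), 3, byrow = TRUE)
  if (bv) b <- matrix(b, nrow(a), 3, byrow = TRUE)
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norms <- function(m) sqrt(rowSums(m * m))

normalize3 <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

#' Rotation matrix from axis-angle (Rodrigues)
#' @keywords internal
rot_axis_angle <- function(axis, angle) {
  k <- normalize3(axis)
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Rotate rows of an N x 3 matrix about a fixed axis by per-row angles
#' @keywords internal
rotate_rows <- function(v, axis, angles) {
  k <- normalize3(axis)
  if (is.null(dim(v))) v <- matrix(v, length(angles), 3, byrow = TRUE)
  ca <- cos(angles); sa <- sin(angles)
  kv <- cross3(k, v)
  kdv <- drop(v %*% k)
  v * ca + kv * sa + outer(kdv * (1 - ca), k)
}

#' Rotation aligning unit vector `from` onto unit vector `to`
#' @keywords internal
align_rotation <- function(from, to) {
  f <- normalize3(from); t2 <- normalize3(to)
  axis <- cross3(f, t2)
  s <- sqrt(sum(axis^2)); cth <- sum(f * t2)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to f
    ref <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(rot_axis_angle(cross3(f, ref), pi))
  }
  rot_axis_angle(axis, atan2(s, cth))
}

#' Quaternion (w,x,y,z) rows to rotation matrices applied to local vectors
#'
#' Returns the rows of `v` rotated from the sensor-local frame to the global
#' frame, one quaternion per row.
#' @keywords internal
quat_rotate_rows <- function(q, v) {
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  u <- cbind(x, y, z)
  uv <- cross3(u, v)
  uuv <- cross3(u, uv)
  v + 2 * (w * uv + uuv)
}

#' Rotation matrix to quaternion (w,x,y,z)
#' @keywords internal
rotmat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
             (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
             (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q / sqrt(sum(q^2))
}

#' Quaternion product, row-wise (w,x,y,z); `a` N x 4, `b` 4-vector or N x 4
#' @keywords internal
quat_multiply <- function(a, b) {
  if (is.null(dim(b))) b <- matrix(b, nrow(a), 4, byrow = TRUE)
  cbind(a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
        a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
        a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
        a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1])
}

#' Cumulative trapezoidal integral
#' @keywords internal
cumtrapz1 <- function(t, y) {
  n <- length(y)
  c(0, cumsum(diff(t) * (y[-1] + y[-n]) / 2))
}

#' Central-difference derivative (one-sided at the endpoints)
#'
#' Works on vectors or column-wise on matrices; `t` must be ~uniform.
#' @keywords internal
central_diff <- function(y, t) {
  vec <- is.null(dim(y))
  if (vec) y <- matrix(y, ncol = 1)
  n <- nrow(y)
  if (n < 3) stop("need at least 3 samples to differentiate")
  d <- y
  d[1, ] <- (y[2, ] - y[1, ]) / (t[2] - t[1])
  d[n, ] <- (y[n, ] - y[n - 1, ]) / (t[n] - t[n - 1])
  d[2:(n - 1), ] <- (y[3:n, ] - y[1:(n - 2), ]) / (t[3:n] - t[1:(n - 2)])
  if (vec) drop(d) else d
}

#' Zero-phase low-pass filter (2nd-order Butterworth, forward-backward)
#'
#' @param x numeric vector.
#' @param rate sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz.
#' @keywords internal
lowpass_zero_phase <- function(x, rate, cutoff) {
  if (length(x) < 12) stop("series too short for zero-phase filtering")
  bf <- signal::butter(2, cutoff / (rate / 2), type = "low")
  # mean-centre to tame filtfilt edge transients (DC passes unchanged)
  m <- mean(x)
  m + as.numeric(signal::filtfilt(bf, x - m))
}

#' Unwrap a phase series (radians) so jumps never exceed pi
#' @keywords internal
unwrap_rad <- function(x) {
  dx <- diff(x)
  adj <- cumsum(c(0, -2 * pi * round(dx / (2 * pi))))
  x + adj
}

#' Signed angle about `axis` from the projection of `a` to the projection of `b`
#' @keywords internal
signed_angle_about <- function(a, b, axis) {
  n <- normalize3(axis)
  pa <- a - sum(a * n) * n
  pb <- b - sum(b * n) * n
  atan2(sum(cross3(pa, pb) * n), sum(pa * pb))
}

#' Local maxima of a vector with a minimum separation constraint
#'
#' Strict local maxima are found first; peaks closer than `min_sep` samples to
#' a larger accepted peak are discarded (greedy, by decreasing height).
#' @keywords internal
find_local_maxima <- function(x, min_sep = 1L) {
  n <- length(x)
  if (n < 3) return(integer(0))
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(idx) == 0 || min_sep <= 1) return(idx)
  ord <- idx[order(x[idx], decreasing = TRUE)]
  keep <- integer(0)
  for (i in ord) {
    if (all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
  }
  sort(keep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
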