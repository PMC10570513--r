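# Accuracy metrics for vGRF reconstruction: per-stride RMSE, range-normalized
# RMSE, Pearson correlation, and the magnitude/timing errors of the three
# characteristic walking vGRF peaks (loading peak LP, mid-stance minimum MP,
# terminal-stance peak TP).

#' Root-mean-square error
#' @param measured,estimated numeric vectors of equal length.
#' @return RMSE in the units of the inputs.
#' @export
rmse <- function(measured, estimated) {
  if (length(measured) != length(estimated)) stop("length mismatch")
  sqrt(mean((measured - estimated)^2))
}

#' Per-stride RMSE
#'
#' @param measured,estimated vGRF series (BW) on a common grid.
#' @param stride stride index per sample.
#' @return named numeric vector: RMSE per stride, BW.
#' @export
rmse_per_stride <- function(measured, estimated, stride) {
  if (length(measured) != length(estimated) ||
      length(measured) != length(stride)) stop("length mismatch")
  vapply(split(seq_along(stride), stride),
         function(i) rmse(measured[i], estimated[i]), numeric(1))
}

#' Range-normalized RMSE
#'
#' RMSE divided by the range (max minus min) of the *measured* signal.
#'
#' @param measured,estimated vGRF series (BW).
#' @return dimensionless NRMSE.
#' @export
nrmse <- function(measured, estimated) {
  rng <- max(measured) - min(measured)
  if (rng <= 0) stop("measured series is constant; NRMSE undefined")
  rmse(measured, estimated) / rng
}

#' Pearson correlation between measured and estimated series
#' @param measured,estimated numeric vectors.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(measured, estimated) {
  if (stats::sd(measured) == 0 || stats::sd(estimated) == 0)
    stop("zero-variance series; correlation undefined")
  stats::cor(measured, estimated)
}

#' Detect the characteristic peaks of one stride's vGRF waveform
#'
#' LP is the maximum over the first half of stance, TP the maximum over the
#' second half, and MP the minimum strictly between them.
#'
#' @param vgrf one stride's vGRF on the cycle grid, BW.
#' @param grid cycle percentages of the samples.
#' @param stance_end end of stance, % cycle (from toe-off detection).
#' @return object of class `peak_set`: magnitudes `lp, mp, tp` (BW) and
#'   timings `lp_t, mp_t, tp_t` (% cycle).
#' @export
detect_vgrf_peaks <- function(vgrf, grid = seq(0, 100, length.out = length(vgrf)),
                              stance_end = 60) {
  st <- which(grid <= stance_end & grid >= 0)
  if (length(st) < 5) stop("stance too short for peak detection")
  half <- st[which.min(abs(grid[st] - stance_end / 2))]
  first <- st[st <= half]; second <- st[st > half]
  i_lp <- first[which.max(vgrf[first])]
  i_tp <- second[which.max(vgrf[second])]
  if (i_tp - i_lp < 2)
    stop("no interior mid-stance minimum: stance is monotone between ",
         "the detected maxima")
  mid <- (i_lp + 1):(i_tp - 1)
  i_mp <- mid[which.min(vgrf[mid])]
  if (vgrf[i_mp] >= min(vgrf[i_lp], vgrf[i_tp]))
    stop("no interior mid-stance minimum: stance waveform has no double bump")
  structure(list(lp = vgrf[i_lp], mp = vgrf[i_mp], tp = vgrf[i_tp],
                 lp_t = grid[i_lp], mp_t = grid[i_mp], tp_t = grid[i_tp]),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> LP %.3f BW @ %.1f%%, MP %.3f @ %.1f%%, TP %.3f @ %.1f%%\n",
              x$lp, x$lp_t, x$mp, x$mp_t, x$tp, x$tp_t))
  invisible(x)
}

#' Magnitude errors and timing delays between two peak sets
#'
#' Magnitude errors are absolute (BW). Delays are signed
#' (estimated minus measured, % cycle): positive means the estimated peak
#' occurs later than the measured one.
#'
#' @param measured,estimated `peak_set` objects.
#' @return list with `magnitude` (named: lp, mp, tp; BW) and `delay`
#'   (named; % cycle).
#' @export
peak_errors <- function(measured, estimated) {
  mag <- c(lp = abs(estimated$lp - measured$lp),
           mp = abs(estimated$mp - measured$mp),
           tp = abs(estimated$tp - measured$tp))
  del <- c(lp = estimated$lp_t - measured$lp_t,
           mp = estimated$mp_t - measured$mp_t,
           tp = estimated$tp_t - measured$tp_t)
  list(magnitude = mag, delay = del)
}

#' Evaluate estimated vGRF against measurements on a cycle dataset
#'
#' Computes per-stride RMSE (mean and sd), NRMSE, Pearson correlation, and
#' per-peak magnitude errors and delays, grouped by gait speed.
#'
#' @param dataset a `cycle_dataset` holding the measured `vgrf`.
#' @param estimated vector of model predictions aligned with `dataset` rows.
#' @param stance_end stance end used for peak detection, % cycle; a single
#'   value or one per speed (named by speed).
#' @return data frame of class `evaluation_report`, one row per speed plus a
#'   `"global"` row.
#' @export
evaluate_vgrf <- function(dataset, estimated, stance_end = 62) {
  stopifnot(nrow(dataset) == length(estimated))
  groups <- c(split(seq_len(nrow(dataset)), dataset$speed),
              list(global = seq_len(nrow(dataset))))
  rows <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    d <- dataset[i, ]; e <- estimated[i]
    se <- if (length(stance_end) > 1) stance_end[[g]] %||% stance_end[[1]]
          else stance_end
    key <- interaction(d$subject, d$speed, d$stride, drop = TRUE)
    per_stride <- rmse_per_stride(d$vgrf, e, key)
    pk <- lapply(levels(key), function(k) {
      j <- which(key == k)
      o <- order(d$cycle_pct[j]); j <- j[o]
      m <- try(detect_vgrf_peaks(d$vgrf[j], d$cycle_pct[j], se), silent = TRUE)
      s <- try(detect_vgrf_peaks(e[j], d$cycle_pct[j], se), silent = TRUE)
      if (inherits(m, "try-error") || inherits(s, "try-error")) return(NULL)
      peak_errors(m, s)
    })
    pk <- pk[!vapply(pk, is.null, TRUE)]
    mag <- if (length(pk)) rowMeans(sapply(pk, `[[`, "magnitude")) else rep(NA_real_, 3)
    del <- if (length(pk)) rowMeans(sapply(pk, `[[`, "delay")) else rep(NA_real_, 3)
    data.frame(group = g, n_strides = length(per_stride),
               rmse_mean = mean(per_stride), rmse_sd = stats::sd(per_stride),
               nrmse = nrmse(d$vgrf, e),
               rho = pearson_correlation(d$vgrf, e),
               lp_mag_err = mag[1], mp_mag_err = mag[2], tp_mag_err = mag[3],
               lp_delay = del[1], mp_delay = del[2], tp_delay = del[3])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("evaluation_report", "data.frame")
  out
}
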