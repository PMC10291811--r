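# From raw device streams to CoP trajectories.

#' CoP trajectory from a force-platform stream
#'
#' Applies the standard plate relation at the plate surface,
#' `x = -My / Fz`, `y = Mx / Fz` (moments in N cm, forces in N), one CoP
#' point per force sample. Samples with `Fz <= fz_threshold` are excluded
#' (and counted in the `n_excluded` attribute) to guard against division
#' blow-ups at vanishing load.
#'
#' @param stream A force stream tibble (from [read_force_csv()] or
#'   [render_force_plate()]), or a `trial_recording`.
#' @param fz_threshold Minimum vertical force, N (default 1).
#' @return A `cop_trajectory`; attribute `n_excluded` counts dropped samples.
#' @export
#' @examples
#' s <- tibble::tibble(time = 0, fx = 0, fy = 0, fz = 10, mx = 2, my = -3, mz = 0)
#' cop_from_forceplate(s, fz_threshold = 0.5)  # (0.3, 0.2)
cop_from_forceplate <- function(stream, fz_threshold = 1) {
  if (inherits(stream, "trial_recording")) stream <- stream$force
  stopifnot(all(c("time", "fz", "mx", "my") %in% names(stream)))
  keep <- stream$fz > fz_threshold
  n_excluded <- sum(!keep)
  if (!any(keep)) {
    stop("empty trajectory: no sample exceeds the Fz threshold", call. = FALSE)
  }
  s <- stream[keep, ]
  out <- new_cop_trajectory(time = s$time,
                            x_ap = -s$my / s$fz,
                            y_ml = s$mx / s$fz,
                            rate = attr(stream, "rate"),
                            device = "force_plate")
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Calibrate a pressure-mat stream against a known mass
#'
#' Derives the multiplicative calibration factor from a static stand of a
#' known mass: `scale = known_mass * g / mean(total raw load per frame)`,
#' and applies it to every frame, converting raw counts to Newtons.
#' Re-deriving the factor from an already calibrated stream of the same mass
#' gives 1 (idempotence).
#'
#' @param stream A `pressure_stream`.
#' @param known_mass Calibration mass, kg (> 0); e.g. a 50 kg researcher.
#' @return The calibrated `pressure_stream` (unit N, `calibration_scale`
#'   updated with the applied factor).
#' @export
calibrate_pressure <- function(stream, known_mass) {
  stopifnot(inherits(stream, "pressure_stream"))
  if (!is.finite(known_mass) || known_mass <= 0) {
    stop("known_mass must be a positive mass in kg", call. = FALSE)
  }
  totals <- apply(stream$frames, 3, sum)
  m <- mean(totals)
  if (m <= 0) stop("calibration error: zero mean total load", call. = FALSE)
  scale <- known_mass * GRAVITY / m
  stream$frames <- stream$frames * scale
  stream$calibration_scale <- scale
  stream$unit <- "N"
  stream
}

#' CoP trajectory from a pressure-mat stream
#'
#' The CoP of each frame is the load-weighted mean of the sensel centre
#' positions. Frames whose total load falls below
#' `load_threshold * median(total load)` are dropped and counted; the
#' centroid is invariant to the calibration scale, so raw or calibrated
#' streams give identical trajectories.
#'
#' @param stream A `pressure_stream`, or a `trial_recording`.
#' @param load_threshold Fraction of the trial-median total load below which
#'   a frame is discarded (default 0.1).
#' @return A `cop_trajectory`; attribute `n_excluded` counts dropped frames.
#' @export
cop_from_pressure <- function(stream, load_threshold = 0.1) {
  if (inherits(stream, "trial_recording")) stream <- stream$pressure
  stopifnot(inherits(stream, "pressure_stream"))
  d <- dim(stream$frames)
  flat <- matrix(stream$frames, d[1] * d[2], d[3])
  totals <- colSums(flat)
  keep <- totals > load_threshold * stats::median(totals) & totals > 0
  if (!any(keep)) {
    stop("empty trajectory: no frame carries sufficient load", call. = FALSE)
  }
  g <- mat_grid(stream$spec)
  xg <- rep(g$x, each = d[1])   # AP coordinate of each sensel (column-major)
  yg <- rep(g$y, times = d[2])  # ML coordinate
  out <- new_cop_trajectory(
    time = stream$time[keep],
    x_ap = colSums(flat[, keep, drop = FALSE] * xg) / totals[keep],
    y_ml = colSums(flat[, keep, drop = FALSE] * yg) / totals[keep],
    rate = stream$spec$rate,
    device = "pressure_mat")
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Resample a CoP trajectory to a new rate
#'
#' Linear interpolation at times `t0 + k / target_rate` within the original
#' time span; every resampled vertex lies on the original polyline, so
#' resampling can never lengthen the sway path.
#'
#' @param traj A `cop_trajectory` with at least 2 samples.
#' @param target_rate Target sampling rate, Hz (> 0).
#' @return A `cop_trajectory` at the target rate.
#' @export
resample_trajectory <- function(traj, target_rate) {
  validate_trajectory(traj, min_samples = 2L)
  if (!is.finite(target_rate) || target_rate <= 0) {
    stop("target_rate must be > 0", call. = FALSE)
  }
  t0 <- traj$time[1]; t1 <- traj$time[nrow(traj)]
  tt <- seq(t0, t1, by = 1 / target_rate)
  out <- new_cop_trajectory(
    time = tt,
    x_ap = stats::approx(traj$time, traj$x_ap, xout = tt)$y,
    y_ml = stats::approx(traj$time, traj$y_ml, xout = tt)$y,
    rate = target_rate,
    device = attr(traj, "device") %||% "unknown",
    trial_id = attr(traj, "trial_id"))
  attr(out, "resampled_from") <- attr(traj, "rate")
  out
}
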