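# Rendering ground-truth CoP dynamics as raw device streams.

GRAVITY <- 9.81  # m/s^2

#' Render a force-platform stream from a ground-truth CoP path
#'
#' Produces the raw 100 Hz plate stream (`time, fx, fy, fz, mx, my, mz`;
#' forces in N, moments in N cm about the plate origin). The vertical force
#' is `body_weight * g` plus zero-mean noise, and the moments follow the
#' plate convention used by [cop_from_forceplate()],
#' `x = -My / Fz`, `y = Mx / Fz`, so that noise-free rendering round-trips
#' the input path exactly. Measurement noise is expressed as CoP-equivalent
#' white noise of sd `spec$cop_noise_sd` (cm) added to the CoP before the
#' moments are formed; channel noise on the force components scales with it.
#'
#' @param cop_path A `cop_trajectory` (ground truth, at the plate rate).
#' @param geometry A [stance_geometry()] supplying the body weight.
#' @param spec A [device_spec()] with `kind = "force_plate"`.
#' @param seed Optional integer seed for the noise draws.
#' @return A tibble with the seven plate channels; attributes `rate`,
#'   `device`.
#' @export
render_force_plate <- function(cop_path, geometry = stance_geometry(),
                               spec = device_spec("force_plate"), seed = NULL) {
  stopifnot(inherits(spec, "device_spec"))
  if (spec$kind != "force_plate") stop("spec$kind must be 'force_plate'", call. = FALSE)
  validate_trajectory(cop_path)
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  n <- nrow(cop_path)
  w_n <- geometry$body_weight * GRAVITY
  nsd <- spec$cop_noise_sd
  # channel noise tied to the CoP noise scale; zero noise => exact stream
  fz <- w_n + stats::rnorm(n, 0, 4 * nsd)
  x_meas <- cop_path$x_ap + stats::rnorm(n, 0, nsd)
  y_meas <- cop_path$y_ml + stats::rnorm(n, 0, nsd)
  out <- tibble::tibble(
    time = cop_path$time,
    fx = stats::rnorm(n, 0, 4 * nsd),
    fy = stats::rnorm(n, 0, 4 * nsd),
    fz = fz,
    mx = y_meas * fz,
    my = -x_meas * fz,
    mz = stats::rnorm(n, 0, 4 * nsd)
  )
  attr(out, "rate") <- attr(cop_path, "rate")
  attr(out, "device") <- "force_plate"
  out
}

# Sensel-centre coordinate grids for a pressure mat spec.
# Columns index AP (x), rows index ML (y); grid centred on the origin.
mat_grid <- function(spec) {
  nr <- spec$grid_dim[1]; nc <- spec$grid_dim[2]; p <- spec$sensel_pitch
  xc <- (seq_len(nc) - (nc + 1) / 2) * p   # AP coordinate per column
  yc <- ((nr + 1) / 2 - seq_len(nr)) * p   # ML coordinate per row (top = left+)
  list(x = xc, y = yc, nr = nr, nc = nc,
       area = p^2)
}

#' Render a pressure-mat frame stream from a ground-truth CoP path
#'
#' Resamples the ground-truth path to the mat rate, splits the body load over
#' the four paws with [solve_paw_shares()], rasterises each paw as an
#' isotropic Gaussian pressure blob of sd `spec$blob_sd` centred on its paw,
#' and quantizes sensel pressures linearly over `[0, max(pressure_range)]`
#' into `quantization_levels` raw counts. Pre-quantization sensel loads sum
#' exactly to `body_weight * g` in every frame (each blob kernel is
#' normalised on the grid).
#'
#' @inheritParams render_force_plate
#' @param spec A [device_spec()] with `kind = "pressure_mat"`.
#' @param quantize Set `FALSE` to keep exact (continuous) sensel loads.
#' @return A `pressure_stream` object: list with `time` (s), `frames`
#'   (`nr x nc x n_frames` array of raw counts, or N when unquantized),
#'   `spec`, `calibration_scale` (N per count), and `unit`.
#' @export
render_pressure_mat <- function(cop_path, geometry = stance_geometry(),
                                spec = device_spec("pressure_mat"), seed = NULL,
                                quantize = TRUE) {
  stopifnot(inherits(spec, "device_spec"))
  if (spec$kind != "pressure_mat") stop("spec$kind must be 'pressure_mat'", call. = FALSE)
  validate_trajectory(cop_path)
  g <- mat_grid(spec)
  pc <- geometry$paw_centres
  margin <- 4 * spec$blob_sd
  if (any(pc[, 1] < min(g$x) + margin) || any(pc[, 1] > max(g$x) - margin) ||
      any(pc[, 2] < min(g$y) + margin) || any(pc[, 2] > max(g$y) - margin)) {
    stop("stance does not fit on the sensel grid (paw blob would be clipped)",
         call. = FALSE)
  }
  # mat clock: nominal k/rate timestamps within the trial span
  src_rate <- attr(cop_path, "rate")
  if (!is.null(src_rate) && abs(src_rate - spec$rate) < 1e-9) {
    tt <- cop_path$time
    xs <- cop_path$x_ap; ys <- cop_path$y_ml
  } else {
    tt <- seq(cop_path$time[1], cop_path$time[nrow(cop_path)], by = 1 / spec$rate)
    xs <- stats::approx(cop_path$time, cop_path$x_ap, xout = tt)$y
    ys <- stats::approx(cop_path$time, cop_path$y_ml, xout = tt)$y
  }
  shares <- solve_paw_shares(cbind(xs, ys), geometry)    # n x 4
  frames <- render_frames_from_shares(t(shares), geometry, spec, quantize)
  structure(list(time = tt, frames = frames$counts, spec = spec,
                 calibration_scale = frames$scale,
                 unit = if (quantize) "raw_count" else "N"),
            class = "pressure_stream")
}

# shares: 4 x n matrix. Returns quantized counts (or exact N) plus the
# N-per-count calibration scale implied by the quantization step.
render_frames_from_shares <- function(shares, geometry, spec, quantize = TRUE) {
  g <- mat_grid(spec)
  w_n <- geometry$body_weight * GRAVITY
  pc <- geometry$paw_centres
  kernels <- vapply(1:4, function(p) {
    kx <- stats::dnorm(g$x, pc[p, 1], spec$blob_sd)
    ky <- stats::dnorm(g$y, pc[p, 2], spec$blob_sd)
    k <- outer(ky, kx)                 # nr x nc
    as.numeric(k / sum(k))             # normalise: loads conserve exactly
  }, numeric(g$nr * g$nc))             # (nr*nc) x 4
  loads <- kernels %*% (w_n * shares)  # sensel loads in N, (nr*nc) x n
  step <- spec$pressure_range[2] / (spec$quantization_levels - 1)  # N/cm^2 per count
  scale <- step * g$area               # N per count
  n <- ncol(loads)
  if (quantize) {
    counts <- round(loads / scale)
    counts[counts < 0] <- 0
    counts[counts > spec$quantization_levels - 1] <- spec$quantization_levels - 1
    arr <- array(counts, dim = c(g$nr, g$nc, n))
  } else {
    arr <- array(loads, dim = c(g$nr, g$nc, n))
  }
  list(counts = arr, scale = scale)
}

#' @export
print.pressure_stream <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<pressure_stream> %d frames of %d x %d sensels @ %g Hz (unit: %s)\n",
              d[3], d[1], d[2], x$spec$rate, x$unit))
  invisible(x)
}
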