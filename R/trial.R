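# One synchronized 10 s stand: ground truth plus both rendered streams.

#' Simulate one synchronized two-device trial
#'
#' Draws a ground-truth CoP path, solves the per-sample paw load shares, and
#' renders the synchronized force-platform (100 Hz) and pressure-mat (60 Hz)
#' streams. The recording keeps its generation inputs (truth path, shares,
#' geometry, specs, seeds) so that artifacts can be injected by re-rendering
#' deterministically.
#'
#' @param params [sway_model_params()] for the ground-truth dynamics.
#' @param geometry [stance_geometry()].
#' @param plate_spec,mat_spec Device specifications.
#' @param seed Integer seed controlling both the path and the device noise.
#' @param trial_id,dog_id Identifiers stored in the recording.
#' @return A `trial_recording`: list with `force` (tibble), `pressure`
#'   (`pressure_stream`), `truth` (`cop_trajectory` at the plate rate),
#'   `geometry`, `specs`, `qc_flags` (tibble of injected artifacts) and
#'   `seed`.
#' @export
simulate_trial <- function(params = sway_model_params(),
                           geometry = stance_geometry(),
                           plate_spec = device_spec("force_plate"),
                           mat_spec = device_spec("pressure_mat"),
                           seed = NULL,
                           trial_id = "trial-1", dog_id = "dog-1") {
  seed <- seed %||% params$seed %||% 1L
  truth <- simulate_cop_path(params, seed = seed)
  rec <- structure(list(trial_id = trial_id, dog_id = dog_id,
                        truth = truth, geometry = geometry,
                        specs = list(plate = plate_spec, mat = mat_spec),
                        share_override = NULL, drift = NULL,
                        qc_flags = tibble::tibble(kind = character(),
                                                  onset = numeric(),
                                                  magnitude = numeric()),
                        seed = as.integer(seed)),
                   class = "trial_recording")
  render_recording(rec)
}

# (Re-)render both device streams from the stored ground truth, applying any
# share override or CoP drift. Deterministic given rec$seed.
render_recording <- function(rec) {
  truth <- rec$truth
  x <- truth$x_ap; y <- truth$y_ml
  if (!is.null(rec$drift)) {
    x <- x + rec$drift$x; y <- y + rec$drift$y
  }
  eff <- new_cop_trajectory(truth$time, x, y, rate = attr(truth, "rate"))
  mat_spec <- rec$specs$mat
  tt <- seq(eff$time[1], eff$time[nrow(eff)], by = 1 / mat_spec$rate)
  xs <- stats::approx(eff$time, eff$x_ap, xout = tt)$y
  ys <- stats::approx(eff$time, eff$y_ml, xout = tt)$y
  shares_mat <- t(solve_paw_shares(cbind(xs, ys), rec$geometry))   # 4 x n_mat
  shares_plate <- t(solve_paw_shares(cbind(x, y), rec$geometry))   # 4 x n_plate
  if (!is.null(rec$share_override)) {
    shares_mat <- apply_share_override(shares_mat, tt, rec$share_override)
    shares_plate <- apply_share_override(shares_plate, eff$time, rec$share_override)
    # unloading moves the true CoP to the centroid of the remaining load
    pc <- rec$geometry$paw_centres
    eff <- new_cop_trajectory(eff$time,
                              colSums(shares_plate * pc[, 1]),
                              colSums(shares_plate * pc[, 2]),
                              rate = attr(truth, "rate"))
  }
  frames <- render_frames_from_shares(shares_mat, rec$geometry, mat_spec,
                                      quantize = TRUE)
  rec$pressure <- structure(list(time = tt, frames = frames$counts,
                                 spec = mat_spec,
                                 calibration_scale = frames$scale,
                                 unit = "raw_count"),
                            class = "pressure_stream")
  rec$force <- render_force_plate(eff, rec$geometry, rec$specs$plate,
                                  seed = rec$seed + 7L)
  rec$effective_truth <- eff
  rec
}

# Ramp one paw's share toward zero after onset, renormalising the rest.
apply_share_override <- function(shares, time, ov) {
  ramp <- pmin(pmax((time - ov$onset) / ov$ramp, 0), 1) * ov$magnitude
  keep <- 1 - ramp                                # multiplier for the paw
  shares[ov$paw, ] <- shares[ov$paw, ] * keep
  tot <- colSums(shares)
  sweep(shares, 2, tot, "/")
}

#' Inject a discard-worthy artifact into a trial recording
#'
#' Emulates the behaviours that force a trial to be discarded: a dog
#' unloading one limb (`"limb_unload"`: the paw's load share ramps toward
#' zero after `onset` over a 0.5 s ramp, the load shifting to the remaining
#' paws) or shifting its body (`"body_shift"`: a drift that ramps linearly
#' from `onset` to the end of the trial, reaching `magnitude` cm in the AP
#' direction). Both streams are re-rendered deterministically from the
#' stored ground truth; the artifact is appended to `qc_flags` as ground
#' truth for quality-control checks.
#'
#' @param recording A `trial_recording` from [simulate_trial()].
#' @param kind `"limb_unload"` or `"body_shift"`.
#' @param onset Onset time, s (within the trial).
#' @param magnitude For `limb_unload`, the fraction of the paw's load
#'   removed (1 = full unload); for `body_shift`, the drift in cm.
#' @param paw Paw index 1--4 (lf, rf, lh, rh) for `limb_unload`.
#' @return The modified `trial_recording`.
#' @export
inject_artifact <- function(recording, kind = c("limb_unload", "body_shift"),
                            onset = 4, magnitude = 1, paw = 3L) {
  stopifnot(inherits(recording, "trial_recording"))
  kind <- match.arg(kind)
  tmax <- max(recording$truth$time)
  if (onset < 0 || onset > tmax) stop("onset must lie within the trial", call. = FALSE)
  if (magnitude == 0) return(recording)
  if (kind == "limb_unload") {
    if (magnitude < 0 || magnitude > 1) {
      stop("limb_unload magnitude is a fraction in [0, 1]", call. = FALSE)
    }
    recording$share_override <- list(paw = as.integer(paw), onset = onset,
                                     ramp = 0.5, magnitude = magnitude)
  } else {
    ramp <- pmin(pmax((recording$truth$time - onset) / (tmax - onset), 0), 1)
    recording$drift <- list(x = magnitude * ramp, y = 0 * ramp)
  }
  recording$qc_flags <- dplyr::bind_rows(
    recording$qc_flags,
    tibble::tibble(kind = kind, onset = onset, magnitude = magnitude))
  render_recording(recording)
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %s / %s: %d plate samples @ %g Hz, %d mat frames @ %g Hz%s\n",
              x$dog_id, x$trial_id, nrow(x$force), x$specs$plate$rate,
              length(x$pressure$time), x$specs$mat$rate,
              if (nrow(x$qc_flags) > 0) sprintf(" [%s]", paste(x$qc_flags$kind, collapse = ",")) else ""))
  invisible(x)
}
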