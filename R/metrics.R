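# The four per-trial postural-stability measures.

#' Maximum anterior-posterior / medial-lateral range
#'
#' Max minus min of the respective CoP coordinate over the trial (cm).
#'
#' @param traj A `cop_trajectory` (>= 1 sample).
#' @return A length-1 numeric, cm.
#' @export
ap_range <- function(traj) {
  validate_trajectory(traj, min_samples = 1L)
  diff(range(traj$x_ap))
}

#' @rdname ap_range
#' @export
ml_range <- function(traj) {
  validate_trajectory(traj, min_samples = 1L)
  diff(range(traj$y_ml))
}

#' Sway path
#'
#' Total length of the CoP trajectory: the sum of planar Euclidean distances
#' between consecutive samples (cm). Strongly dependent on the sampling
#' rate, so cross-device comparisons of this measure reflect capture
#' frequency as much as posture.
#'
#' @param traj A `cop_trajectory` (>= 2 samples).
#' @return A length-1 numeric, cm.
#' @export
sway_path <- function(traj) {
  validate_trajectory(traj, min_samples = 2L)
  sum(sqrt(diff(traj$x_ap)^2 + diff(traj$y_ml)^2))
}

#' 95% confidence-ellipse area
#'
#' Area of the covariance-based ellipse expected to contain 95% of the CoP
#' points: `pi * q * sqrt(lambda1 * lambda2)` with `lambda` the eigenvalues
#' of the sample covariance of `(x, y)` (denominator n - 1) and
#' `q = qchisq(0.95, 2) = 5.991`, the large-sample prediction constant.
#' Collinear or coincident points give area 0 with a degeneracy warning.
#'
#' @param traj A `cop_trajectory` (>= 3 samples for a non-degenerate area).
#' @param q Prediction constant (default `qchisq(0.95, df = 2)`).
#' @return A length-1 numeric, cm^2.
#' @export
ellipse_area_95 <- function(traj, q = stats::qchisq(0.95, df = 2)) {
  validate_trajectory(traj, min_samples = 1L)
  if (nrow(traj) < 3) {
    warning("fewer than 3 samples: degenerate ellipse, area 0", call. = FALSE)
    return(0)
  }
  ev <- eigen(stats::cov(cbind(traj$x_ap, traj$y_ml)), symmetric = TRUE,
              only.values = TRUE)$values
  ev[ev < 0] <- 0
  if (min(ev) <= .Machine$double.eps * max(ev, 1)) {
    warning("collinear or coincident CoP points: degenerate ellipse, area 0",
            call. = FALSE)
    return(0)
  }
  pi * q * sqrt(prod(ev))
}

#' All four stability measures for one trajectory
#'
#' @param traj A `cop_trajectory`.
#' @return A one-row tibble: `ap_range`, `ml_range`, `sway_path`,
#'   `ellipse_area_95` (cm / cm^2), plus `n_samples` and `rate`.
#' @export
#' @examples
#' sq <- tibble::tibble(time = 0:4 / 10,
#'                      x_ap = c(0, 1, 1, 0, 0), y_ml = c(0, 0, 1, 1, 0))
#' stability_measures(sq)
stability_measures <- function(traj) {
  validate_trajectory(traj, min_samples = 2L)
  tibble::tibble(
    ap_range = ap_range(traj),
    ml_range = ml_range(traj),
    sway_path = sway_path(traj),
    ellipse_area_95 = suppressWarnings(ellipse_area_95(traj)),
    n_samples = nrow(traj),
    rate = attr(traj, "rate") %||% NA_real_
  )
}

#' Per-dog means of the per-trial measures
#'
#' Aggregates per-trial stability measures to one row per dog and device
#' (the unit entering the validity and cohort analyses; the reliability
#' model averages the same k trials).
#'
#' @param measures A data frame of per-trial measures with grouping columns.
#' @param ... Grouping columns (defaults to `dog_id` and `device` when
#'   present).
#' @return A tibble of group means with an `n_trials` count.
#' @export
trial_means <- function(measures, ...) {
  vars <- intersect(c("ap_range", "ml_range", "sway_path", "ellipse_area_95"),
                    names(measures))
  if (length(vars) == 0) stop("no stability-measure columns found", call. = FALSE)
  if (nrow(measures) == 0) stop("zero accepted trials: nothing to aggregate", call. = FALSE)
  groups <- rlang::enquos(...)
  if (length(groups) == 0) {
    gcols <- intersect(c("dog_id", "device"), names(measures))
    grouped <- dplyr::group_by(measures, dplyr::across(dplyr::all_of(gcols)))
  } else {
    grouped <- dplyr::group_by(measures, !!!groups)
  }
  dplyr::summarise(grouped,
                   dplyr::across(dplyr::all_of(vars), mean),
                   n_trials = dplyr::n(), .groups = "drop")
}
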