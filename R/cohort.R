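# Synthetic demographic cohort with age and weight effects on the
# stability measures.
#
# Per-dog measure targets are mapped from the demographics, then inverted
# into sway-model parameters: the AP/ML range targets fix the per-axis
# stationary sd through the expected-range ratio kappa(rho), and the
# force-plate sway-path target fixes the lag-1 coefficient rho through the
# closed-form expected step length of the AR(1) increments. Realised
# per-trial measures then scatter around the targets through ordinary
# sampling variability.

# E[range]/sigma for a stationary AR(1) over a 10 s, 100 Hz trial
# (n = 1000), as a cubic in the lag-1 coefficient rho. Fitted once against
# direct simulation (800 replicates per knot over rho in [0.05, 0.95]);
# max error ~1.5%.
KAPPA_COEF <- c(6.5606, -1.4498, 4.8076, -4.4973)

kappa_range <- function(rho) {
  rho <- pmin(pmax(rho, 0), 0.97)
  KAPPA_COEF[1] + KAPPA_COEF[2] * rho + KAPPA_COEF[3] * rho^2 + KAPPA_COEF[4] * rho^3
}

# complete elliptic integral of the second kind, parameter m = k^2
ellip_e <- function(m) {
  stats::integrate(function(th) sqrt(1 - m * sin(th)^2), 0, pi / 2,
                   rel.tol = 1e-10)$value
}

# E|step| of the planar increment: per-axis step sds (sx, sy)
expected_step <- function(sx, sy) {
  a <- max(sx, sy); b <- min(sx, sy)
  if (a == 0) return(0)
  sqrt(2 / pi) * a * ellip_e(1 - (b / a)^2)
}

# Expected plate-measured sway path for sigma = (sap, sml), lag-1 rho,
# n samples, with white CoP-equivalent device noise.
expected_path <- function(sap, sml, rho, n = 1000L, noise_sd = 0.05) {
  sx <- sqrt(2 * sap^2 * (1 - rho) + 2 * noise_sd^2)
  sy <- sqrt(2 * sml^2 * (1 - rho) + 2 * noise_sd^2)
  (n - 1) * expected_step(sx, sy)
}

# Invert (ap_target, ml_target, path_target) -> (sigma_ap, sigma_ml, rho).
# Two-stage fixed point on kappa(rho); rho clamped to [0.05, 0.95] when the
# path target is unreachable at the given amplitudes.
invert_targets <- function(ap_t, ml_t, path_t, n = 1000L, noise_sd = 0.05) {
  rho <- 0.5
  for (i in 1:3) {
    kap <- kappa_range(rho)
    sap <- ap_t / kap; sml <- ml_t / kap
    f <- function(r) expected_path(sap, sml, r, n, noise_sd) - path_t
    lo <- 0.05; hi <- 0.95
    if (f(lo) <= 0) rho <- lo
    else if (f(hi) >= 0) rho <- hi
    else rho <- stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
  }
  kap <- kappa_range(rho)
  list(sigma_ap = ap_t / kap, sigma_ml = ml_t / kap, rho = rho,
       expected_path = expected_path(ap_t / kap, ml_t / kap, rho, n, noise_sd))
}

# Truncated-normal draw by rejection (ranges are wide; cheap).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Simulate the demographic cohort
#'
#' Samples a cohort of dogs (sex, breed type, age, weight, height, body
#' length, BCS), maps age and weight to per-dog stability-measure targets
#' via [cohort_effect_params()], inverts the targets into per-dog sway-model
#' parameters, and simulates `trials_per_dog` synchronized two-device
#' trials per dog, returning the per-trial stability measures from both
#' device pipelines.
#'
#' @param params A [cohort_effect_params()].
#' @param seed Optional integer seed overriding `params$seed`.
#' @param keep_recordings Keep the full `trial_recording` objects
#'   (memory-heavy; default `FALSE` retains only the measures).
#' @param geometry Base [stance_geometry()]; per-dog body weight is filled
#'   in from the sampled demographics.
#' @return A `sway_cohort` tibble: one row per dog x device x trial with
#'   demographics, `device`, `trial`, the four measures, and `artifact`
#'   (injected artifact kind or `NA`). Attributes: `ground_truth` (per-dog
#'   targets and inverted model parameters), `params`, and optionally
#'   `recordings`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_effect_params(n_dogs = 2, seed = 1))
#' trial_means(coh)
simulate_cohort <- function(params = cohort_effect_params(), seed = NULL,
                            keep_recordings = FALSE,
                            geometry = stance_geometry()) {
  stopifnot(inherits(params, "cohort_effect_params"))
  seed <- seed %||% params$seed %||% 1L
  withr::local_seed(as.integer(seed))

  n <- params$n_dogs
  dogs <- tibble::tibble(
    dog_id = sprintf("dog-%03d", seq_len(n)),
    sex = sample(SEX_LEVELS, n, replace = TRUE, prob = c(12, 30) / 42),
    breed_type = sample(BREED_LEVELS, n, replace = TRUE, prob = c(16, 16, 10) / 42),
    age = rtruncnorm(n, params$age_mean, params$age_sd,
                     params$age_range[1], params$age_range[2]),
    weight = rtruncnorm(n, params$weight_mean, params$weight_sd,
                        params$weight_range[1], params$weight_range[2]),
    height_withers = rtruncnorm(n, 19.2, 1.9, 14, 26)
  )
  ratio <- rtruncnorm(n, 1.40, 0.11, 1.1, 1.8)
  dogs$body_length <- ratio * dogs$height_withers
  dogs$bcs <- round(rtruncnorm(n, 3.4, 0.9, 1, 5) * 2) / 2
  dogs$length_height_ratio <- dogs$body_length / dogs$height_withers

  ae <- params$age_effect; we <- params$weight_effect
  nsd <- params$noise_sd
  ap_t <- pmax(ae$ap[1] - ae$ap[2] * log(dogs$age) + stats::rnorm(n, 0, nsd["ap"]), 0.5)
  ml_t <- pmax(ae$ml[1] - ae$ml[2] * log(dogs$age) + stats::rnorm(n, 0, nsd["ml"]), 0.7)
  path_t <- pmax(we$plate[1] + we$plate[2] * dogs$weight + we$plate[3] * dogs$weight^2 +
                   stats::rnorm(n, 0, nsd["path"]), 120)
  mat_path_ref <- we$mat[1] * dogs$weight^we$mat[2]

  plate_spec <- device_spec("force_plate")
  mat_spec <- device_spec("pressure_mat")
  sm <- sway_model_params()           # carries duration/rate defaults
  n_samp <- round(sm$duration * sm$rate)

  inv <- purrr::pmap(list(ap_t, ml_t, path_t), function(a, m, p) {
    invert_targets(a, m, p, n = n_samp, noise_sd = plate_spec$cop_noise_sd)
  })
  truth <- dplyr::bind_cols(
    dogs[, c("dog_id", "age", "weight")],
    tibble::tibble(
      ap_target = ap_t, ml_target = ml_t, path_target = path_t,
      mat_path_ref = mat_path_ref,
      area_target = pi * stats::qchisq(0.95, 2) *
        purrr::map_dbl(inv, "sigma_ap") * purrr::map_dbl(inv, "sigma_ml"),
      sigma_ap = purrr::map_dbl(inv, "sigma_ap"),
      sigma_ml = purrr::map_dbl(inv, "sigma_ml"),
      rho = purrr::map_dbl(inv, "rho"),
      expected_path = purrr::map_dbl(inv, "expected_path")))

  trial_seeds <- matrix(
    sample.int(.Machine$integer.max - 10L, n * params$trials_per_dog),
    nrow = n)
  artifact_draw <- matrix(
    stats::runif(n * params$trials_per_dog) < params$artifact_rate, nrow = n)
  artifact_kind <- matrix(
    sample(c("limb_unload", "body_shift"), n * params$trials_per_dog,
           replace = TRUE), nrow = n)
  artifact_onset <- matrix(stats::runif(n * params$trials_per_dog, 2, 7), nrow = n)

  rows <- vector("list", n * params$trials_per_dog)
  recordings <- if (keep_recordings) vector("list", n * params$trials_per_dog) else NULL
  idx <- 0L
  for (i in seq_len(n)) {
    g <- stance_geometry(paw_centres = geometry$paw_centres,
                         nominal_shares = geometry$nominal_shares,
                         body_weight = dogs$weight[i])
    tau <- -1 / (sm$rate * log(truth$rho[i]))
    p_i <- sway_model_params(tau_ap = tau, tau_ml = tau,
                             sigma_ap = truth$sigma_ap[i],
                             sigma_ml = truth$sigma_ml[i],
                             duration = sm$duration, rate = sm$rate)
    for (tr in seq_len(params$trials_per_dog)) {
      idx <- idx + 1L
      rec <- simulate_trial(p_i, g, plate_spec, mat_spec,
                            seed = trial_seeds[i, tr],
                            trial_id = sprintf("trial-%d", tr),
                            dog_id = dogs$dog_id[i])
      art <- NA_character_
      if (artifact_draw[i, tr]) {
        art <- artifact_kind[i, tr]
        rec <- inject_artifact(rec, art, onset = artifact_onset[i, tr],
                               magnitude = if (art == "limb_unload") 1 else 3)
      }
      m_plate <- stability_measures(cop_from_forceplate(rec$force))
      m_mat <- stability_measures(cop_from_pressure(rec$pressure))
      rows[[idx]] <- dplyr::bind_cols(
        dogs[i, ],
        tibble::tibble(trial = tr, artifact = art),
        dplyr::bind_rows(
          dplyr::mutate(m_plate, device = "force_plate"),
          dplyr::mutate(m_mat, device = "pressure_mat")))
      if (keep_recordings) recordings[[idx]] <- rec
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::relocate(out, "device", .after = "trial")
  attr(out, "ground_truth") <- truth
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  if (keep_recordings) attr(out, "recordings") <- recordings
  class(out) <- c("sway_cohort", class(out))
  out
}

#' Plot cohort measures against a demographic predictor
#'
#' @param object A `sway_cohort`.
#' @param predictor `"age"` or `"weight"`.
#' @param ... Unused.
#' @return A ggplot object faceted by measure and device.
#' @exportS3Method ggplot2::autoplot
autoplot.sway_cohort <- function(object, predictor = c("age", "weight"), ...) {
  predictor <- match.arg(predictor)
  long <- tidyr::pivot_longer(
    trial_means(object, .data$dog_id, .data$device, .data$age, .data$weight),
    cols = c("ap_range", "ml_range", "sway_path", "ellipse_area_95"),
    names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[predictor]], y = .data$value,
                                     colour = .data$device)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = predictor, y = "per-dog mean")
}
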