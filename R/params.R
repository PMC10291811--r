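# Parameter objects for the synthetic quiet-stance generator.

#' Sway-model parameters
#'
#' Parameters of the ground-truth centre-of-pressure (CoP) dynamics used by
#' [simulate_cop_path()]. Each body axis follows an independent stationary
#' first-order autoregressive process (the sampled form of an
#' Ornstein--Uhlenbeck process) with correlation time `tau` (s) and
#' stationary standard deviation `sigma` (cm).
#'
#' The defaults are calibrated so that a 10 s trial sampled at 100 Hz has an
#' expected maximum anterior-posterior range near 2.45 cm and maximum
#' medial-lateral range near 3.45 cm, the normative force-platform magnitudes
#' for small-breed dogs in quiet standing.
#'
#' @param tau_ap,tau_ml Correlation time of the AP / ML axis, seconds (> 0).
#' @param sigma_ap,sigma_ml Stationary standard deviation of the CoP position
#'   on the AP / ML axis, cm (>= 0).
#' @param duration Trial length, seconds (> 0).
#' @param rate Sampling rate, Hz (> 0).
#' @param seed Optional integer seed; identical seeds give identical paths.
#' @return A list of class `sway_model_params`.
#' @export
#' @examples
#' p <- sway_model_params(duration = 2)
#' path <- simulate_cop_path(p)
sway_model_params <- function(tau_ap = 0.02, tau_ml = 0.02,
                              sigma_ap = 0.38, sigma_ml = 0.54,
                              duration = 10, rate = 100, seed = NULL) {
  num <- c(tau_ap = tau_ap, tau_ml = tau_ml, sigma_ap = sigma_ap,
           sigma_ml = sigma_ml, duration = duration, rate = rate)
  if (any(!is.finite(num))) {
    stop("sway_model_params: all numeric parameters must be finite", call. = FALSE)
  }
  if (tau_ap <= 0 || tau_ml <= 0) stop("tau_ap and tau_ml must be > 0", call. = FALSE)
  if (sigma_ap < 0 || sigma_ml < 0) stop("sigma_ap and sigma_ml must be >= 0", call. = FALSE)
  if (duration <= 0 || rate <= 0) stop("duration and rate must be > 0", call. = FALSE)
  if (round(duration * rate) < 2) {
    stop("degenerate trial: duration * rate must give at least 2 samples", call. = FALSE)
  }
  structure(list(tau_ap = tau_ap, tau_ml = tau_ml,
                 sigma_ap = sigma_ap, sigma_ml = sigma_ml,
                 duration = duration, rate = rate, seed = seed),
            class = "sway_model_params")
}

#' Stance geometry of a standing quadruped
#'
#' Positions of the four paw centres on the support surface, the nominal
#' share of body weight carried by each paw, and the body mass. Coordinates
#' are cm in surface coordinates: x is anterior-posterior (cranial positive),
#' y is medial-lateral (left positive), origin at the surface centre.
#'
#' The default is a small-dog stance: front paws at x = +13 cm, hind paws at
#' x = -13 cm, half-track 3.5 cm, with a front-heavy 0.3/0.3/0.2/0.2 nominal
#' load split (quadrupeds carry more weight on the thoracic limbs).
#'
#' @param paw_centres 4 x 2 numeric matrix of paw-centre positions (cm),
#'   rows ordered left-front, right-front, left-hind, right-hind.
#' @param nominal_shares Length-4 non-negative load fractions summing to 1.
#' @param body_weight Body mass, kg (> 0).
#' @return A list of class `stance_geometry`.
#' @export
stance_geometry <- function(paw_centres = NULL,
                            nominal_shares = c(0.3, 0.3, 0.2, 0.2),
                            body_weight = 5.4) {
  if (is.null(paw_centres)) {
    paw_centres <- rbind(lf = c(13, 3.5), rf = c(13, -3.5),
                         lh = c(-13, 3.5), rh = c(-13, -3.5))
  }
  paw_centres <- as.matrix(paw_centres)
  if (!all(dim(paw_centres) == c(4L, 2L)) || any(!is.finite(paw_centres))) {
    stop("paw_centres must be a finite 4 x 2 matrix", call. = FALSE)
  }
  if (anyDuplicated(paw_centres) > 0) {
    stop("paw centres must be pairwise distinct", call. = FALSE)
  }
  if (length(nominal_shares) != 4L || any(nominal_shares < 0)) {
    stop("nominal_shares must be 4 non-negative fractions", call. = FALSE)
  }
  if (abs(sum(nominal_shares) - 1) > 1e-9) {
    stop("nominal_shares must sum to 1 (within 1e-9)", call. = FALSE)
  }
  if (!is.finite(body_weight) || body_weight <= 0) {
    stop("body_weight must be a positive mass in kg", call. = FALSE)
  }
  if (is.null(rownames(paw_centres))) rownames(paw_centres) <- c("lf", "rf", "lh", "rh")
  structure(list(paw_centres = paw_centres,
                 nominal_shares = as.numeric(nominal_shares),
                 body_weight = body_weight),
            class = "stance_geometry")
}

#' Measurement-device specification
#'
#' Describes one of the two recording devices. The force platform samples at
#' 100 Hz and is characterised by its CoP-equivalent noise (default 0.05 cm,
#' i.e. < 0.5 mm CoP accuracy). The pressure mat samples at 60 Hz on a
#' rectangular sensel grid with a measuring resolution of 1.4 sensel/cm^2
#' (pitch 1/sqrt(1.4) ~ 0.845 cm), a pressure range of 34.5--86.2 N/cm^2 and
#' 8-bit quantization.
#'
#' @param kind `"force_plate"` or `"pressure_mat"`.
#' @param rate Sampling rate, Hz.
#' @param cop_noise_sd Force plate only: CoP-equivalent white noise sd, cm.
#' @param sensel_pitch Pressure mat only: sensel pitch, cm.
#' @param grid_dim Pressure mat only: grid size `c(n_ml_rows, n_ap_cols)`.
#' @param pressure_range Pressure mat only: `c(min, max)` measurable
#'   pressure, N/cm^2; quantization spans `[0, max]`.
#' @param quantization_levels Pressure mat only: number of raw count levels.
#' @param blob_sd Pressure mat only: sd of the isotropic Gaussian paw-pressure
#'   blob used when rendering synthetic frames, cm.
#' @return A list of class `device_spec`.
#' @export
device_spec <- function(kind = c("force_plate", "pressure_mat"),
                        rate = NULL,
                        cop_noise_sd = 0.05,
                        sensel_pitch = 1 / sqrt(1.4),
                        grid_dim = c(44L, 52L),
                        pressure_range = c(34.5, 86.2),
                        quantization_levels = 256L,
                        blob_sd = 0.8) {
  kind <- match.arg(kind)
  if (is.null(rate)) rate <- if (kind == "force_plate") 100 else 60
  if (!is.finite(rate) || rate <= 0) stop("rate must be > 0", call. = FALSE)
  if (kind == "force_plate") {
    if (!is.finite(cop_noise_sd) || cop_noise_sd < 0) {
      stop("cop_noise_sd must be >= 0", call. = FALSE)
    }
    out <- list(kind = kind, rate = rate, cop_noise_sd = cop_noise_sd)
  } else {
    if (sensel_pitch <= 0) stop("sensel_pitch must be > 0", call. = FALSE)
    if (length(grid_dim) != 2L || any(grid_dim < 2)) {
      stop("grid_dim must give at least a 2 x 2 sensel grid", call. = FALSE)
    }
    if (pressure_range[1] >= pressure_range[2]) {
      stop("pressure_range must satisfy min < max", call. = FALSE)
    }
    if (quantization_levels < 2) stop("quantization_levels must be >= 2", call. = FALSE)
    if (blob_sd <= 0) stop("blob_sd must be > 0", call. = FALSE)
    out <- list(kind = kind, rate = rate, sensel_pitch = sensel_pitch,
                grid_dim = as.integer(grid_dim),
                pressure_range = as.numeric(pressure_range),
                quantization_levels = as.integer(quantization_levels),
                blob_sd = blob_sd)
  }
  structure(out, class = "device_spec")
}

#' Cohort-effect parameters for the synthetic dog cohort
#'
#' Controls the demographic composition of a simulated cohort and the
#' cohort-level effects of age and weight on the stability measures.
#'
#' Age acts on postural amplitude: the per-dog force-platform targets for AP
#' and ML range decrease logarithmically with age
#' (`target = intercept - slope * log(age)`), and the 95% ellipse-area target
#' decreases with them (it is implied by the two amplitudes). Weight acts on
#' sway-path length: the force-platform sway-path target follows a quadratic
#' in weight (`c0 + c1 w + c2 w^2`, decreasing over the cohort range) and the
#' pressure-mat reference target a power law (`a * w^b`). Per-dog Gaussian
#' noise (`noise_sd`) scatters targets between dogs.
#'
#' @param n_dogs Number of dogs (>= 2).
#' @param age_range,weight_range Truncation ranges for sampled age (years)
#'   and weight (kg); non-degenerate.
#' @param age_mean,age_sd,weight_mean,weight_sd Sampling moments of the
#'   demographic normals before truncation.
#' @param age_effect List with components `ap` and `ml`, each
#'   `c(intercept, slope)` of the decreasing logarithmic map age -> range
#'   target (cm).
#' @param weight_effect List with components `plate` (`c(c0, c1, c2)`,
#'   quadratic map weight -> force-plate sway-path target, cm) and `mat`
#'   (`c(a, b)`, power map weight -> pressure-mat sway-path reference, cm).
#' @param noise_sd Named vector `c(ap =, ml =, path =)` of between-dog
#'   target noise (cm).
#' @param trials_per_dog Trials per dog (default 5, 10 s each).
#' @param artifact_rate Probability that a trial carries an injected
#'   discard-worthy artifact.
#' @param seed Optional integer seed.
#' @return A list of class `cohort_effect_params`.
#' @export
cohort_effect_params <- function(n_dogs = 42L,
                                 age_range = c(0.6, 13),
                                 weight_range = c(3.2, 9),
                                 age_mean = 4.3, age_sd = 3.2,
                                 weight_mean = 5.4, weight_sd = 1.4,
                                 age_effect = list(ap = c(3.00, 0.38),
                                                   ml = c(4.08, 0.43)),
                                 weight_effect = list(plate = c(1100, -110, 5.5),
                                                      mat = c(312, -0.3)),
                                 noise_sd = c(ap = 0.60, ml = 0.70, path = 17),
                                 trials_per_dog = 5L,
                                 artifact_rate = 0,
                                 seed = NULL) {
  if (n_dogs < 2) stop("n_dogs must be >= 2", call. = FALSE)
  if (diff(age_range) <= 0 || diff(weight_range) <= 0) {
    stop("age_range and weight_range must be non-degenerate", call. = FALSE)
  }
  if (age_range[1] <= 0.5) age_range[1] <- max(age_range[1], 0.51)
  stopifnot(is.list(age_effect), all(c("ap", "ml") %in% names(age_effect)),
            is.list(weight_effect), all(c("plate", "mat") %in% names(weight_effect)),
            length(weight_effect$plate) == 3L, length(weight_effect$mat) == 2L)
  noise_sd <- noise_sd[c("ap", "ml", "path")]
  if (any(is.na(noise_sd)) || any(noise_sd < 0)) {
    stop("noise_sd must provide non-negative ap, ml and path components", call. = FALSE)
  }
  if (artifact_rate < 0 || artifact_rate > 1) {
    stop("artifact_rate must be in [0, 1]", call. = FALSE)
  }
  structure(list(n_dogs = as.integer(n_dogs),
                 age_range = age_range, weight_range = weight_range,
                 age_mean = age_mean, age_sd = age_sd,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 age_effect = age_effect, weight_effect = weight_effect,
                 noise_sd = noise_sd,
                 trials_per_dog = as.integer(trials_per_dog),
                 artifact_rate = artifact_rate, seed = seed),
            class = "cohort_effect_params")
}
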