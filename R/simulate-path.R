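#' Simulate a ground-truth CoP path
#'
#' Draws one quiet-stance CoP trajectory. Each axis is an independent
#' stationary AR(1) process, the exact discretization of an
#' Ornstein--Uhlenbeck process: lag-1 coefficient `rho = exp(-1 / (rate * tau))`,
#' innovation sd `sigma * sqrt(1 - rho^2)`, and a stationary initial draw, so
#' the marginal sd is exactly `sigma` at every sample.
#'
#' The trial holds `n = round(duration * rate)` samples at times
#' `0, 1/rate, ..., (n - 1)/rate` (the first sample sits at t = 0; the
#' nominal end time `duration` itself is not sampled).
#'
#' @param params A [sway_model_params()] object.
#' @param seed Optional integer seed overriding `params$seed`.
#' @return A `cop_trajectory` tibble with columns `time`, `x_ap`, `y_ml` (cm).
#' @export
#' @examples
#' path <- simulate_cop_path(sway_model_params(duration = 2, seed = 1))
#' stability_measures(path)
simulate_cop_path <- function(params = sway_model_params(), seed = NULL) {
  if (!inherits(params, "sway_model_params")) {
    params <- do.call(sway_model_params, as.list(params))
  }
  seed <- seed %||% params$seed
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  n <- round(params$duration * params$rate)
  x <- ar1_draw(n, params$rate, params$tau_ap, params$sigma_ap)
  y <- ar1_draw(n, params$rate, params$tau_ml, params$sigma_ml)
  new_cop_trajectory(time = (seq_len(n) - 1) / params$rate,
                     x_ap = x, y_ml = y, rate = params$rate)
}

# Stationary AR(1): x_1 ~ N(0, sigma^2), x_t = rho x_{t-1} + e_t.
ar1_draw <- function(n, rate, tau, sigma) {
  if (sigma == 0) return(numeric(n))
  rho <- exp(-1 / (rate * tau))
  innov <- stats::rnorm(n, 0, sigma * sqrt(1 - rho^2))
  innov[1] <- stats::rnorm(1, 0, sigma)
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}
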