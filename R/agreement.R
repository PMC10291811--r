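# Method-comparison validity: Bland-Altman agreement and Pearson
# correlation between the two devices.

#' Bland-Altman agreement between two devices
#'
#' Computes the mean difference (bias, device A minus device B), the sd of
#' the differences (denominator n - 1), the 95% limits of agreement
#' `bias +/- 1.96 sd`, and the proportional-bias trend: the ordinary
#' least-squares slope of the differences on the pair means, with its
#' two-sided p-value. A positive bias means device A reads higher.
#'
#' @param data A data frame in long format: one value per subject and
#'   device. Alternatively `NULL` when `a` and `b` are given directly.
#' @param value Column holding the measured value (unquoted).
#' @param device Column naming the device (unquoted); must have exactly two
#'   levels. `device_a` selects which level plays A.
#' @param id Column identifying the subject (unquoted); pairs are matched on
#'   it.
#' @param device_a Optional level of `device` treated as device A (default:
#'   first level encountered).
#' @param a,b Numeric vectors of paired values, used when `data` is `NULL`.
#' @param loa_multiplier Multiplier for the limits of agreement
#'   (default 1.96).
#' @return A `sway_agreement` object with fields `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `pearson_r`, `pearson_p`, `trend_slope`,
#'   `trend_p`, `n`, and the paired data in `$pairs`. Supports [tidy()],
#'   [glance()] and [ggplot2::autoplot()].
#' @export
#' @examples
#' d <- tibble::tibble(dog = rep(1:5, 2),
#'                     device = rep(c("plate", "mat"), each = 5),
#'                     ap = c(2, 3, 4, 2.5, 3.5, 1, 2, 3, 1.5, 2.5))
#' bland_altman(d, ap, device, dog)
bland_altman <- function(data = NULL, value, device, id, device_a = NULL,
                         a = NULL, b = NULL, loa_multiplier = 1.96) {
  if (!is.null(data)) {
    value <- rlang::enquo(value); device <- rlang::enquo(device); id <- rlang::enquo(id)
    wide <- tidyr::pivot_wider(
      dplyr::select(data, !!id, !!device, !!value),
      names_from = !!device, values_from = !!value)
    devs <- setdiff(names(wide), rlang::as_name(id))
    if (length(devs) != 2) {
      stop("bland_altman needs exactly two device levels", call. = FALSE)
    }
    if (!is.null(device_a)) devs <- c(device_a, setdiff(devs, device_a))
    a <- wide[[devs[1]]]; b <- wide[[devs[2]]]
    labels <- devs
  } else {
    labels <- c("A", "B")
  }
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3) stop("bland_altman needs at least 3 finite pairs", call. = FALSE)
  diffs <- a - b
  means <- (a + b) / 2
  bias <- mean(diffs)
  sd_diff <- stats::sd(diffs)
  ct <- pearson_validity(a, b)
  # proportional-bias trend: OLS of differences on pair means, computed
  # directly so that exact fits and constant differences stay warning-free
  sxx <- sum((means - mean(means))^2)
  if (sxx > 0) {
    trend_slope <- sum((means - mean(means)) * (diffs - bias)) / sxx
    resid <- diffs - bias - trend_slope * (means - mean(means))
    s2 <- sum(resid^2) / (length(a) - 2)
    trend_p <- if (s2 > 0) {
      tval <- trend_slope / sqrt(s2 / sxx)
      2 * stats::pt(-abs(tval), df = length(a) - 2)
    } else NA_real_
  } else {
    trend_slope <- 0; trend_p <- NA_real_
  }
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = bias - loa_multiplier * sd_diff,
                 loa_high = bias + loa_multiplier * sd_diff,
                 loa_multiplier = loa_multiplier,
                 pearson_r = ct$r, pearson_p = ct$p,
                 trend_slope = trend_slope, trend_p = trend_p,
                 n = length(a), devices = labels,
                 pairs = tibble::tibble(a = a, b = b,
                                        mean = means, diff = diffs)),
            class = "sway_agreement")
}

#' Pearson validity correlation
#'
#' Product-moment correlation between paired device readings with the
#' two-sided p-value from the t transform on n - 2 degrees of freedom
#' (via [stats::cor.test()]).
#'
#' @param a,b Paired numeric vectors (>= 3 finite pairs, non-zero variance).
#' @return A list `list(r, p, n)`.
#' @export
pearson_validity <- function(a, b) {
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3) stop("pearson_validity needs at least 3 finite pairs", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("undefined correlation: one side has zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(a, b, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' @export
print.sway_agreement <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (%s - %s), n = %d\n",
              x$devices[1], x$devices[2], x$n))
  cat(sprintf("  bias %.3f  sd(diff) %.3f  LoA [%.3f, %.3f]\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high))
  cat(sprintf("  Pearson r %.3f (p %.3g); trend slope %.3f (p %.3g)\n",
              x$pearson_r, x$pearson_p, x$trend_slope, x$trend_p))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sway_agreement <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd_diff = x$sd_diff,
                 loa_low = x$loa_low, loa_high = x$loa_high,
                 pearson_r = x$pearson_r, pearson_p = x$pearson_p,
                 trend_slope = x$trend_slope, trend_p = x$trend_p, n = x$n)
}

#' @exportS3Method generics::glance
glance.sway_agreement <- function(x, ...) tidy.sway_agreement(x)

#' @exportS3Method ggplot2::autoplot
autoplot.sway_agreement <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = sprintf("Mean of %s and %s", object$devices[1], object$devices[2]),
                  y = sprintf("%s - %s", object$devices[1], object$devices[2]),
                  title = "Bland-Altman agreement")
}

#' Device validity table across all four measures
#'
#' Per-measure device means and SDs, Pearson correlation between devices,
#' and the Bland-Altman bias, limits of agreement and proportional-bias
#' trend, computed on per-dog means (one value per dog and device).
#'
#' @param measures Long tibble of per-dog (or per-trial) measures with
#'   `dog_id`, `device` and the four measure columns; per-dog means are
#'   taken if several rows per dog/device are present.
#' @param device_a Device level treated as A in differences (default
#'   `"force_plate"`).
#' @param per_dog_means Aggregate trials to per-dog means first
#'   (default TRUE).
#' @return A `sway_validity` tibble: one row per measure.
#' @export
device_validity <- function(measures, device_a = "force_plate",
                            per_dog_means = TRUE) {
  vars <- intersect(c("ap_range", "ml_range", "sway_path", "ellipse_area_95"),
                    names(measures))
  dat <- if (per_dog_means) trial_means(measures) else measures
  devs <- unique(dat$device)
  if (length(devs) != 2) stop("device_validity needs exactly two devices", call. = FALSE)
  device_b <- setdiff(devs, device_a)
  rows <- purrr::map(vars, function(v) {
    wide <- tidyr::pivot_wider(dat[, c("dog_id", "device", v)],
                               names_from = "device", values_from = dplyr::all_of(v))
    ba <- bland_altman(a = wide[[device_a]], b = wide[[device_b]])
    tibble::tibble(measure = v,
                   mean_a = mean(wide[[device_a]]), sd_a = stats::sd(wide[[device_a]]),
                   mean_b = mean(wide[[device_b]]), sd_b = stats::sd(wide[[device_b]]),
                   dplyr::bind_cols(tidy(ba)))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "device_a") <- device_a
  attr(out, "device_b") <- device_b
  class(out) <- c("sway_validity", class(out))
  out
}
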