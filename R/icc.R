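# Intraclass correlation for inter-trial reliability: two-way mixed
# effects, absolute agreement, mean of k ratings -- ICC(A,k) in the
# McGraw & Wong nomenclature.

#' ICC(A,k): two-way mixed, absolute agreement, average of k ratings
#'
#' From the two-way mean squares of a complete n x k matrix (rows = subjects,
#' columns = trials/raters) -- rows `MS_R`, columns `MS_C`, error `MS_E` --
#' the point estimate is
#' `ICC(A,k) = (MS_R - MS_E) / (MS_R + (MS_C - MS_E) / n)`.
#' The 95% confidence interval is the F-based absolute-agreement interval
#' with Satterthwaite degrees of freedom for the single-rating form,
#' transformed to the average-of-k form by the Spearman-Brown relation.
#' The significance test is `F = MS_R / MS_E` on `(n - 1, (n - 1)(k - 1))`
#' degrees of freedom.
#'
#' Negative estimates (possible near the null) are reported as computed,
#' with a warning, rather than floored at zero.
#'
#' @param x A complete numeric n x k matrix, or a long data frame.
#' @param subject,trial,value For the data-frame interface: unquoted columns
#'   identifying the subject, the trial/rater and the measured value.
#' @param conf_level Confidence level (default 0.95).
#' @return A `sway_icc` object: `icc`, `ci_low`, `ci_high`, `p_value`,
#'   `band`, `n`, `k`, the mean squares, and the model descriptor. Supports
#'   [tidy()] and [glance()].
#' @export
#' @examples
#' m <- matrix(c(4, 4.1, 6, 6.2, 8, 7.9), nrow = 3, byrow = TRUE)
#' icc_a_k(m)
icc_a_k <- function(x, subject, trial, value, conf_level = 0.95) {
  if (is.data.frame(x)) {
    subject <- rlang::enquo(subject); trial <- rlang::enquo(trial)
    value <- rlang::enquo(value)
    wide <- tidyr::pivot_wider(dplyr::select(x, !!subject, !!trial, !!value),
                               names_from = !!trial, values_from = !!value)
    x <- as.matrix(wide[, -1, drop = FALSE])
  }
  x <- as.matrix(x)
  if (anyNA(x)) stop("icc_a_k requires a complete matrix (no missing cells)", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("icc_a_k needs at least 2 subjects and 2 trials", call. = FALSE)

  grand <- mean(x)
  rowm <- rowMeans(x); colm <- colMeans(x)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  sse <- sum((x - outer(rowm, colm, "+") + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))

  icc_k <- (msr - mse) / (msr + (msc - mse) / n)
  icc_1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  if (is.finite(icc_k) && icc_k < 0) {
    warning("negative ICC estimate (reported as computed)", call. = FALSE)
  }

  alpha <- 1 - conf_level
  if (1 - icc_1 < 1e-12) {
    # zero within-subject variance: the interval degenerates at the estimate
    ci <- c(icc_k, icc_k)
    f_stat <- Inf
    p <- 0
    return(structure(list(icc = icc_k, icc_single = icc_1,
                          ci_low = min(ci), ci_high = max(ci),
                          conf_level = conf_level, p_value = p,
                          band = icc_band(icc_k),
                          n = n, k = k, ms_rows = msr, ms_cols = msc,
                          ms_error = mse,
                          model = sprintf(
                            "two-way mixed effects, absolute agreement, mean of k = %d", k)),
                     class = "sway_icc"))
  }
  a <- k * icc_1 / (n * (1 - icc_1))
  b <- 1 + k * icc_1 * (n - 1) / (n * (1 - icc_1))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  l1 <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  u1 <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  sb <- function(r1) r1 * k / (1 + r1 * (k - 1))
  ci <- c(sb(l1), sb(u1))

  f_stat <- msr / mse
  p <- stats::pf(f_stat, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)

  structure(list(icc = icc_k, icc_single = icc_1,
                 ci_low = min(ci), ci_high = max(ci),
                 conf_level = conf_level, p_value = p,
                 band = icc_band(icc_k),
                 n = n, k = k, ms_rows = msr, ms_cols = msc, ms_error = mse,
                 model = sprintf(
                   "two-way mixed effects, absolute agreement, mean of k = %d", k)),
            class = "sway_icc")
}

#' Qualitative reliability band for an ICC value
#'
#' `< 0.5` poor; `[0.5, 0.75)` moderate; `[0.75, 0.90)` good; `>= 0.90`
#' excellent. Boundary values fall in the upper band.
#'
#' @param value Numeric ICC value(s), each `<= 1`.
#' @return Character vector of bands.
#' @export
#' @examples
#' icc_band(c(0.49, 0.5, 0.792, 0.986))
icc_band <- function(value) {
  if (any(value > 1 + 1e-12, na.rm = TRUE)) {
    stop("ICC values cannot exceed 1", call. = FALSE)
  }
  cut(value, breaks = c(-Inf, 0.5, 0.75, 0.90, Inf), right = FALSE,
      labels = c("poor", "moderate", "good", "excellent")) |> as.character()
}

#' @export
print.sway_icc <- function(x, ...) {
  cat(sprintf("ICC(A,k) [%s]\n", x$model))
  cat(sprintf("  ICC %.3f  %g%% CI [%.3f, %.3f]  (%s; p %.3g; n = %d, k = %d)\n",
              x$icc, 100 * x$conf_level, x$ci_low, x$ci_high, x$band,
              x$p_value, x$n, x$k))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sway_icc <- function(x, ...) {
  tibble::tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
                 p_value = x$p_value, band = x$band, n = x$n, k = x$k)
}

#' @exportS3Method generics::glance
glance.sway_icc <- function(x, ...) tidy.sway_icc(x)

#' Inter-trial reliability table per measure and device
#'
#' Builds the per-device subject x trial matrices from a long per-trial
#' measures table and computes [icc_a_k()] for each stability measure.
#' Only dogs contributing the full set of `k` trials on a device enter that
#' device's matrix (the absolute-agreement model needs complete rows).
#'
#' @param measures Long tibble with `dog_id`, `device`, `trial` and the
#'   measure columns.
#' @return A `sway_reliability` tibble: one row per measure and device with
#'   ICC, CI bounds, band and the n/k actually used.
#' @export
device_reliability <- function(measures) {
  vars <- intersect(c("ap_range", "ml_range", "sway_path", "ellipse_area_95"),
                    names(measures))
  stopifnot(all(c("dog_id", "device", "trial") %in% names(measures)))
  combos <- tidyr::expand_grid(measure = vars,
                               device = unique(measures$device))
  rows <- purrr::pmap(combos, function(measure, device) {
    sub <- measures[measures$device == device, c("dog_id", "trial", measure)]
    k_full <- max(table(sub$dog_id))
    counts <- table(sub$dog_id)
    keep <- names(counts)[counts == k_full]
    sub <- sub[sub$dog_id %in% keep, ]
    wide <- tidyr::pivot_wider(sub, names_from = "trial",
                               values_from = dplyr::all_of(measure))
    if (ncol(wide) - 1L < 2L || nrow(wide) < 2L) {
      return(tibble::tibble(measure = measure, device = device,
                            icc = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, p_value = NA_real_,
                            band = NA_character_, n = nrow(wide),
                            k = ncol(wide) - 1L))
    }
    res <- icc_a_k(as.matrix(wide[, -1]))
    dplyr::bind_cols(tibble::tibble(measure = measure, device = device),
                     tidy(res))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sway_reliability", class(out))
  out
}
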