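# Demographic regression families: linear, logarithmic, quadratic,
# exponential, power. Non-linear families are fitted by least squares in
# the ORIGINAL scale (log-scale closed forms serve only as starting
# values), so the reported R^2 is comparable across families.

FIT_FAMILIES <- c("linear", "logarithmic", "quadratic", "exponential", "power")
FAMILY_NPAR <- c(linear = 2L, logarithmic = 2L, quadratic = 3L,
                 exponential = 2L, power = 2L)

#' Fit one regression family
#'
#' Families: `linear` `y = a + b x`; `logarithmic` `y = a + b log(x)`;
#' `quadratic` `y = a + b x + c x^2`; `exponential` `y = a exp(b x)`;
#' `power` `y = a x^b`. The logarithmic and power families require `x > 0`;
#' exponential and power initialisation requires `y > 0` (the least-squares
#' refinement itself runs in the original scale via
#' [minpack.lm::nlsLM()]). `r_squared = 1 - RSS/TSS` on original-scale
#' residuals; the overall p-value is the F test of the fit against the
#' intercept-only model.
#'
#' @param data A data frame, or `NULL` when `x`/`y` are vectors.
#' @param x,y Predictor / response: unquoted columns of `data`, or numeric
#'   vectors when `data` is `NULL`.
#' @param family One of `r toString(FIT_FAMILIES)`.
#' @return A `sway_fit` object: `family`, named `coefficients`,
#'   `r_squared`, `p_value`, `n`, `rss`, plus predictor/response names.
#'   Supports [tidy()], [glance()], [predict()] and [ggplot2::autoplot()].
#' @export
#' @examples
#' fit_family(NULL, x = 1:10, y = 3 + 2 * (1:10), family = "linear")
fit_family <- function(data = NULL, x, y, family = FIT_FAMILIES) {
  family <- match.arg(family)
  if (!is.null(data)) {
    xq <- rlang::enquo(x); yq <- rlang::enquo(y)
    xname <- rlang::as_name(xq); yname <- rlang::as_name(yq)
    x <- rlang::eval_tidy(xq, data); y <- rlang::eval_tidy(yq, data)
  } else {
    xname <- "x"; yname <- "y"
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  npar <- FAMILY_NPAR[[family]]
  if (length(x) < npar + 1) {
    stop(sprintf("fit_family(%s) needs at least %d observations", family, npar + 1),
         call. = FALSE)
  }
  if (family %in% c("logarithmic", "power") && any(x <= 0)) {
    stop(sprintf("family '%s' requires strictly positive x", family), call. = FALSE)
  }
  if (family %in% c("exponential", "power") && any(y <= 0)) {
    stop(sprintf("family '%s' requires strictly positive y for initialisation",
                 family), call. = FALSE)
  }

  co <- switch(
    family,
    linear = {
      fit <- stats::lm(y ~ x)
      stats::setNames(stats::coef(fit), c("a", "b"))
    },
    logarithmic = {
      fit <- stats::lm(y ~ log(x))
      stats::setNames(stats::coef(fit), c("a", "b"))
    },
    quadratic = {
      fit <- stats::lm(y ~ x + I(x^2))
      stats::setNames(stats::coef(fit), c("a", "b", "c"))
    },
    exponential = {
      init <- unname(stats::coef(stats::lm(log(y) ~ x)))
      fit <- minpack.lm::nlsLM(y ~ a * exp(b * x),
                               start = list(a = exp(init[1]), b = init[2]),
                               control = minpack.lm::nls.lm.control(maxiter = 200))
      stats::coef(fit)[c("a", "b")]
    },
    power = {
      init <- unname(stats::coef(stats::lm(log(y) ~ log(x))))
      fit <- minpack.lm::nlsLM(y ~ a * x^b,
                               start = list(a = exp(init[1]), b = init[2]),
                               control = minpack.lm::nls.lm.control(maxiter = 200))
      stats::coef(fit)[c("a", "b")]
    })

  pred <- predict_family(family, co, x)
  rss <- sum((y - pred)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) max(0, 1 - rss / tss) else 1
  n <- length(x)
  df1 <- npar - 1L; df2 <- n - npar
  p_value <- if (rss == 0) {
    0
  } else if (tss <= rss) {
    1
  } else {
    f_stat <- ((tss - rss) / df1) / (rss / df2)
    stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  }
  structure(list(family = family, coefficients = co,
                 r_squared = r2, p_value = p_value, n = n, rss = rss,
                 predictor = xname, response = yname,
                 data = tibble::tibble(x = x, y = y)),
            class = "sway_fit")
}

predict_family <- function(family, co, x) {
  switch(family,
         linear = co[["a"]] + co[["b"]] * x,
         logarithmic = co[["a"]] + co[["b"]] * log(x),
         quadratic = co[["a"]] + co[["b"]] * x + co[["c"]] * x^2,
         exponential = co[["a"]] * exp(co[["b"]] * x),
         power = co[["a"]] * x^co[["b"]])
}

#' @export
predict.sway_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
  else if (is.data.frame(newdata)) newdata[[object$predictor]] %||% newdata[[1]]
  else newdata
  predict_family(object$family, object$coefficients, x)
}

#' Fit several families and select the best
#'
#' Fits every requested family (skipping ones whose domain constraints the
#' data violate), returns the one with the highest `r_squared`, breaking
#' ties (within 1e-9) toward fewer coefficients. All candidate fits are
#' retained in `$candidates`.
#'
#' @inheritParams fit_family
#' @param families Candidate families (>= 2).
#' @return The winning `sway_fit`, with a `candidates` field (named list of
#'   all successful fits).
#' @export
select_family <- function(data = NULL, x, y, families = FIT_FAMILIES) {
  if (length(families) < 2) stop("select_family needs at least 2 candidate families",
                                 call. = FALSE)
  if (!is.null(data)) {
    xq <- rlang::enquo(x); yq <- rlang::enquo(y)
    xv <- rlang::eval_tidy(xq, data); yv <- rlang::eval_tidy(yq, data)
    xname <- rlang::as_name(xq); yname <- rlang::as_name(yq)
  } else {
    xv <- x; yv <- y; xname <- "x"; yname <- "y"
  }
  fits <- list()
  for (fam in families) {
    f <- tryCatch(fit_family(NULL, xv, yv, family = fam), error = function(e) NULL)
    if (!is.null(f)) {
      f$predictor <- xname; f$response <- yname
      fits[[fam]] <- f
    }
  }
  if (length(fits) == 0) stop("selection error: every candidate family failed",
                              call. = FALSE)
  r2 <- vapply(fits, `[[`, numeric(1), "r_squared")
  npar <- FAMILY_NPAR[names(fits)]
  best_r2 <- max(r2)
  contenders <- names(fits)[r2 >= best_r2 - 1e-9]
  winner <- contenders[which.min(npar[contenders])]
  out <- fits[[winner]]
  out$candidates <- fits
  out
}

#' @export
print.sway_fit <- function(x, ...) {
  cat(sprintf("sway_fit: %s, %s ~ %s\n", x$family, x$response, x$predictor))
  cat("  coefficients:", paste(sprintf("%s = %.6g", names(x$coefficients),
                                       x$coefficients), collapse = ", "), "\n")
  cat(sprintf("  R^2 = %.4f, p = %.3g, n = %d\n", x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sway_fit <- function(x, ...) {
  tibble::tibble(family = x$family,
                 term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @exportS3Method generics::glance
glance.sway_fit <- function(x, ...) {
  tibble::tibble(family = x$family, r_squared = x$r_squared,
                 p_value = x$p_value, n = x$n,
                 predictor = x$predictor, response = x$response)
}

#' @exportS3Method ggplot2::autoplot
autoplot.sway_fit <- function(object, ...) {
  grid <- tibble::tibble(x = seq(min(object$data$x), max(object$data$x),
                                 length.out = 200))
  grid$y <- predict_family(object$family, object$coefficients, grid$x)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = object$predictor, y = object$response,
                  title = sprintf("%s fit (R^2 = %.2f)", object$family,
                                  object$r_squared))
}
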