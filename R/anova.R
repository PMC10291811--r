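#' One-way analysis of variance
#'
#' Classical between/within decomposition with equal-variance assumption:
#' `F = MS_between / MS_within` on `(g - 1, N - g)` degrees of freedom
#' (computed via [stats::oneway.test()] with `var.equal = TRUE`), plus the
#' per-group means and SDs.
#'
#' @param data A data frame.
#' @param value Unquoted column holding the response.
#' @param group Unquoted column holding the factor (>= 2 groups, each with
#'   >= 2 values).
#' @return A `sway_anova` object: `f_statistic`, `p_value`, `df_between`,
#'   `df_within`, `groups` (tibble of group n/mean/sd) and the factor name.
#'   Supports [tidy()] and [glance()].
#' @export
#' @examples
#' d <- tibble::tibble(g = rep(c("a", "b"), each = 4), y = c(1:4, 3:6))
#' one_way_anova(d, y, g)
one_way_anova <- function(data, value, group) {
  value <- rlang::enquo(value); group <- rlang::enquo(group)
  y <- rlang::eval_tidy(value, data)
  g <- as.factor(rlang::eval_tidy(group, data))
  keep <- is.finite(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(g[keep])
  sizes <- table(g)
  if (length(sizes) < 2) stop("one_way_anova needs at least 2 groups", call. = FALSE)
  if (any(sizes < 2)) {
    stop(sprintf("group '%s' has fewer than 2 values", names(sizes)[sizes < 2][1]),
         call. = FALSE)
  }
  gm <- tapply(y, g, mean)
  if (max(gm) - min(gm) == 0) {
    # identical group means: F = 0 exactly, no evidence of any difference
    f_stat <- 0; p <- 1
  } else {
    ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
    f_stat <- unname(ow$statistic); p <- ow$p.value
  }
  groups <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(y = y, g = g), g),
    n = dplyr::n(), mean = mean(y), sd = stats::sd(y), .groups = "drop")
  names(groups)[1] <- "group"
  structure(list(factor = rlang::as_name(group),
                 f_statistic = f_stat, p_value = p,
                 df_between = length(sizes) - 1L,
                 df_within = length(y) - length(sizes),
                 groups = groups),
            class = "sway_anova")
}

#' @export
print.sway_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA on %s: F(%d, %d) = %.4g, p = %.3g\n",
              x$factor, x$df_between, x$df_within, x$f_statistic, x$p_value))
  print(x$groups)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sway_anova <- function(x, ...) x$groups

#' @exportS3Method generics::glance
glance.sway_anova <- function(x, ...) {
  tibble::tibble(factor = x$factor, f_statistic = x$f_statistic,
                 p_value = x$p_value, df_between = x$df_between,
                 df_within = x$df_within)
}
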