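# CoP trajectory container: a tibble (time, x_ap, y_ml) with metadata
# attributes. Kept as a plain tibble subclass so dplyr verbs keep working.

new_cop_trajectory <- function(time, x_ap, y_ml, rate,
                               device = "truth", trial_id = NA_character_) {
  out <- tibble::tibble(time = as.numeric(time),
                        x_ap = as.numeric(x_ap),
                        y_ml = as.numeric(y_ml))
  attr(out, "rate") <- rate
  attr(out, "device") <- device
  attr(out, "trial_id") <- trial_id
  class(out) <- c("cop_trajectory", class(out))
  out
}

validate_trajectory <- function(traj, min_samples = 2L) {
  if (!is.data.frame(traj) || !all(c("x_ap", "y_ml") %in% names(traj))) {
    stop("expected a CoP trajectory with x_ap and y_ml columns", call. = FALSE)
  }
  if (nrow(traj) < min_samples) {
    stop(sprintf("trajectory has %d samples; at least %d required",
                 nrow(traj), min_samples), call. = FALSE)
  }
  if (any(!is.finite(traj$x_ap)) || any(!is.finite(traj$y_ml))) {
    stop("trajectory contains non-finite coordinates", call. = FALSE)
  }
  invisible(traj)
}

#' @export
print.cop_trajectory <- function(x, ...) {
  cat(sprintf("<cop_trajectory> device=%s rate=%s Hz n=%d\n",
              attr(x, "device") %||% "?",
              format(attr(x, "rate") %||% NA), nrow(x)))
  NextMethod()
}

#' Plot a CoP trajectory with its 95% confidence ellipse
#'
#' @param object A `cop_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cop_trajectory <- function(object, ...) {
  el <- ellipse_outline(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$y_ml, y = .data$x_ap)) +
    ggplot2::geom_path(alpha = 0.6, colour = "grey30") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "ML (cm, left +)", y = "AP (cm, cranial +)",
                  title = sprintf("CoP trajectory (%s)", attr(object, "device") %||% ""))
  if (!is.null(el)) {
    p <- p + ggplot2::geom_path(data = el, ggplot2::aes(x = .data$y_ml, y = .data$x_ap),
                                colour = "firebrick", linewidth = 0.7)
  }
  p
}

# 95% covariance-ellipse outline for plotting; NULL when degenerate.
ellipse_outline <- function(traj, q = 5.991, n_points = 181L) {
  if (nrow(traj) < 3) return(NULL)
  cv <- stats::cov(cbind(traj$x_ap, traj$y_ml))
  eg <- eigen(cv, symmetric = TRUE)
  if (any(eg$values <= 0)) return(NULL)
  th <- seq(0, 2 * pi, length.out = n_points)
  circ <- rbind(sqrt(q * eg$values[1]) * cos(th), sqrt(q * eg$values[2]) * sin(th))
  pts <- t(eg$vectors %*% circ)
  tibble::tibble(x_ap = pts[, 1] + mean(traj$x_ap),
                 y_ml = pts[, 2] + mean(traj$y_ml))
}
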