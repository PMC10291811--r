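# Naive reference implementations and small fixture builders. The oracles
# deliberately use direct loops / first-principles formulas, independent of
# the package's vectorised code paths.

make_traj <- function(x, y, rate = 100) {
  pawsway:::new_cop_trajectory(time = (seq_along(x) - 1) / rate,
                               x_ap = x, y_ml = y, rate = rate)
}

random_traj <- function(n, scale = 1, rate = 100) {
  make_traj(stats::rnorm(n, 0, scale), stats::rnorm(n, 0, scale), rate = rate)
}

naive_ap_range <- function(traj) max(traj$x_ap) - min(traj$x_ap)
naive_ml_range <- function(traj) max(traj$y_ml) - min(traj$y_ml)

naive_sway_path <- function(traj) {
  total <- 0
  for (i in 2:nrow(traj)) {
    total <- total + sqrt((traj$x_ap[i] - traj$x_ap[i - 1])^2 +
                            (traj$y_ml[i] - traj$y_ml[i - 1])^2)
  }
  total
}

# covariance ellipse from explicit scalar formulas (no eigen())
naive_ellipse_area <- function(traj, q = qchisq(0.95, 2)) {
  x <- traj$x_ap; y <- traj$y_ml; n <- length(x)
  sxx <- sum((x - mean(x))^2) / (n - 1)
  syy <- sum((y - mean(y))^2) / (n - 1)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  det <- sxx * syy - sxy^2
  if (det <= 0) return(0)
  pi * q * sqrt(det)
}

# machine-precision agreement bound for two independent ellipse-area
# routes: 1e-12 relative to the well-conditioned covariance scale
# (the determinant itself cancels catastrophically when points are nearly
# collinear, where no pair of implementations can pin 1e-12 of the area)
ellipse_match_bound <- function(traj, q = qchisq(0.95, 2)) {
  sxx <- var(traj$x_ap); syy <- var(traj$y_ml)
  1e-12 * max(1, pi * q * sqrt(sxx * syy))
}

# brute-force search over the load-share simplex at a fixed resolution:
# keep grid points satisfying the centroid constraint to tolerance, return
# the one closest to the nominal shares
brute_force_shares <- function(cop, geometry, res = 0.01, tol = 0.02) {
  pc <- geometry$paw_centres
  s0 <- geometry$nominal_shares
  grid <- seq(0, 1, by = res)
  best <- NULL; best_d <- Inf
  for (s1 in grid) for (s2 in grid) {
    if (s1 + s2 > 1) next
    rem <- 1 - s1 - s2
    for (s3 in grid[grid <= rem + 1e-9]) {
      s4 <- rem - s3
      s <- c(s1, s2, s3, s4)
      cx <- sum(s * pc[, 1]); cy <- sum(s * pc[, 2])
      if (abs(cx - cop[1]) > tol || abs(cy - cop[2]) > tol) next
      d <- sum((s - s0)^2)
      if (d < best_d) { best_d <- d; best <- s }
    }
  }
  best
}

quick_sway_params <- function(seed = NULL, duration = 2, ...) {
  sway_model_params(duration = duration, seed = seed, ...)
}
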