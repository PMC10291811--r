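#' Distribute body load over the four paws for a given CoP
#'
#' Finds the four non-negative load fractions that sum to one, place the
#' load-weighted centroid of the paw centres at the requested CoP, and among
#' all feasible solutions lie closest (least squares) to the stance's nominal
#' shares. The three equality constraints leave a single degree of freedom,
#' so the solution is the exact projection of the nominal shares onto a line
#' segment inside the simplex -- computed in closed form, and vectorised over
#' a whole trajectory of CoP points.
#'
#' @param cop A length-2 numeric `c(x_ap, y_ml)` or an n x 2 matrix /
#'   data frame of CoP points (cm). Must lie inside the convex hull of the
#'   paw centres.
#' @param geometry A [stance_geometry()].
#' @return For a single point, a length-4 named vector of fractions; for n
#'   points, an n x 4 matrix (rows sum to 1).
#' @export
#' @examples
#' g <- stance_geometry(nominal_shares = rep(0.25, 4))
#' solve_paw_shares(c(0, 0), g)
solve_paw_shares <- function(cop, geometry = stance_geometry()) {
  single <- is.null(dim(cop)) && length(cop) == 2L
  pts <- if (single) matrix(as.numeric(cop), 1L) else as.matrix(cop)[, 1:2, drop = FALSE]
  if (any(!is.finite(pts))) stop("CoP coordinates must be finite", call. = FALSE)
  pc <- geometry$paw_centres
  s0 <- geometry$nominal_shares

  # constraints A s = b(cop): sum, x-centroid, y-centroid
  A <- rbind(rep(1, 4), pc[, 1], pc[, 2])
  sv <- svd(A, nu = 3, nv = 4)
  if (sum(sv$d > max(sv$d) * 1e-10) < 3L) {
    stop("degenerate stance: paw centres do not span the plane", call. = FALSE)
  }
  d <- sv$v[, 4]                         # null-space direction
  Ainv <- sv$v[, 1:3] %*% diag(1 / sv$d) %*% t(sv$u)  # pseudo-inverse

  b <- rbind(1, t(pts))                  # 3 x n
  sp <- Ainv %*% b                       # particular solutions, 4 x n
  t_star <- as.numeric(crossprod(d, s0 - sp))  # unconstrained optimum (||d|| = 1)

  # feasibility interval for s = sp + t d >= 0
  lo <- rep(-Inf, ncol(sp)); hi <- rep(Inf, ncol(sp))
  for (i in 1:4) {
    r <- -sp[i, ] / d[i]
    if (d[i] > 0) lo <- pmax(lo, r) else if (d[i] < 0) hi <- pmin(hi, r)
    else if (any(sp[i, ] < -1e-12)) {
      bad <- which(sp[i, ] < -1e-12)[1]
      stop(sprintf("CoP point %d lies outside the support polygon of the paws", bad),
           call. = FALSE)
    }
  }
  tol <- 1e-9
  infeas <- lo > hi + tol
  if (any(infeas)) {
    stop(sprintf("CoP point %d lies outside the support polygon of the paws",
                 which(infeas)[1]), call. = FALSE)
  }
  tt <- pmin(pmax(t_star, lo), hi)
  shares <- sp + outer(d, tt)
  shares[shares < 0 & shares > -tol] <- 0
  if (single) {
    out <- shares[, 1]
    names(out) <- rownames(pc)
    out
  } else {
    out <- t(shares)
    colnames(out) <- rownames(pc)
    out
  }
}
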