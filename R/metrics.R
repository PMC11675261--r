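#' Metric fields
#'
#' A `metric_field` is a per-pixel metric definition evaluable on tangent
#' vectors. Kinds:
#' \describe{
#'   \item{isotropic}{`F_x(u) = speed(x) * |u|`.}
#'   \item{riemannian}{`F_x(u) = sqrt(u' M(x) u)` with a symmetric positive
#'     definite tensor `M`.}
#'   \item{asymmetric_quadratic}{`F_x(u) = sqrt(u' M(x) u + max(0, <w(x), u>)^2)`.}
#'   \item{elastica_cost}{an orientation-dependent scalar cost
#'     `phi(x, theta)` used by the curvature-penalized solver.}
#' }
#' @name metric_field
NULL

new_metric_field <- function(kind, grid, ...) {
  structure(c(list(kind = kind, grid = grid), list(...)),
            class = "metric_field")
}

#' @export
print.metric_field <- function(x, ...) {
  cat(sprintf("<metric_field %s, %d x %d>\n", x$kind,
              x$grid$shape[1], x$grid$shape[2]))
  invisible(x)
}

#' Uniform or spatially varying isotropic metric
#'
#' @param grid an [image_grid()].
#' @param speed positive scalar or matrix: the per-pixel cost multiplier, so
#'   a constant `speed = c` yields distances `c` times Euclidean.
#' @return an isotropic `metric_field`.
#' @export
isotropic_metric <- function(grid, speed = 1) {
  nr <- grid$shape[[1]]; nc <- grid$shape[[2]]
  if (length(speed) == 1L) speed <- matrix(speed, nr, nc)
  if (any(speed <= 0)) stop("speed must be positive everywhere")
  new_metric_field("isotropic", grid, speed = speed)
}

#' Riemannian edge-adherence metric
#'
#' Builds the tensor field `M(x) = t t' + exp(mu * fhat(x)) r r'` from edge
#' features: unit cost along the edge tangent `t`, and a cost growing
#' exponentially with edge strength for motion along `r` (towards/across the
#' nearest edge). Where the direction field is undefined the tensor falls
#' back to the identity (there `fhat` is negligible, so the two agree).
#'
#' @param feat an [compute_edge_features()] result.
#' @param mu positive exponential contrast weight.
#' @return a riemannian `metric_field`.
#' @export
build_riemannian_metric <- function(feat, mu) {
  stopifnot(inherits(feat, "edge_features"))
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0)
    stop("mu must be a single positive number")
  a <- exp(mu * feat$fhat) - 1      # M = I + a * r r'
  Mrr <- 1 + a * feat$rr^2
  Mrc <- a * feat$rr * feat$rc
  Mcc <- 1 + a * feat$rc^2
  new_metric_field("riemannian", feat$grid, Mrr = Mrr, Mrc = Mrc, Mcc = Mcc,
                   mu = mu)
}

#' Asymmetric quadratic metric pair
#'
#' Builds the two mutually reversed Finsler metrics used to trace voting
#' paths in the two rotational senses. Both share the tensor
#' `M(x) = ct(x)^2 t t' + r r'` with `ct = exp(-mu * fhat)` (cheap motion
#' along edge tangents), and differ by the sign of the asymmetric vector:
#' `w0 = eta * fhat * t`, `w1 = -w0`. Evaluation is
#' `F_x(u) = sqrt(u' M u + max(0, <w, u>)^2)`.
#'
#' @param feat an [compute_edge_features()] result.
#' @param mu positive exponential contrast weight.
#' @param eta asymmetry weight, >= 0; `eta = 0` gives a symmetric pair.
#' @return list of two asymmetric_quadratic `metric_field`s `(aq0, aq1)`.
#' @export
build_aq_metrics <- function(feat, mu, eta) {
  stopifnot(inherits(feat, "edge_features"))
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0)
    stop("mu must be a single positive number")
  if (!is.numeric(eta) || length(eta) != 1L || eta < 0)
    stop("eta must be a single number >= 0")
  ct2 <- exp(-2 * mu * feat$fhat)
  # M = ct^2 t t' + r r'; where directions are undefined fhat ~ 0 => M ~ I
  Mrr <- ct2 * feat$tr_^2 + feat$rr^2
  Mrc <- ct2 * feat$tr_ * feat$tc + feat$rr * feat$rc
  Mcc <- ct2 * feat$tc^2 + feat$rc^2
  und <- !feat$defined
  Mrr[und] <- 1; Mrc[und] <- 0; Mcc[und] <- 1
  w0r <- eta * feat$fhat * feat$tr_
  w0c <- eta * feat$fhat * feat$tc
  aq0 <- new_metric_field("asymmetric_quadratic", feat$grid,
                          Mrr = Mrr, Mrc = Mrc, Mcc = Mcc,
                          wr = w0r, wc = w0c, mu = mu, eta = eta)
  aq1 <- new_metric_field("asymmetric_quadratic", feat$grid,
                          Mrr = Mrr, Mrc = Mrc, Mcc = Mcc,
                          wr = -w0r, wc = -w0c, mu = mu, eta = eta)
  list(aq0 = aq0, aq1 = aq1)
}

#' Orientation-dependent elastica cost
#'
#' The cost `phi(x, theta) = exp(-mu * g(x, theta) / max g)` with
#' `g(x, theta) = <n_theta, W(x) n_theta>`, where `theta` labels the travel
#' direction `v(theta) = (-sin, cos)` and `n_theta` is its perpendicular:
#' traveling along an edge tangent puts `n_theta` on the gradient direction,
#' maximizing `g` and minimizing the cost. `g` is normalized by its global
#' maximum over all pixels and orientations so that `phi` lies in
#' `(exp(-mu), 1]` (identically 1 for a flat image).
#'
#' @param feat an [compute_edge_features()] result.
#' @param mu positive exponential contrast weight.
#' @param n_angles number of orientation bins (>= 16).
#' @return an elastica_cost `metric_field` with a `(rows, cols, n_angles)`
#'   `cost_by_angle` array.
#' @export
build_elastica_cost <- function(feat, mu, n_angles = 64L) {
  stopifnot(inherits(feat, "edge_features"))
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0)
    stop("mu must be a single positive number")
  n_angles <- as.integer(n_angles)
  if (n_angles < 16L) stop("n_angles must be >= 16")
  nr <- feat$grid$shape[[1]]; nc <- feat$grid$shape[[2]]
  th <- 2 * pi * (seq_len(n_angles) - 1L) / n_angles
  g <- array(0, dim = c(nr, nc, n_angles))
  for (i in seq_len(n_angles)) {
    s <- sin(th[i]); co <- cos(th[i])   # n_theta = perp(v) = (-co, -s)
    g[, , i] <- co^2 * feat$Wrr + 2 * s * co * feat$Wrc + s^2 * feat$Wcc
  }
  gmax <- max(g)
  phi <- if (gmax <= 1e-14) array(1, dim = dim(g)) else exp(-mu * g / gmax)
  new_metric_field("elastica_cost", feat$grid, cost_by_angle = phi,
                   angles = th, mu = mu, n_angles = n_angles)
}

#' Evaluate a metric on a tangent vector
#'
#' Direct evaluation of `F_x(u)` at a pixel, mainly for verification: the
#' solvers evaluate metrics internally.
#'
#' @param metric a `metric_field` (not elastica_cost).
#' @param x pixel (row, col), 1-based.
#' @param u tangent vector (drow, dcol).
#' @return the positive scalar `F_x(u)` (0 iff `u = 0`).
#' @export
metric_eval <- function(metric, x, u) {
  r <- x[1]; c <- x[2]
  if (metric$kind == "isotropic")
    return(metric$speed[r, c] * sqrt(sum(u^2)))
  if (metric$kind == "elastica_cost")
    stop("elastica costs are evaluated on lifted states, not tangents")
  q <- u[1] * (metric$Mrr[r, c] * u[1] + metric$Mrc[r, c] * u[2]) +
       u[2] * (metric$Mrc[r, c] * u[1] + metric$Mcc[r, c] * u[2])
  if (metric$kind == "asymmetric_quadratic") {
    s <- metric$wr[r, c] * u[1] + metric$wc[r, c] * u[2]
    if (s > 0) q <- q + s^2
  }
  sqrt(max(q, 0))
}
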