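#' Curvature-penalized (elastica) distance on the orientation-lifted grid
#'
#' Solves for the minimal elastica energy
#' `int phi(x, theta) (1 + tau^2 kappa^2) ds` over lifted states
#' `(pixel, orientation bin)` by label-setting on motion primitives: each
#' primitive is a primitive integer move within Chebyshev radius 2 whose
#' terminal orientation is the move's own angle snapped to the nearest bin;
#' its curvature is the wrapped orientation change divided by the move
#' length, so the primitive energy is exactly
#' `phi_mid * len * (1 + tau^2 kappa^2)`.
#'
#' @param cost an elastica_cost `metric_field` from [build_elastica_cost()]
#'   (at least 16 orientation bins).
#' @param tau positive curvature weight (pixels): the turning radius below
#'   which curvature dominates the length term.
#' @param source source pixel (row, col), 1-based.
#' @param source_angles "all" (free initial orientation) or an integer
#'   vector of 1-based orientation bin indices.
#' @param obstacles optional obstacle mask.
#' @return a `lifted_distance` object with fields `values`
#'   (`rows x cols x n_angles` array), `pred`, `cost`, `tau`, `grid`.
#' @export
elastica_distance <- function(cost, tau, source, source_angles = "all",
                              obstacles = NULL) {
  stopifnot(inherits(cost, "metric_field"), cost$kind == "elastica_cost")
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("tau must be a single positive number")
  nA <- cost$n_angles
  if (nA < 16L) stop("n_angles must be >= 16")
  grid <- cost$grid
  nr <- grid$shape[[1]]; nc <- grid$shape[[2]]
  src <- as_pixel_matrix(source)
  if (!all(in_grid(src, grid))) stop("source outside the grid")
  abins <- if (identical(source_angles, "all")) seq_len(nA)
           else as.integer(source_angles)
  if (any(abins < 1L | abins > nA)) stop("invalid source angle bins")
  states <- cbind(rep(src[, 1], each = length(abins)) - 1L,
                  rep(src[, 2], each = length(abins)) - 1L,
                  rep(abins, times = nrow(src)) - 1L)
  obs <- prepare_obstacle(obstacles, nr, nc)
  res <- cpp_solve_lifted(nr, nc, nA, as.numeric(cost$cost_by_angle), tau,
                          states, obs, 2L)
  structure(list(values = array(res$dist, dim = c(nr, nc, nA)),
                 pred = res$pred, cost = cost, tau = tau, grid = grid,
                 source = src),
            class = "lifted_distance")
}

#' @export
print.lifted_distance <- function(x, ...) {
  cat(sprintf("<lifted_distance %d x %d x %d bins, tau = %g>\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3], x$tau))
  invisible(x)
}

# Backtrack the lifted predecessor chain ending at state (r, c, a) (1-based)
# and project onto the image plane.
backtrack_lifted <- function(ld, r, c, a) {
  nr <- ld$grid$shape[[1]]; nc <- ld$grid$shape[[2]]
  npix <- nr * nc
  idx <- (r - 1L) + nr * (c - 1L) + npix * (a - 1L)  # 0-based
  if (!is.finite(ld$values[r, c, a]))
    stop(sprintf("endpoint (%d, %d) unreachable in the lifted domain", r, c))
  chain <- integer(0)
  repeat {
    chain <- c(chain, idx)
    p <- ld$pred[idx + 1L]
    if (p < 0L) break
    idx <- p
    if (length(chain) > length(ld$pred)) stop("predecessor cycle detected")
  }
  pix <- chain %% npix
  rc <- cbind(pix %% nr + 1L, pix %/% nr + 1L)
  rc <- rc[rev(seq_len(nrow(rc))), , drop = FALSE]
  list(points = rc, angles = rev(chain %/% npix) + 1L,
       value = ld$values[r, c, a])
}

best_angle <- function(ld, r, c) {
  v <- ld$values[r, c, ]
  if (!any(is.finite(v))) stop(sprintf("pixel (%d, %d) unreachable", r, c))
  which.min(v)  # first minimum: deterministic
}

#' Elastica minimal path between two pixels
#'
#' Backtracks the curvature-penalized minimal path from `start` to `end`,
#' with free orientation at both ends (minimum over terminal bins).
#'
#' @param cost elastica_cost `metric_field`.
#' @param tau positive curvature weight.
#' @param start,end pixels (row, col), distinct.
#' @param source_angles as in [elastica_distance()].
#' @param obstacles optional obstacle mask.
#' @return a [discrete_path()] with `metric_length` the lifted distance.
#' @export
elastica_path_to_point <- function(cost, tau, start, end,
                                   source_angles = "all", obstacles = NULL) {
  if (all(start == end)) stop("start and end must differ")
  ld <- elastica_distance(cost, tau, start, source_angles, obstacles)
  a <- best_angle(ld, end[1], end[2])
  bt <- backtrack_lifted(ld, end[1], end[2], a)
  discrete_path(subdivide_points(bt$points), metric_length = bt$value)
}

#' Elastica minimal path to the domain boundary
#'
#' Finds the boundary pixel minimizing the lifted distance (minimum over
#' orientation bins; ties broken lexicographically) and backtracks the path
#' to it.
#'
#' @param cost elastica_cost `metric_field`.
#' @param tau positive curvature weight.
#' @param start interior pixel (row, col), not on the boundary ring.
#' @param source_angles as in [elastica_distance()].
#' @param obstacles optional obstacle mask.
#' @return a [discrete_path()] from `start` to the arg-min boundary pixel.
#' @export
elastica_path_to_boundary <- function(cost, tau, start,
                                      source_angles = "all",
                                      obstacles = NULL) {
  grid <- cost$grid
  bd <- grid_boundary(grid)
  on_bd <- start[1] == 1 | start[1] == grid$shape[[1]] |
           start[2] == 1 | start[2] == grid$shape[[2]]
  if (on_bd) stop("start must not lie on the domain boundary")
  ld <- elastica_distance(cost, tau, start, source_angles, obstacles)
  vals <- apply(ld$values, c(1, 2), min)  # min over orientation
  bvals <- vals[cbind(bd[, 1], bd[, 2])]
  if (!any(is.finite(bvals))) stop("no boundary pixel is reachable")
  k <- which.min(bvals)                   # bd is in lexicographic order
  a <- best_angle(ld, bd[k, 1], bd[k, 2])
  bt <- backtrack_lifted(ld, bd[k, 1], bd[k, 2], a)
  discrete_path(subdivide_points(bt$points), metric_length = bt$value)
}

# Re-integrate the elastica energy of a lifted backtracked chain; used by
# tests and the cut-optimality check. pts: integer chain (no subdivision),
# ang: matching 1-based bins.
elastica_energy_of_chain <- function(cost, tau, pts, ang) {
  nA <- cost$n_angles
  abin <- 2 * pi / nA
  e <- 0
  for (i in seq_len(nrow(pts) - 1L)) {
    d <- pts[i + 1L, ] - pts[i, ]
    len <- sqrt(sum(d^2))
    dth <- (ang[i + 1L] - ang[i]) * abin
    while (dth > pi) dth <- dth - 2 * pi
    while (dth <= -pi) dth <- dth + 2 * pi
    kap <- dth / len
    thmid <- (ang[i] - 1L) * abin + dth / 2
    b <- (round(thmid / abin) %% nA) + 1L
    pmid <- 0.5 * (cost$cost_by_angle[pts[i, 1], pts[i, 2], b] +
                   cost$cost_by_angle[pts[i + 1L, 1], pts[i + 1L, 2], b])
    e <- e + pmid * len * (1 + tau^2 * kap^2)
  }
  e
}
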