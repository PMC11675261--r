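#' Solve the eikonal equation on a grid
#'
#' Computes the discrete geodesic distance from a source set under an
#' isotropic, Riemannian or asymmetric quadratic metric, by single-pass
#' label-setting (Dijkstra) on a grid graph connecting each pixel to all
#' primitive neighbours within Chebyshev radius `rho`. Edge weights are the
#' line integral of the metric along the move (midpoint quadrature over
#' unit-length pieces with bilinear field interpolation), one-sided in the
#' travel direction for asymmetric metrics; this keeps short and long moves
#' mutually consistent on varying fields. Obstacle pixels are removed from
#' the graph, and moves whose swept supercover touches an obstacle are
#' rejected, so no path can hop over or graze an obstacle set. Ties in the
#' priority queue are broken by lexicographic pixel order, so the result is
#' deterministic.
#'
#' @param metric a `metric_field` of kind isotropic, riemannian or
#'   asymmetric_quadratic.
#' @param sources integer matrix of (row, col) source pixels (1-based), or a
#'   single pixel as a length-2 vector.
#' @param obstacles optional [pixel_mask()] (or logical matrix) of excluded
#'   pixels.
#' @param track_euclidean if TRUE, also accumulate the Euclidean length of
#'   the realized discrete shortest path to each pixel.
#' @param rho stencil Chebyshev radius (default 3).
#' @return a `distance_map` object with fields `values` (distances, `Inf`
#'   where unreachable), `pred` (predecessor pixel linear indices, the
#'   geodesic flow), `eu` (Euclidean companion lengths or NULL), `sources`,
#'   `metric_kind`, `grid`.
#' @export
solve_eikonal <- function(metric, sources, obstacles = NULL,
                          track_euclidean = FALSE, rho = 3L) {
  stopifnot(inherits(metric, "metric_field"))
  if (metric$kind == "elastica_cost")
    stop("use elastica_distance() for curvature-penalized metrics")
  grid <- metric$grid
  nr <- grid$shape[[1]]; nc <- grid$shape[[2]]
  sources <- as_pixel_matrix(sources)
  if (!all(in_grid(sources, grid))) stop("source pixel outside the grid")
  obs <- prepare_obstacle(obstacles, nr, nc)
  if (length(obs) && all(obs)) stop("all pixels are obstructed")

  z <- matrix(0, 0, 0)
  args <- switch(metric$kind,
    isotropic = list(kind = 0L, speed = metric$speed,
                     mrr = numeric(0), mrc = numeric(0), mcc = numeric(0),
                     wr = numeric(0), wc = numeric(0)),
    riemannian = list(kind = 1L, speed = numeric(0),
                      mrr = metric$Mrr, mrc = metric$Mrc, mcc = metric$Mcc,
                      wr = numeric(0), wc = numeric(0)),
    asymmetric_quadratic = list(kind = 2L, speed = numeric(0),
                                mrr = metric$Mrr, mrc = metric$Mrc,
                                mcc = metric$Mcc,
                                wr = metric$wr, wc = metric$wc))
  res <- cpp_solve_grid(nr, nc, args$kind,
                        as.numeric(args$speed), as.numeric(args$mrr),
                        as.numeric(args$mrc), as.numeric(args$mcc),
                        as.numeric(args$wr), as.numeric(args$wc),
                        sources - 1L, obs, as.integer(rho),
                        isTRUE(track_euclidean))
  structure(list(values = matrix(res$dist, nr, nc),
                 pred = res$pred,          # 0-based linear, -1 at sources
                 eu = if (track_euclidean) matrix(res$eu, nr, nc) else NULL,
                 sources = sources, metric_kind = metric$kind, grid = grid),
            class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  fin <- is.finite(x$values)
  cat(sprintf("<distance_map %s, %d x %d, %d sources, max %.3f>\n",
              x$metric_kind, nrow(x$values), ncol(x$values),
              nrow(x$sources), max(x$values[fin])))
  invisible(x)
}

as_pixel_matrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, 1L, 2L)
  p <- as.matrix(p)
  storage.mode(p) <- "integer"
  if (ncol(p) != 2L) stop("pixels must be (row, col) pairs")
  p
}

prepare_obstacle <- function(obstacles, nr, nc) {
  if (is.null(obstacles)) return(logical(0))
  m <- as.matrix(obstacles)
  if (!identical(dim(m), c(nr, nc))) stop("obstacle mask shape mismatch")
  as.logical(m)
}

#' Backtrack a geodesic from a distance map
#'
#' Follows the predecessor chain from `endpoint` down to a source pixel and
#' returns the path ordered source -> endpoint. The distance value is
#' strictly decreasing along the chain towards the source, and the path
#' never enters obstacle pixels (they were removed from the graph).
#'
#' @param dist a `distance_map` from [solve_eikonal()].
#' @param endpoint pixel (row, col), 1-based; must have a finite distance.
#' @return a [discrete_path()] from a source to `endpoint`, with
#'   `metric_length` set to the distance value at `endpoint`.
#' @export
backtrack_geodesic <- function(dist, endpoint) {
  nr <- nrow(dist$values)
  ep <- as.integer(endpoint)
  if (!is.finite(dist$values[ep[1], ep[2]]))
    stop(sprintf("endpoint (%d, %d) is unreachable", ep[1], ep[2]))
  idx <- (ep[1] - 1L) + nr * (ep[2] - 1L)          # 0-based linear
  chain <- integer(0)
  repeat {
    chain <- c(chain, idx)
    p <- dist$pred[idx + 1L]
    if (p < 0L) break
    idx <- p
    if (length(chain) > length(dist$pred)) stop("predecessor cycle detected")
  }
  rc <- cbind(chain %% nr + 1L, chain %/% nr + 1L)
  rc <- rc[rev(seq_len(nrow(rc))), , drop = FALSE]  # source -> endpoint
  if (nrow(rc) == 1L) rc <- rbind(rc, rc)           # endpoint is a source
  discrete_path(subdivide_points(rc),
                metric_length = dist$values[ep[1], ep[2]])
}
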