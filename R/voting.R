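#' Farthest point sampling of voting endpoints
#'
#' Iteratively selects the pixel maximizing the geodesic distance to the
#' already selected set, starting from a seed set (here: the union of all
#' rasterized cuts), until `K` points are chosen. Ties are broken by
#' lexicographic (row, col) order. The default metric is uniform
#' (Euclidean-like on the stencil graph); an isotropic `metric_field` may
#' be supplied for edge-weighted sampling.
#'
#' @param grid an [image_grid()].
#' @param seed integer matrix of (row, col) seed pixels (nonempty).
#' @param K number of endpoints to sample (>= 1).
#' @param metric optional isotropic `metric_field`.
#' @param rho stencil radius.
#' @return an `endpoint_set` with fields `points` (K x 2), `seed`,
#'   `dist_at_selection` (non-increasing in k).
#' @export
farthest_point_sampling <- function(grid, seed, K, metric = NULL, rho = 3L) {
  seed <- as_pixel_matrix(seed)
  if (nrow(seed) == 0L) stop("seed set must be nonempty")
  if (!all(in_grid(seed, grid))) stop("seed pixel outside the grid")
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  nr <- grid$shape[[1]]; nc <- grid$shape[[2]]
  speed <- if (is.null(metric)) matrix(1, nr, nc) else {
    stopifnot(metric$kind == "isotropic")
    metric$speed
  }
  res <- cpp_fps(nr, nc, as.numeric(speed), seed - 1L, K, as.integer(rho),
                 logical(0))
  structure(list(points = res$points + 1L, seed = seed,
                 dist_at_selection = res$dist),
            class = "endpoint_set")
}

#' @export
print.endpoint_set <- function(x, ...) {
  cat(sprintf("<endpoint_set: K = %d, seeded by %d pixels>\n",
              nrow(x$points), nrow(x$seed)))
  invisible(x)
}

#' Competition-selected voting paths for one cut
#'
#' From each of the cut's two offset source points, geodesic distance maps
#' are solved under both asymmetric quadratic metrics with the cut barrier
#' as an obstacle (paths may neither cross nor touch the cut). For every
#' endpoint the cheaper metric wins -- strictly cheaper selects the
#' reversed-orientation metric, ties select the first -- and the winning
#' geodesic is backtracked. Endpoints on the barrier are skipped with a
#' warning; endpoints walled off from an offset are dropped and counted.
#'
#' @param cut an `adaptive_cut`.
#' @param aq list `(aq0, aq1)` from [build_aq_metrics()].
#' @param endpoints an `endpoint_set`.
#' @param independent_sides if TRUE (default) the left side selects by its
#'   own distance pair; otherwise it reuses the right side's selection map.
#' @return list with `paths` (list of [discrete_path()], right side then
#'   left side), `side` ("r"/"l" per path), `selected` (0 or 1: winning
#'   metric per path), `n_dropped`, `n_skipped`.
#' @export
competition_voting_paths <- function(cut, aq, endpoints,
                                     independent_sides = TRUE) {
  stopifnot(inherits(cut, "adaptive_cut"), inherits(endpoints, "endpoint_set"))
  grid <- aq$aq0$grid
  q <- endpoints$points
  on_barrier <- cut$barrier[cbind(q[, 1], q[, 2])]
  if (any(on_barrier))
    warning(sprintf("%d endpoint(s) on this cut's barrier were skipped",
                    sum(on_barrier)))
  q <- q[!on_barrier, , drop = FALSE]

  solve_side <- function(src) {
    list(d0 = solve_eikonal(aq$aq0, src, obstacles = cut$barrier),
         d1 = solve_eikonal(aq$aq1, src, obstacles = cut$barrier))
  }
  side_r <- solve_side(cut$offset_r)
  side_l <- solve_side(cut$offset_l)

  paths <- list(); side <- character(0); selected <- integer(0)
  n_dropped <- 0L
  for (s in c("r", "l")) {
    maps <- if (s == "r") side_r else side_l
    sel_maps <- if (s == "l" && !independent_sides) side_r else maps
    for (k in seq_len(nrow(q))) {
      v0 <- sel_maps$d0$values[q[k, 1], q[k, 2]]
      v1 <- sel_maps$d1$values[q[k, 1], q[k, 2]]
      if (!is.finite(maps$d0$values[q[k, 1], q[k, 2]]) &&
          !is.finite(maps$d1$values[q[k, 1], q[k, 2]])) {
        n_dropped <- n_dropped + 1L
        next
      }
      use1 <- is.finite(v1) && (!is.finite(v0) || v1 < v0)
      dm <- if (use1) maps$d1 else maps$d0
      if (!is.finite(dm$values[q[k, 1], q[k, 2]])) {
        dm <- if (use1) maps$d0 else maps$d1   # winner unreachable: other map
        use1 <- !use1
      }
      paths[[length(paths) + 1L]] <- backtrack_geodesic(dm, q[k, ])
      side <- c(side, s)
      selected <- c(selected, as.integer(use1))
    }
  }
  list(paths = paths, side = side, selected = selected,
       n_dropped = n_dropped, n_skipped = sum(on_barrier),
       endpoints_used = q)
}

#' Accumulate voting scores
#'
#' Counts, per pixel, how many selected voting paths cover it: each source's
#' paths are supercover-rasterized and summed into that source's integer
#' field `Vj`; the total map is `V = sum_j Vj`.
#'
#' @param paths_by_source list over sources; each element a list of
#'   [discrete_path()]s (e.g. the `paths` field of
#'   [competition_voting_paths()]).
#' @param grid an [image_grid()].
#' @return a `voting_score` object with `per_source` (list of integer
#'   matrices), `total`, `n_paths` (total path count).
#' @export
accumulate_votes <- function(paths_by_source, grid) {
  if (!length(paths_by_source) || !any(lengths(paths_by_source) > 0))
    stop("at least one source with at least one path is required")
  nr <- grid$shape[[1]]; nc <- grid$shape[[2]]
  per_source <- vector("list", length(paths_by_source))
  total <- matrix(0L, nr, nc)
  n_paths <- 0L
  for (j in seq_along(paths_by_source)) {
    Vj <- matrix(0L, nr, nc)
    for (p in paths_by_source[[j]]) {
      idx <- rasterize_indices(p$points, nr, nc)
      Vj[idx] <- Vj[idx] + 1L
      n_paths <- n_paths + 1L
    }
    per_source[[j]] <- Vj
    total <- total + Vj
  }
  structure(list(per_source = per_source, total = total, n_paths = n_paths,
                 grid = grid),
            class = "voting_score")
}

#' @export
print.voting_score <- function(x, ...) {
  cat(sprintf("<voting_score: %d sources, %d paths, max vote %d>\n",
              length(x$per_source), x$n_paths, max(x$total)))
  invisible(x)
}

#' Flow-consistency filter for path pairs
#'
#' Optional validity check for the pairwise voting branch: a pair of
#' geodesics meeting at an endpoint forms a valid closed contour only if
#' their terminal tangents are close to antiparallel, i.e. the cosine of
#' their terminal directions is below a threshold `zeta` in `[-1, 0)`.
#'
#' @param pairs list of lists with elements `g0`, `g1` (two
#'   [discrete_path()]s ending at the same endpoint) and optionally `qk`.
#' @param zeta cosine threshold in `[-1, 0)`; pairs with
#'   `T = cos(angle) < zeta` are kept.
#' @return list with `paths` (kept paths, both members of each kept pair),
#'   `T` (cosines per pair), `kept` (logical per pair).
#' @export
flow_consistency_filter <- function(pairs, zeta) {
  if (!is.numeric(zeta) || length(zeta) != 1L || zeta < -1 || zeta >= 0)
    stop("zeta must lie in [-1, 0)")
  Tv <- vapply(pairs, function(p) {
    sum(terminal_direction(p$g0) * terminal_direction(p$g1))
  }, numeric(1))
  kept <- Tv < zeta
  paths <- list()
  for (i in which(kept)) {
    paths[[length(paths) + 1L]] <- pairs[[i]]$g0
    paths[[length(paths) + 1L]] <- pairs[[i]]$g1
  }
  list(paths = paths, T = Tv, kept = kept)
}
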