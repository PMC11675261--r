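#' Adaptive cut through a landmark
#'
#' Builds the cut `C = C1 u C2` for one rectified landmark: `C1` is the
#' elastica minimal path from the center to the landmark, `C2` the elastica
#' minimal path from the landmark to the domain boundary; their
#' concatenation places the landmark at the middle index. The cut's barrier
#' mask is its supercover rasterization dilated by radius 1; the unit normal
#' at the landmark is the +90-degree rotation of the local cut tangent
#' (central difference over +/- 2 samples), and the two offset source
#' points sit at `-eps * N` (left) and `+eps * N` (right) of the landmark.
#'
#' @param center interior pixel (row, col).
#' @param pj rectified landmark pixel, distinct from `center`.
#' @param cost elastica_cost `metric_field`.
#' @param tau positive curvature weight.
#' @param epsilon offset magnitude in pixels (default 2, exceeding the
#'   barrier dilation radius 1).
#' @param continuity if TRUE, constrain the initial orientation of `C2` to
#'   continue the terminal orientation of `C1` at the landmark.
#' @return an `adaptive_cut` object with fields `path`, `barrier`,
#'   `normal`, `offset_l`, `offset_r`, `pj`, `center`, `epsilon`.
#' @export
build_cut <- function(center, pj, cost, tau, epsilon = 2,
                      continuity = FALSE) {
  grid <- cost$grid
  nr <- grid$shape[[1]]; nc <- grid$shape[[2]]
  center <- as.integer(center); pj <- as.integer(pj)
  if (center[1] <= 1L || center[1] >= nr || center[2] <= 1L || center[2] >= nc)
    stop("center must be strictly interior")
  if (all(center == pj)) stop("landmark coincides with the center")
  ld1 <- elastica_distance(cost, tau, center, "all")
  build_cut_from_center_map(ld1, pj, cost, tau, epsilon, continuity)
}

#' @export
print.adaptive_cut <- function(x, ...) {
  cat(sprintf(
    "<adaptive_cut through (%d, %d), %d path points, %d barrier pixels>\n",
    x$pj[1], x$pj[2], nrow(x$path$points), sum(x$barrier)))
  invisible(x)
}

# Central-difference tangent at index `mid`, widening the window if the
# difference degenerates (e.g. when the outward half initially retraces the
# inward half); final fallback: the supplied direction.
cut_tangent_at <- function(pts, mid, fallback) {
  n <- nrow(pts)
  for (w in 2:8) {
    i0 <- max(1L, mid - w); i1 <- min(n, mid + w)
    tg <- pts[i1, ] - pts[i0, ]
    len <- sqrt(sum(tg^2))
    if (is.finite(len) && len > 1e-9) return(tg / len)
  }
  fallback / sqrt(sum(fallback^2))
}

dilate_mask <- function(mask, radius) {
  kern <- EBImage::makeBrush(2L * radius + 1L, shape = "box")
  m <- as.matrix(EBImage::dilate(matrix(as.numeric(mask), nrow(mask)), kern))
  pixel_mask(m > 0.5, attr(mask, "grid"), role = attr(mask, "role"))
}

# Round each offset to a pixel; if it lands on the barrier (or outside),
# march outwards along the normal in half-pixel steps until off-barrier.
place_offsets <- function(pj, nj, epsilon, barrier, grid) {
  pick <- function(sgn) {
    for (s in seq(epsilon, epsilon + 12, by = 0.5)) {
      q <- round(pj + sgn * s * nj)
      if (q[1] < 1 || q[1] > grid$shape[[1]] ||
          q[2] < 1 || q[2] > grid$shape[[2]]) next
      if (!barrier[q[1], q[2]]) return(as.integer(q))
    }
    stop("could not place an offset source point off the barrier")
  }
  list(l = pick(-1), r = pick(+1))
}

#' Build all adaptive cuts
#'
#' One cut per rectified landmark, each independent of the others. The
#' center-based elastica distance is solved once and shared across cuts.
#'
#' @param landmarks a rectified [landmark_set()].
#' @param cost elastica_cost `metric_field`.
#' @param tau positive curvature weight.
#' @param epsilon offset magnitude in pixels.
#' @param continuity as in [build_cut()].
#' @return list of `adaptive_cut` objects, one per landmark, in order.
#' @export
build_all_cuts <- function(landmarks, cost, tau, epsilon = 2,
                           continuity = FALSE) {
  stopifnot(inherits(landmarks, "landmark_set"))
  pts <- landmarks$rectified_points
  if (is.null(pts)) stop("landmarks must be rectified before cut construction")
  if (anyDuplicated(pts))
    warning("identical rectified landmarks: duplicate cuts will be built")
  center <- landmarks$center
  grid <- cost$grid
  nr <- grid$shape[[1]]; nc <- grid$shape[[2]]

  ld1 <- elastica_distance(cost, tau, center, "all")
  cuts <- vector("list", nrow(pts))
  for (j in seq_len(nrow(pts))) {
    pj <- pts[j, ]
    res <- tryCatch(
      build_cut_from_center_map(ld1, pj, cost, tau, epsilon, continuity),
      error = function(e)
        stop(sprintf("cut construction failed for landmark %d: %s",
                     j, conditionMessage(e)), call. = FALSE))
    cuts[[j]] <- res
  }
  cuts
}

# Same as build_cut() but reusing the precomputed center lifted distance.
build_cut_from_center_map <- function(ld1, pj, cost, tau, epsilon,
                                      continuity) {
  grid <- cost$grid
  nr <- grid$shape[[1]]; nc <- grid$shape[[2]]
  pj <- as.integer(pj)
  a1 <- best_angle(ld1, pj[1], pj[2])
  bt1 <- backtrack_lifted(ld1, pj[1], pj[2], a1)
  c1 <- discrete_path(subdivide_points(bt1$points), metric_length = bt1$value)
  on_bd <- pj[1] == 1L || pj[1] == nr || pj[2] == 1L || pj[2] == nc
  if (on_bd) {
    path <- c1
  } else {
    src_ang <- if (continuity) a1 else "all"
    c2 <- elastica_path_to_boundary(cost, tau, pj, source_angles = src_ang)
    path <- concatenate_paths(c1, c2)
  }
  mid <- if (on_bd) nrow(path$points) else (nrow(path$points) + 1L) %/% 2L
  tg <- cut_tangent_at(path$points, mid, fallback = pj - ld1$source[1, ])
  nj <- c(-tg[2], tg[1])
  ras <- rasterize_path(path, grid)
  barrier <- dilate_mask(ras, 1L)
  off <- place_offsets(pj, nj, epsilon, barrier, grid)
  structure(list(path = path, barrier = barrier, normal = nj,
                 offset_l = off$l, offset_r = off$r,
                 offset_l_exact = pj - epsilon * nj,
                 offset_r_exact = pj + epsilon * nj,
                 pj = pj, center = ld1$source[1, ], epsilon = epsilon),
            class = "adaptive_cut")
}
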