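#' Discrete polyline path
#'
#' An ordered polyline of subpixel (row, col) points with its Euclidean
#' length and, optionally, a metric length. Consecutive points may be at
#' most 2 pixel units apart; dense chains coming from the solvers are
#' subdivided to satisfy this.
#'
#' @param points numeric matrix with columns (row, col), at least 2 rows.
#'   Vertices further than 2 pixel units apart are subdivided by midpoint
#'   insertion (which leaves the polyline geometry unchanged).
#' @param metric_length optional metric length of the path.
#' @return a `discrete_path` object with fields `points`,
#'   `euclidean_length`, `metric_length`.
#' @export
discrete_path <- function(points, metric_length = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 2L)
    stop("a path needs >= 2 (row, col) points")
  storage.mode(points) <- "double"
  if (any(segment_lengths(points) > 2))
    points <- subdivide_points(points, max_gap = 2)
  gaps <- segment_lengths(points)
  structure(list(points = points,
                 euclidean_length = sum(gaps),
                 metric_length = metric_length),
            class = "discrete_path")
}

segment_lengths <- function(points) {
  n <- nrow(points)
  if (n < 2L) return(numeric(0))
  sqrt(rowSums((points[-1, , drop = FALSE] - points[-n, , drop = FALSE])^2))
}

#' @export
print.discrete_path <- function(x, ...) {
  cat(sprintf("<discrete_path, %d points, euclidean length %.3f%s>\n",
              nrow(x$points), x$euclidean_length,
              if (is.null(x$metric_length)) ""
              else sprintf(", metric length %.3f", x$metric_length)))
  invisible(x)
}

# Insert midpoints into the longest segments (points stay on the polyline)
# until the path has exactly n points. Used to equalize part lengths before
# concatenation and to enforce the <= 2 px consecutive-gap invariant.
upsample_points <- function(points, n) {
  while (nrow(points) < n) {
    gaps <- segment_lengths(points)
    i <- which.max(gaps)
    mid <- (points[i, ] + points[i + 1, ]) / 2
    points <- rbind(points[seq_len(i), , drop = FALSE], mid,
                    points[(i + 1):nrow(points), , drop = FALSE])
  }
  points
}

subdivide_points <- function(points, max_gap = 1.5) {
  gaps <- segment_lengths(points)
  if (!length(gaps) || max(gaps) <= max_gap) return(points)
  out <- list(points[1, , drop = FALSE])
  for (i in seq_along(gaps)) {
    a <- points[i, ]; b <- points[i + 1, ]
    k <- ceiling(gaps[i] / max_gap)
    t <- seq_len(k) / k
    out[[i + 1]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

#' Concatenate two paths
#'
#' Joins path `a` then path `b` into one path, reparameterized so that `a`
#' occupies the first half of the index range and `b` the second, with the
#' join point at the exact middle index. The shorter part (in point count)
#' is upsampled by segment-midpoint insertion, which leaves its geometry --
#' and hence any rasterization -- unchanged.
#'
#' @param a,b `discrete_path` objects; the last point of `a` must match the
#'   first point of `b` within 1 pixel unit.
#' @return a `discrete_path` traversing `a` then `b`.
#' @export
concatenate_paths <- function(a, b) {
  stopifnot(inherits(a, "discrete_path"), inherits(b, "discrete_path"))
  pa <- a$points; pb <- b$points
  gap <- sqrt(sum((pa[nrow(pa), ] - pb[1, ])^2))
  if (gap > 1)
    stop("curves are not adjacent: endpoint mismatch of ", round(gap, 3),
         " pixel units")
  if (gap > 0) pb[1, ] <- pa[nrow(pa), ]  # snap the join
  n <- max(nrow(pa), nrow(pb))
  pa <- upsample_points(pa, n)
  pb <- upsample_points(pb, n)
  ml <- if (!is.null(a$metric_length) && !is.null(b$metric_length))
    a$metric_length + b$metric_length else NULL
  discrete_path(rbind(pa, pb[-1, , drop = FALSE]), metric_length = ml)
}

#' Supercover rasterization of a path
#'
#' Marks every pixel whose closed unit cell is touched by any segment of the
#' polyline (conservative supercover, not Bresenham), so a voting path can
#' never miss a pixel it grazes.
#'
#' @param path a `discrete_path`.
#' @param grid an [image_grid()]; all path points must lie inside it.
#' @return a [pixel_mask()] with role "contour".
#' @export
rasterize_path <- function(path, grid) {
  pts <- path$points
  if (!all(in_grid(pts, grid)))
    stop("path has points outside the grid")
  nr <- grid$shape[[1]]; nc <- grid$shape[[2]]
  idx <- cpp_supercover(pts - 1, nr, nc) + 1L
  m <- matrix(FALSE, nr, nc)
  m[idx] <- TRUE
  pixel_mask(m, grid, role = "contour")
}

rasterize_indices <- function(points, nr, nc) {
  cpp_supercover(points - 1, nr, nc) + 1L
}

#' Terminal direction of a path
#'
#' Unit tangent at the path's final point, estimated by a least-squares line
#' fit (principal direction) over the last `max(3, 5%)` points, oriented
#' along the direction of travel.
#'
#' @param path a `discrete_path` with at least 4 points.
#' @return unit 2-vector (drow, dcol).
#' @export
terminal_direction <- function(path) {
  pts <- path$points
  n <- nrow(pts)
  if (n < 4L) stop("path too short for tangent estimation (need >= 4 points)")
  k <- max(3L, ceiling(0.05 * n))
  tail_pts <- pts[(n - k):n, , drop = FALSE]
  ctr <- sweep(tail_pts, 2, colMeans(tail_pts))
  if (sum(ctr^2) < 1e-18) stop("degenerate (zero-length) path tail")
  v <- svd(ctr, nu = 0, nv = 1)$v[, 1]
  # orient along travel: from first to last tail point
  tr <- tail_pts[nrow(tail_pts), ] - tail_pts[1, ]
  if (sum(v * tr) < 0) v <- -v
  v / sqrt(sum(v^2))
}
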