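#' Landmark set
#'
#' A center pixel inside the target plus an ordered (clockwise) list of
#' approximate boundary points, as produced by polar-representation
#' detectors, with space for their rectified positions.
#'
#' @param center pixel (row, col) inside the target.
#' @param points J x 2 matrix of ordered approximate boundary pixels, J >= 3.
#' @param rectified optional J x 2 matrix of rectified points.
#' @param xi rectification neighbourhood radius in pixels.
#' @return a `landmark_set` object.
#' @export
landmark_set <- function(center, points, rectified = NULL, xi = 6) {
  points <- as_pixel_matrix(points)
  if (nrow(points) < 3L) stop("at least 3 landmarks are required")
  center <- as.integer(center)
  if (!is.null(rectified)) {
    rectified <- as_pixel_matrix(rectified)
    if (nrow(rectified) != nrow(points))
      stop("rectified list must match the raw list in length and order")
  }
  structure(list(center = center, raw_points = points,
                 rectified_points = rectified, xi = xi),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set: center (%d, %d), J = %d%s, xi = %g>\n",
              x$center[1], x$center[2], nrow(x$raw_points),
              if (is.null(x$rectified_points)) "" else " (rectified)", x$xi))
  invisible(x)
}

#' Read landmarks from JSON
#'
#' Schema: `{"center": [r, c], "points": [[r, c], ...]}`, 1-based pixel
#' coordinates; an optional `"rectified"` array is honoured.
#'
#' @param path JSON file path.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  landmark_set(center = as.integer(x$center),
               points = matrix(as.integer(x$points), ncol = 2),
               rectified = if (!is.null(x$rectified))
                 matrix(as.integer(x$rectified), ncol = 2) else NULL,
               xi = if (!is.null(x$xi)) x$xi else 6)
}

#' Write landmarks to JSON
#'
#' @param lm a [landmark_set()].
#' @param path output file path.
#' @param provenance short string recorded alongside (e.g. "rectified").
#' @export
write_landmarks <- function(lm, path, provenance = "raw") {
  obj <- list(center = lm$center,
              points = unname(apply(lm$raw_points, 1, as.list)),
              xi = lm$xi, provenance = provenance)
  if (!is.null(lm$rectified_points))
    obj$rectified <- unname(apply(lm$rectified_points, 1, as.list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rectify landmarks onto image edges
#'
#' Moves each raw landmark to the strongest edge point of its geodesic
#' neighbourhood: from each raw point a Riemannian eikonal problem is solved
#' with Euclidean-length tracking; the neighbourhood contains every pixel
#' whose realized minimal path has Euclidean length at most `xi`; the
#' rectified point is the arg-max of the edge indicator `f` over that
#' neighbourhood (ties broken by smaller geodesic distance, then
#' lexicographic order). If `f` is constant on the neighbourhood the raw
#' point is kept.
#'
#' The solve is restricted to a window of half-width `ceil(xi) + 4` around
#' each raw point, which contains the whole neighbourhood since realized
#' Euclidean path lengths bound the straight-line distance.
#'
#' @param landmarks a [landmark_set()] (raw points inside the grid).
#' @param feat edge features of the image.
#' @param metric_R the Riemannian metric from [build_riemannian_metric()].
#' @param xi neighbourhood radius in pixels (>= 1); defaults to the set's.
#' @return the [landmark_set()] with `rectified_points` filled, order
#'   preserved.
#' @export
rectify_landmarks <- function(landmarks, feat, metric_R, xi = NULL) {
  stopifnot(inherits(landmarks, "landmark_set"),
            inherits(feat, "edge_features"),
            inherits(metric_R, "metric_field"),
            metric_R$kind == "riemannian")
  if (is.null(xi)) xi <- landmarks$xi
  if (!is.numeric(xi) || xi < 1) stop("xi must be >= 1 pixel")
  grid <- feat$grid
  raw <- landmarks$raw_points
  if (!all(in_grid(raw, grid))) stop("raw landmark outside the grid")
  nr <- grid$shape[[1]]; nc <- grid$shape[[2]]
  w <- as.integer(ceiling(xi)) + 4L

  rect <- raw
  if (!feat$flat) {
    for (j in seq_len(nrow(raw))) {
      p <- raw[j, ]
      r0 <- max(1L, p[1] - w); r1 <- min(nr, p[1] + w)
      c0 <- max(1L, p[2] - w); c1 <- min(nc, p[2] + w)
      sub <- crop_riemannian(metric_R, r0, r1, c0, c1)
      dm <- solve_eikonal(sub, c(p[1] - r0 + 1L, p[2] - c0 + 1L),
                          track_euclidean = TRUE)
      inT <- is.finite(dm$eu) & dm$eu <= xi + 1e-9
      fsub <- feat$f[r0:r1, c0:c1, drop = FALSE]
      fT <- fsub[inT]
      if (max(fT) - min(fT) <= 1e-12) next   # flat f: identity fallback
      ord <- order(-fsub[inT],
                   dm$values[inT],
                   row(fsub)[inT], col(fsub)[inT])
      pick <- which(inT)[ord[1]]
      rect[j, ] <- c((pick - 1L) %% nrow(fsub) + r0,
                     (pick - 1L) %/% nrow(fsub) + c0)
    }
  }
  landmark_set(landmarks$center, raw, rectified = rect, xi = xi)
}

crop_riemannian <- function(metric, r0, r1, c0, c1) {
  new_metric_field("riemannian", image_grid(r1 - r0 + 1L, c1 - c0 + 1L),
                   Mrr = metric$Mrr[r0:r1, c0:c1, drop = FALSE],
                   Mrc = metric$Mrc[r0:r1, c0:c1, drop = FALSE],
                   Mcc = metric$Mcc[r0:r1, c0:c1, drop = FALSE],
                   mu = metric$mu)
}
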