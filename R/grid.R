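#' Discrete image domain
#'
#' Defines the rectangular pixel grid on which all computations run.
#' Coordinates are (row, col), 1-based from R, with pixel centers at integer
#' positions and unit spacing. The domain boundary is the outermost pixel
#' ring.
#'
#' @param rows,cols grid dimensions; both must be at least 8.
#' @return an object of class `image_grid` with fields `shape` (rows, cols)
#'   and `spacing` (always 1).
#' @export
image_grid <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (length(rows) != 1L || length(cols) != 1L || is.na(rows) || is.na(cols))
    stop("rows and cols must be single integers")
  if (rows < 8L || cols < 8L)
    stop("grids smaller than 8x8 are not supported")
  structure(list(shape = c(rows = rows, cols = cols), spacing = 1),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid %d x %d, unit spacing>\n",
              x$shape[1], x$shape[2]))
  invisible(x)
}

#' Boundary pixels of a grid
#'
#' The outermost pixel ring, i.e. the discrete domain boundary used as the
#' endpoint set of adaptive cuts.
#'
#' @param grid an [image_grid()].
#' @return integer matrix with columns (row, col), one row per boundary
#'   pixel, in lexicographic order; exactly `2*rows + 2*cols - 4` pixels.
#' @export
grid_boundary <- function(grid) {
  nr <- grid$shape[[1]]; nc <- grid$shape[[2]]
  r <- rep(seq_len(nr), times = nc)
  c <- rep(seq_len(nc), each = nr)
  keep <- r == 1L | r == nr | c == 1L | c == nc
  m <- cbind(row = r[keep], col = c[keep])
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' Shape-matched boolean mask
#'
#' A logical field over an image grid with a role tag. Used for obstacles
#' (cut barriers), regions and contours.
#'
#' @param values logical matrix matching the grid shape.
#' @param grid an [image_grid()].
#' @param role one of "obstacle", "region", "contour".
#' @return a `pixel_mask` object (logical matrix with attributes).
#' @export
pixel_mask <- function(values, grid, role = c("obstacle", "region", "contour")) {
  role <- match.arg(role)
  values <- as.matrix(values)
  storage.mode(values) <- "logical"
  if (!identical(dim(values), unname(grid$shape)))
    stop("mask shape does not match its grid")
  structure(values, class = c("pixel_mask", "matrix"),
            role = role, grid = grid)
}

#' @export
print.pixel_mask <- function(x, ...) {
  cat(sprintf("<pixel_mask %s, %d x %d, %d set>\n", attr(x, "role"),
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

in_grid <- function(pts, grid) {
  nr <- grid$shape[[1]]; nc <- grid$shape[[2]]
  pts[, 1] >= 1 & pts[, 1] <= nr & pts[, 2] >= 1 & pts[, 2] <= nc
}
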