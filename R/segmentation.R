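#' Extract a segmentation from the voting score map
#'
#' Binarizes the total voting score at `threshold_fraction` times the total
#' number of voting paths, closes the band morphologically (disc radius 2),
#' keeps the connected component enclosing the center (or, failing that,
#' the nearest component, with a warning), fills holes to obtain the region
#' mask, and takes the region's inner boundary as the single-pixel-wide
#' closed contour. With 1000 paths and the default fraction 0.1 the
#' absolute threshold is 100.
#'
#' @param votes a `voting_score`.
#' @param center interior pixel (row, col).
#' @param threshold_fraction fraction in (0, 1) of the total path count.
#' @param truth optional ground-truth region mask for scoring.
#' @return a `segmentation_result` with fields `contour`, `region`
#'   ([pixel_mask()]s), `threshold_used`, and, when `truth` is given,
#'   `score` (the precision fraction |S n G| / |S|) and `dice_standard`.
#' @export
extract_segmentation <- function(votes, center, threshold_fraction = 0.1,
                                 truth = NULL) {
  stopifnot(inherits(votes, "voting_score"))
  if (!is.numeric(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction >= 1)
    stop("threshold_fraction must lie in (0, 1)")
  if (max(votes$total) == 0L) stop("voting score map is identically zero")
  grid <- votes$grid
  nr <- grid$shape[[1]]; nc <- grid$shape[[2]]
  thr <- as.integer(round(threshold_fraction * votes$n_paths))
  bin <- votes$total >= thr
  if (!any(bin))
    stop(sprintf(paste0("binarization at threshold %d is empty; ",
                        "try a lower threshold_fraction"), thr))

  brush <- EBImage::makeBrush(5L, shape = "disc")
  closed <- as.matrix(EBImage::closing(matrix(as.numeric(bin), nr), brush)) > 0.5
  # label on a 1-px dilation so 8-connected (diagonally linked) bands count
  # as one component and single-pixel rings still enclose their interior
  box3 <- matrix(1, 3L, 3L)
  dil <- as.matrix(EBImage::dilate(matrix(as.numeric(closed), nr), box3)) > 0.5
  lab <- as.matrix(EBImage::bwlabel(matrix(as.numeric(dil), nr)))
  ids <- setdiff(sort(unique(as.vector(lab))), 0)

  # prefer the component whose filled hull encloses the center
  fill_of <- function(id) {
    f <- as.matrix(EBImage::fillHull(matrix(as.numeric(lab == id), nr))) > 0.5
    as.matrix(EBImage::erode(matrix(as.numeric(f), nr), box3)) > 0.5
  }
  enclosing <- integer(0)
  for (id in ids)
    if (fill_of(id)[center[1], center[2]]) enclosing <- c(enclosing, id)
  if (length(enclosing)) {
    sizes <- vapply(enclosing, function(id) sum(lab == id & closed), numeric(1))
    comp <- enclosing[which.max(sizes)]
  } else {
    warning("no component encloses the center; using the nearest one")
    labc <- lab; labc[!closed] <- 0
    d2 <- (row(lab) - center[1])^2 + (col(lab) - center[2])^2
    d2[labc == 0] <- Inf
    comp <- labc[which.min(d2)]
  }

  region <- fill_of(comp) | (closed & lab == comp)
  eroded <- as.matrix(EBImage::erode(
    matrix(as.numeric(region), nr),
    matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3L))) > 0.5
  contour <- region & !eroded

  out <- structure(list(contour = pixel_mask(contour, grid, "contour"),
                        region = pixel_mask(region, grid, "region"),
                        threshold_used = thr),
                   class = "segmentation_result")
  if (!is.null(truth)) {
    truth <- as.matrix(truth) > 0.5
    out$score <- precision_score(region, truth)
    out$dice_standard <- dice_score(region, truth)
  }
  out
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result: region %d px, contour %d px, threshold %d%s>\n",
              sum(x$region), sum(x$contour), x$threshold_used,
              if (is.null(x$score)) ""
              else sprintf(", score %.4f, Dice %.4f", x$score,
                           x$dice_standard)))
  invisible(x)
}

#' Precision-fraction accuracy score
#'
#' The fraction `|S n G| / |S|` of the predicted set lying inside the
#' ground truth. Note this is not the conventional Dice coefficient; see
#' [dice_score()] for that.
#'
#' @param S predicted mask (logical matrix or [pixel_mask()]), nonempty.
#' @param G ground-truth mask of the same shape.
#' @return scalar in `[0, 1]`; 1 iff `S` is a subset of `G`.
#' @export
precision_score <- function(S, G) {
  S <- as.matrix(S) > 0.5; G <- as.matrix(G) > 0.5
  if (!identical(dim(S), dim(G))) stop("mask shapes do not match")
  if (!any(S)) stop("the predicted set S is empty")
  sum(S & G) / sum(S)
}

#' Conventional Dice coefficient
#'
#' `2 |S n G| / (|S| + |G|)`.
#'
#' @inheritParams precision_score
#' @return scalar in `[0, 1]`.
#' @export
dice_score <- function(S, G) {
  S <- as.matrix(S) > 0.5; G <- as.matrix(G) > 0.5
  if (!identical(dim(S), dim(G))) stop("mask shapes do not match")
  den <- sum(S) + sum(G)
  if (den == 0) return(1)
  2 * sum(S & G) / den
}
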