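#' Edge features of an image
#'
#' Computes, per pixel, the Gaussian-derivative channel gradients, the
#' structure tensor `W = grad(I) grad(I)'` summed over channels, its
#' eigenvalues, the edge indicator `f = lambda1 + lambda2` (the trace of W),
#' and a unit vector field `r` pointing towards the closest image edge with
#' its perpendicular tangent field `t`. The edge set feeding the distance
#' transform behind `r` is obtained by non-maximum suppression of the
#' normalized indicator along the dominant eigenvector, thresholded at 0.2.
#'
#' @param image numeric matrix (grayscale) or (rows, cols, channels) array
#'   with finite values; intensities are expected in a common range such as
#'   \[0, 1\].
#' @param sigma Gaussian derivative scale in pixels (> 0).
#' @return an `edge_features` object with fields `grid`, `sigma`, `Wrr`,
#'   `Wrc`, `Wcc` (structure tensor components), `lambda1`, `lambda2`
#'   (eigenvalues, `lambda1 <= lambda2`), `f` (edge indicator), `fhat`
#'   (`f` rescaled to \[0, 1\] by its global maximum), `rr`, `rc` (edge
#'   direction field), `tr_`, `tc` (edge tangent, `r` rotated +90 degrees),
#'   `defined` (logical, where the direction field exists), and `flat`
#'   (TRUE for a constant image).
#' @export
compute_edge_features <- function(image, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single positive number")
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  if (length(dim(image)) != 3L)
    stop("image must be a matrix or a rows x cols x channels array")
  if (!all(is.finite(image))) stop("image must be finite-valued")
  nr <- dim(image)[1]; nc <- dim(image)[2]; nch <- dim(image)[3]
  grid <- image_grid(nr, nc)

  kr <- gaussian_deriv_kernels(sigma)
  Wrr <- Wrc <- Wcc <- matrix(0, nr, nc)
  for (k in seq_len(nch)) {
    ch <- image[, , k]
    gr <- EBImage::filter2(ch, kr$d_row, boundary = "replicate")
    gc <- EBImage::filter2(ch, kr$d_col, boundary = "replicate")
    Wrr <- Wrr + gr * gr
    Wrc <- Wrc + gr * gc
    Wcc <- Wcc + gc * gc
  }

  tr <- Wrr + Wcc
  disc <- sqrt(pmax((Wrr - Wcc)^2 + 4 * Wrc^2, 0))
  lambda2 <- (tr + disc) / 2
  lambda1 <- (tr - disc) / 2
  f <- tr
  fmax <- max(f)
  flat <- fmax <= 1e-14
  fhat <- if (flat) matrix(0, nr, nc) else f / fmax

  if (flat) {
    rr <- rc <- tr_ <- tc <- matrix(0, nr, nc)
    defined <- matrix(FALSE, nr, nc)
  } else {
    dirs <- edge_direction_field(fhat, Wrr, Wrc, Wcc, lambda2)
    rr <- dirs$rr; rc <- dirs$rc; defined <- dirs$defined
    tr_ <- -rc   # t = r rotated +90 degrees: (dr, dc) -> (-dc, dr)
    tc <- rr
  }

  structure(list(grid = grid, sigma = sigma,
                 Wrr = Wrr, Wrc = Wrc, Wcc = Wcc,
                 lambda1 = lambda1, lambda2 = lambda2,
                 f = f, fhat = fhat,
                 rr = rr, rc = rc, tr_ = tr_, tc = tc,
                 defined = defined, flat = flat),
            class = "edge_features")
}

#' @export
print.edge_features <- function(x, ...) {
  cat(sprintf("<edge_features %d x %d, sigma = %g, max f = %.4g%s>\n",
              nrow(x$f), ncol(x$f), x$sigma, max(x$f),
              if (x$flat) " (flat image)" else ""))
  invisible(x)
}

gaussian_deriv_kernels <- function(sigma) {
  h <- max(3L, ceiling(3.5 * sigma))
  u <- (-h):h
  g <- exp(-u^2 / (2 * sigma^2)); g <- g / sum(g)
  dg <- -u / sigma^2 * exp(-u^2 / (2 * sigma^2))
  dg <- dg / sum(u * dg) * 1  # normalize so response to a unit ramp is 1
  list(d_row = outer(dg, g), d_col = outer(g, dg))
}

# Unit direction towards the closest edge pixel, realized as the descent
# direction of the Euclidean distance transform to the NMS-thresholded edge
# set; falls back to the dominant eigenvector of W where that gradient
# vanishes (on the edge itself).
edge_direction_field <- function(fhat, Wrr, Wrc, Wcc, lambda2, thresh = 0.2) {
  nr <- nrow(fhat); nc <- ncol(fhat)
  ev <- principal_eigvec(Wrr, Wrc, Wcc, lambda2)

  # non-maximum suppression along the dominant eigenvector (across the edge)
  orow <- ifelse(abs(ev$vr) >= 0.4142 * abs(ev$vc), sign(ev$vr), 0)
  ocol <- ifelse(abs(ev$vc) >= 0.4142 * abs(ev$vr), sign(ev$vc), 0)
  edge <- fhat > thresh
  ri <- row(fhat); ci <- col(fhat)
  rp <- pmin(pmax(ri + orow, 1), nr); cp <- pmin(pmax(ci + ocol, 1), nc)
  rm <- pmin(pmax(ri - orow, 1), nr); cm <- pmin(pmax(ci - ocol, 1), nc)
  edge <- edge & fhat >= fhat[cbind(as.vector(rp), as.vector(cp))] &
                 fhat >= fhat[cbind(as.vector(rm), as.vector(cm))]
  if (!any(edge)) edge <- fhat >= max(fhat)  # degenerate: keep global max

  D <- as.matrix(EBImage::distmap(matrix(as.numeric(!edge), nr, nc)))
  Ds <- as.matrix(EBImage::filter2(D, smooth_kernel(1), boundary = "replicate"))
  gr <- central_diff(Ds, 1L)
  gc <- central_diff(Ds, 2L)
  nrm <- sqrt(gr^2 + gc^2)
  defined <- nrm > 1e-6
  rr <- ifelse(defined, -gr / pmax(nrm, 1e-12), 0)
  rc <- ifelse(defined, -gc / pmax(nrm, 1e-12), 0)

  # on/near the edge the distance gradient vanishes: use the dominant
  # eigenvector (the across-edge direction) there
  evn <- sqrt(ev$vr^2 + ev$vc^2)
  fallback <- !defined & evn > 1e-6
  rr[fallback] <- (ev$vr / evn)[fallback]
  rc[fallback] <- (ev$vc / evn)[fallback]
  defined <- defined | fallback
  list(rr = rr, rc = rc, defined = defined)
}

principal_eigvec <- function(Wrr, Wrc, Wcc, lambda2) {
  # eigenvector of the larger eigenvalue of [[Wrr, Wrc], [Wrc, Wcc]]
  vr <- ifelse(abs(Wrc) > 1e-14, lambda2 - Wcc, as.numeric(Wrr >= Wcc))
  vc <- ifelse(abs(Wrc) > 1e-14, Wrc, as.numeric(Wrr < Wcc))
  n <- sqrt(vr^2 + vc^2)
  bad <- n < 1e-14
  list(vr = ifelse(bad, 0, vr / pmax(n, 1e-14)),
       vc = ifelse(bad, 0, vc / pmax(n, 1e-14)))
}

smooth_kernel <- function(sigma) {
  h <- max(2L, ceiling(3 * sigma))
  u <- (-h):h
  g <- exp(-u^2 / (2 * sigma^2)); g <- g / sum(g)
  outer(g, g)
}

central_diff <- function(m, dim) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  if (dim == 1L) {
    out[2:(nr - 1), ] <- (m[3:nr, ] - m[1:(nr - 2), ]) / 2
    out[1, ] <- m[2, ] - m[1, ]
    out[nr, ] <- m[nr, ] - m[nr - 1, ]
  } else {
    out[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / 2
    out[, 1] <- m[, 2] - m[, 1]
    out[, nc] <- m[, nc] - m[, nc - 1]
  }
  out
}
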