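# Small deterministic fixtures shared across test files.

step_image <- function(n = 32L, at = NULL) {
  if (is.null(at)) at <- n %/% 2L
  img <- matrix(0, n, n)
  img[, (at + 1L):n] <- 1
  img
}

disk_image <- function(n = 64L, radius = n * 0.3, center = c(n, n) / 2 + 0.5,
                       fg = 0.7, bg = 0.2) {
  rr <- row(matrix(0, n, n)); cc <- col(matrix(0, n, n))
  inside <- (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
  img <- matrix(bg, n, n); img[inside] <- fg
  list(image = img, region = inside, center = round(center),
       radius = radius, ctr = center)
}

staircase_path <- function(n_steps, start = c(1, 1), seed = 1) {
  set.seed(seed)
  pts <- matrix(start, 1, 2)
  for (i in seq_len(n_steps)) {
    step <- if (runif(1) < 0.5) c(1, 0) else c(0, 1)
    pts <- rbind(pts, pts[nrow(pts), ] + step)
  }
  discrete_path(pts)
}

quarter_circle_path <- function(radius = 10, n = 60, center = c(15, 15)) {
  # starts at the south point heading east, ends at the east point heading
  # north (tangent (-1, 0))
  th <- seq(-pi / 2, 0, length.out = n)
  discrete_path(cbind(center[1] - radius * sin(th),
                      center[2] + radius * cos(th)))
}
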