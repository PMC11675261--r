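#' Synthetic scene descriptor
#'
#' Collects everything needed to regenerate a synthetic test scene
#' deterministically: shape family, intensity model, degradations and seed.
#' Defaults emulate the working scale of abdominal CT crops (around
#' 100--150 px) and the output format of polar-representation detectors:
#' clockwise-ordered boundary points near, but not on, the true contour,
#' plus a center point inside the target.
#'
#' @param family one of "disk", "ellipse", "star", "ushape".
#' @param seed integer RNG seed for the scene's private stream.
#' @param size image side length in pixels (square image, >= 32).
#' @param intensity "constant" or "linear" (adds a linear illumination
#'   ramp to the whole image).
#' @param noise_var additive Gaussian noise variance (0 disables).
#' @param blur_sigma Gaussian blur sigma in pixels (0 disables).
#' @param brightness multiplicative brightness factor (1 = unchanged).
#' @param n_landmarks number of polar rays / landmarks J (>= 3).
#' @param perturb radial landmark perturbation radius in pixels.
#' @return a `scene_descriptor` list.
#' @export
scene_descriptor <- function(family = c("disk", "ellipse", "star", "ushape"),
                             seed = 0L, size = 128L,
                             intensity = c("constant", "linear"),
                             noise_var = 0, blur_sigma = 0, brightness = 1,
                             n_landmarks = 36L, perturb = 3) {
  family <- match.arg(family)
  intensity <- match.arg(intensity)
  size <- as.integer(size)
  if (size < 32L) stop("size must be >= 32")
  n_landmarks <- as.integer(n_landmarks)
  if (n_landmarks < 3L) stop("n_landmarks must be >= 3")
  structure(list(family = family, seed = as.integer(seed), size = size,
                 intensity = intensity, noise_var = noise_var,
                 blur_sigma = blur_sigma, brightness = brightness,
                 n_landmarks = n_landmarks, perturb = perturb),
            class = "scene_descriptor")
}

with_scene_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic scene
#'
#' Draws the shape with the requested intensity model (foreground 0.7 on
#' background 0.2), samples `J` polar rays from the shape center, locates
#' the outermost true-boundary crossing per ray (matching the
#' greatest-length-per-ray behaviour of polar detectors), perturbs each
#' landmark radially by uniform noise within the stated radius, and applies
#' the requested degradations in the order blur, brightness, additive
#' noise. Regeneration from the same descriptor is bit-identical.
#'
#' @param descriptor a [scene_descriptor()].
#' @return a `synthetic_scene` with fields `image` (float matrix),
#'   `truth_region`, `truth_contour` ([pixel_mask()]s), `landmarks`
#'   ([landmark_set()]), `descriptor`.
#' @export
make_scene <- function(descriptor) {
  stopifnot(inherits(descriptor, "scene_descriptor"))
  d <- descriptor
  with_scene_seed(d$seed, {
    n <- d$size
    grid <- image_grid(n, n)
    shp <- draw_shape(d$family, n)
    region <- shp$region
    eroded <- as.matrix(EBImage::erode(
      matrix(as.numeric(region), n),
      matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3L))) > 0.5
    contour <- region & !eroded

    img <- matrix(0.2, n, n)
    img[region] <- 0.7
    if (d$intensity == "linear") {
      a <- stats::runif(2, -0.1, 0.1)
      img <- img + a[1] * (row(img) / n) + a[2] * (col(img) / n)
    }
    if (d$blur_sigma > 0)
      img <- as.matrix(EBImage::filter2(img, smooth_kernel(d$blur_sigma),
                                        boundary = "replicate"))
    if (d$brightness != 1) img <- img * d$brightness
    if (d$noise_var > 0)
      img <- img + matrix(stats::rnorm(n * n, 0, sqrt(d$noise_var)), n, n)

    lm <- sample_landmarks(region, shp$center, d$n_landmarks, d$perturb, grid)
    structure(list(image = img,
                   truth_region = pixel_mask(region, grid, "region"),
                   truth_contour = pixel_mask(contour, grid, "contour"),
                   landmarks = lm, descriptor = d),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  d <- x$descriptor
  cat(sprintf("<synthetic_scene %s, %dx%d, seed %d, J = %d>\n",
              d$family, d$size, d$size, d$seed, d$n_landmarks))
  invisible(x)
}

# Shape masks. All shapes keep their area >= ~8% of the image and their
# interior center strictly inside the region.
draw_shape <- function(family, n) {
  ctr <- c(n, n) / 2 + stats::runif(2, -3, 3)
  R <- 0.30 * n
  rr <- row(matrix(0, n, n)); cc <- col(matrix(0, n, n))
  dr <- rr - ctr[1]; dc <- cc - ctr[2]
  if (family == "disk") {
    region <- dr^2 + dc^2 <= R^2
  } else if (family == "ellipse") {
    alpha <- stats::runif(1, 0, pi)
    a <- 1.2 * R; b <- 0.75 * R
    x <- dr * cos(alpha) + dc * sin(alpha)
    y <- -dr * sin(alpha) + dc * cos(alpha)
    region <- (x / a)^2 + (y / b)^2 <= 1
  } else if (family == "star") {
    th <- atan2(-dr, dc)
    rad <- 0.88 * R * (1 + 0.22 * cos(5 * th))
    region <- dr^2 + dc^2 <= rad^2
  } else {  # ushape: two arms joined by a bottom bar
    h <- 0.62 * n; w <- 0.5 * n
    r0 <- ctr[1] - h / 2; r1 <- ctr[1] + h / 2
    c0 <- ctr[2] - w / 2; c1 <- ctr[2] + w / 2
    notch_w <- 0.4 * w
    rm <- r1 - 0.38 * h      # notch bottom
    outer <- rr >= r0 & rr <= r1 & cc >= c0 & cc <= c1
    notch <- rr < rm & cc > ctr[2] - notch_w / 2 & cc < ctr[2] + notch_w / 2
    region <- outer & !notch
    ctr <- c((rm + r1) / 2, ctr[2])   # interior center: in the bottom bar
  }
  ctr <- round(ctr)
  if (!region[ctr[1], ctr[2]]) stop("internal: shape center left the region")
  list(region = region, center = as.integer(ctr))
}

# Polar-ray landmark sampling: J rays at equal angular intervals, clockwise
# order; per ray the outermost region->background transition is the true
# boundary point; perturb radially, round, clamp into the grid.
sample_landmarks <- function(region, center, J, perturb, grid) {
  n <- nrow(region)
  th <- -2 * pi * (seq_len(J) - 1L) / J     # decreasing angle = clockwise
  pts <- matrix(0L, J, 2)
  for (i in seq_len(J)) {
    v <- c(-sin(th[i]), cos(th[i]))
    dmax <- ray_exit_distance(center, v, n)
    s <- seq(0, dmax, by = 0.25)
    inside <- region[cbind(pmin(pmax(round(center[1] + s * v[1]), 1), n),
                           pmin(pmax(round(center[2] + s * v[2]), 1), n))]
    last_in <- max(which(inside))
    d_true <- s[last_in]
    d <- d_true + stats::runif(1, -perturb, perturb)
    p <- round(center + d * v)
    if (any(p < 1 | p > n)) {
      warning("perturbed landmark clamped into the grid")
      p <- pmin(pmax(p, 1L), n)
    }
    pts[i, ] <- as.integer(p)
  }
  landmark_set(center, pts)
}

ray_exit_distance <- function(center, v, n) {
  lim <- Inf
  if (abs(v[1]) > 1e-12)
    lim <- min(lim, max((1 - center[1]) / v[1], (n - center[1]) / v[1]))
  if (abs(v[2]) > 1e-12)
    lim <- min(lim, max((1 - center[2]) / v[2], (n - center[2]) / v[2]))
  lim
}

#' Generate a suite of scenes
#'
#' Cross-product of shape families and seeds, in deterministic order
#' (families outer, seeds inner). Suite scenes default to the adverse
#' conditions the generator is meant to emulate -- a linear illumination
#' ramp and additive Gaussian noise of variance 0.01 -- rather than the
#' clean single-scene defaults.
#'
#' @param families character vector of shape families.
#' @param seeds integer vector of seeds.
#' @param intensity,noise_var see [scene_descriptor()].
#' @param ... further arguments passed to [scene_descriptor()].
#' @return list of `synthetic_scene`s of length
#'   `length(families) * length(seeds)`.
#' @export
make_suite <- function(families = c("disk", "ellipse", "star", "ushape"),
                       seeds = 0:2, intensity = "linear",
                       noise_var = 0.01, ...) {
  if (!length(families) || !length(seeds))
    stop("families and seeds must be nonempty")
  out <- list()
  for (f in families)
    for (s in seeds)
      out[[length(out) + 1L]] <- make_scene(
        scene_descriptor(f, seed = s, intensity = intensity,
                         noise_var = noise_var, ...))
  out
}

#' Write a scene to disk
#'
#' Image and masks as 8-bit PNG, landmarks and descriptor as JSON.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if missing).
#' @param stem file name stem.
#' @return the directory, invisibly.
#' @export
write_scene <- function(scene, dir, stem = "scene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img <- scene$image
  img01 <- (img - min(img)) / max(max(img) - min(img), 1e-12)
  png::writePNG(img01, file.path(dir, paste0(stem, ".png")))
  png::writePNG(matrix(as.numeric(scene$truth_region), nrow(img)),
                file.path(dir, paste0(stem, "_region.png")))
  png::writePNG(matrix(as.numeric(scene$truth_contour), nrow(img)),
                file.path(dir, paste0(stem, "_contour.png")))
  write_landmarks(scene$landmarks,
                  file.path(dir, paste0(stem, "_landmarks.json")))
  jsonlite::write_json(unclass(scene$descriptor),
                       file.path(dir, paste0(stem, "_descriptor.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
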