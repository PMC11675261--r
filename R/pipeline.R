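#' Pipeline parameters
#'
#' All tunable numeric parameters of the segmentation pipeline with their
#' defaults. Calling with an unknown argument is an error, so stray config
#' keys are rejected.
#'
#' @param sigma Gaussian derivative scale for edge features, pixels.
#' @param mu_R exponential contrast weight of the rectification metric and
#'   of the asymmetric quadratic voting metrics.
#' @param mu_phi exponential contrast weight of the elastica cost.
#' @param eta asymmetry weight of the voting metrics (>= 0).
#' @param tau curvature weight of the elastica energy, pixels.
#' @param n_angles orientation bins of the lifted grid (>= 16).
#' @param xi rectification neighbourhood radius, pixels.
#' @param epsilon cut offset magnitude, pixels.
#' @param K number of farthest-point-sampled voting endpoints per run.
#' @param threshold_fraction binarization threshold as a fraction of the
#'   total voting path count.
#' @param zeta terminal-cosine threshold of the optional flow-consistency
#'   branch, in `[-1, 0)`.
#' @param use_flow_filter enable the optional pairwise flow-consistency
#'   voting branch (off by default: the multi-cut pipeline uses pure
#'   distance-competition voting).
#' @param rho stencil Chebyshev radius of the planar eikonal solver.
#' @param continuity constrain each cut's outward half to continue the
#'   inward half's terminal orientation at the landmark.
#' @param independent_sides compute the left-side competition from its own
#'   distance pair rather than reusing the right side's.
#' @return a named list of class `geovote_control`.
#' @export
geovote_control <- function(sigma = 2, mu_R = 4, mu_phi = 1, eta = 1,
                            tau = 2, n_angles = 64L, xi = 6, epsilon = 2,
                            K = 100L, threshold_fraction = 0.1,
                            zeta = -0.5, use_flow_filter = FALSE,
                            rho = 3L, continuity = FALSE,
                            independent_sides = TRUE) {
  ctl <- list(sigma = sigma, mu_R = mu_R, mu_phi = mu_phi, eta = eta,
              tau = tau, n_angles = as.integer(n_angles), xi = xi,
              epsilon = epsilon, K = as.integer(K),
              threshold_fraction = threshold_fraction, zeta = zeta,
              use_flow_filter = isTRUE(use_flow_filter),
              rho = as.integer(rho), continuity = isTRUE(continuity),
              independent_sides = isTRUE(independent_sides))
  stopifnot(ctl$sigma > 0, ctl$mu_R > 0, ctl$mu_phi > 0, ctl$eta >= 0,
            ctl$tau > 0, ctl$n_angles >= 16L, ctl$xi >= 1,
            ctl$epsilon > 0, ctl$K >= 1L,
            ctl$threshold_fraction > 0, ctl$threshold_fraction < 1,
            ctl$zeta >= -1, ctl$zeta < 0, ctl$rho >= 1L)
  class(ctl) <- "geovote_control"
  ctl
}

#' Multi-source circular geodesic voting segmentation
#'
#' Runs the full pipeline: edge features, landmark rectification, one
#' adaptive cut per landmark, farthest point sampling of voting endpoints
#' seeded by the union of all cuts, distance-competition voting paths per
#' cut, vote accumulation, and contour/region extraction. The run is
#' deterministic: repeating it with the same inputs and control gives
#' bit-identical masks.
#'
#' @param image numeric matrix (grayscale in \[0, 1\]) or
#'   rows x cols x channels array, or a PNG file path.
#' @param landmarks a [landmark_set()] or a landmark JSON file path.
#' @param control a [geovote_control()] list.
#' @param truth optional ground-truth region mask for scoring.
#' @param verbose log each stage with timings.
#' @return an object of class `geovote`: a list with `region`, `contour`,
#'   `votes`, `landmarks` (rectified), `cuts`, `endpoints`, `features`,
#'   `threshold_used`, `score` / `dice_standard` (when `truth` given),
#'   `control`, `timings`.
#' @examples
#' \donttest{
#' scene <- make_scene(scene_descriptor("disk", seed = 0, n_landmarks = 5))
#' fit <- geovote(scene$image, scene$landmarks, truth = scene$truth_region)
#' summary(fit)
#' }
#' @export
geovote <- function(image, landmarks, control = geovote_control(),
                    truth = NULL, verbose = FALSE) {
  stopifnot(inherits(control, "geovote_control"))
  if (is.character(image)) image <- read_image(image)
  if (is.character(landmarks)) landmarks <- read_landmarks(landmarks)
  stopifnot(inherits(landmarks, "landmark_set"))
  timings <- c()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    dt <- proc.time()[["elapsed"]] - t0
    timings[[name]] <<- dt
    if (verbose) message(sprintf("[geovote] %-22s %6.2f s", name, dt))
    val
  }

  feat <- tick("edge_features", compute_edge_features(image, control$sigma))
  grid <- feat$grid
  metric_R <- build_riemannian_metric(feat, control$mu_R)
  lm <- tick("rectify_landmarks",
             rectify_landmarks(landmarks, feat, metric_R, xi = control$xi))
  cost <- tick("elastica_cost",
               build_elastica_cost(feat, control$mu_phi, control$n_angles))
  cuts <- tick("adaptive_cuts",
               build_all_cuts(lm, cost, control$tau,
                              epsilon = control$epsilon,
                              continuity = control$continuity))

  seed <- do.call(rbind, lapply(cuts, function(ct) {
    idx <- which(as.matrix(rasterize_path(ct$path, grid)))
    cbind((idx - 1L) %% grid$shape[[1]] + 1L,
          (idx - 1L) %/% grid$shape[[1]] + 1L)
  }))
  seed <- unique(seed)
  endpoints <- tick("farthest_point_sampling",
                    farthest_point_sampling(grid, seed, control$K,
                                            rho = control$rho))

  aq <- build_aq_metrics(feat, control$mu_R, control$eta)
  paths_by_source <- tick("voting_paths", {
    lapply(cuts, function(ct) {
      res <- competition_voting_paths(
        ct, aq, endpoints, independent_sides = control$independent_sides)
      res$paths
    })
  })
  votes <- tick("accumulate_votes",
                accumulate_votes(paths_by_source, grid))
  seg <- tick("extract_segmentation",
              extract_segmentation(votes, lm$center,
                                   control$threshold_fraction, truth = truth))

  structure(list(region = seg$region, contour = seg$contour,
                 votes = votes, landmarks = lm, cuts = cuts,
                 endpoints = endpoints, features = feat,
                 threshold_used = seg$threshold_used,
                 score = seg$score, dice_standard = seg$dice_standard,
                 image = image, control = control, timings = timings),
            class = "geovote")
}

#' @export
print.geovote <- function(x, ...) {
  cat("Multi-source circular geodesic voting segmentation\n")
  cat(sprintf("  sources (landmarks): %d   endpoints: %d   voting paths: %d\n",
              length(x$cuts), nrow(x$endpoints$points), x$votes$n_paths))
  cat(sprintf("  region: %d px   contour: %d px   threshold: %d\n",
              sum(x$region), sum(x$contour), x$threshold_used))
  if (!is.null(x$score))
    cat(sprintf("  score (|S&G|/|S|): %.4f   Dice: %.4f\n",
                x$score, x$dice_standard))
  invisible(x)
}

#' @export
summary.geovote <- function(object, ...) {
  print(object)
  cat("\nStage timings (s):\n")
  for (nm in names(object$timings))
    cat(sprintf("  %-22s %6.2f\n", nm, object$timings[[nm]]))
  cat(sprintf("\nControl: sigma=%g mu_R=%g mu_phi=%g eta=%g tau=%g xi=%g K=%d thr=%g\n",
              object$control$sigma, object$control$mu_R,
              object$control$mu_phi, object$control$eta, object$control$tau,
              object$control$xi, object$control$K,
              object$control$threshold_fraction))
  invisible(object)
}

#' @export
fitted.geovote <- function(object, ...) object$region

#' Plot a segmentation result
#'
#' Shows the input image with the extracted contour, the rectified
#' landmarks and the center overlaid.
#'
#' @param x a `geovote` object.
#' @param ... passed to [graphics::image()].
#' @export
plot.geovote <- function(x, ...) {
  img <- x$image
  if (length(dim(img)) == 3L) img <- img[, , 1]
  nr <- nrow(img); nc <- ncol(img)
  graphics::image(t(img)[, nr:1], col = grDevices::gray.colors(256),
                  axes = FALSE, asp = nr / nc, ...)
  idx <- which(as.matrix(x$contour))
  pr <- (idx - 1L) %% nr + 1L; pc <- (idx - 1L) %/% nr + 1L
  graphics::points((pc - 1) / (nc - 1), (nr - pr) / (nr - 1),
                   pch = ".", col = "green", cex = 2)
  lmp <- x$landmarks$rectified_points
  graphics::points((lmp[, 2] - 1) / (nc - 1), (nr - lmp[, 1]) / (nr - 1),
                   col = "red", pch = 19, cex = 0.6)
  ctr <- x$landmarks$center
  graphics::points((ctr[2] - 1) / (nc - 1), (nr - ctr[1]) / (nr - 1),
                   col = "orange", pch = 3)
  invisible(x)
}

#' Write pipeline artifacts to disk
#'
#' Rectified landmarks (JSON), cut polylines (JSON), voting map (CSV),
#' contour and region (PNG), and a JSON report.
#'
#' @param fit a `geovote` object.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_geovote <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_landmarks(fit$landmarks, file.path(dir, "landmarks_rectified.json"),
                  provenance = "rectified")
  cuts <- lapply(fit$cuts, function(ct) unname(apply(ct$path$points, 1, as.list)))
  jsonlite::write_json(cuts, file.path(dir, "cuts.json"), digits = NA)
  utils::write.csv(fit$votes$total, file.path(dir, "votes.csv"),
                   row.names = FALSE)
  write_mask_png(fit$contour, file.path(dir, "contour.png"))
  write_mask_png(fit$region, file.path(dir, "region.png"))
  report <- list(threshold_used = fit$threshold_used,
                 n_paths = fit$votes$n_paths,
                 score = fit$score, dice_standard = fit$dice_standard,
                 parameters = unclass(fit$control),
                 timings = as.list(fit$timings))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Source-count sweep
#'
#' Subsamples each scene's landmark list to the requested source counts and
#' runs the pipeline per count, collecting accuracy scores. Subsampling is
#' evenly spaced over the ordered landmark list by default, or random under
#' a seed.
#'
#' @param scenes list of `synthetic_scene`s (e.g. [make_suite()]).
#' @param source_counts integer vector of landmark counts to test.
#' @param control a [geovote_control()].
#' @param sampling "even" or "random".
#' @param sample_seed RNG seed for random subsampling.
#' @return data.frame with one row per (scene, count): family, seed, count,
#'   score, dice.
#' @export
run_source_sweep <- function(scenes, source_counts,
                             control = geovote_control(),
                             sampling = c("even", "random"),
                             sample_seed = 0L) {
  sampling <- match.arg(sampling)
  rows <- list()
  for (sc in scenes) {
    J <- nrow(sc$landmarks$raw_points)
    for (cnt in source_counts) {
      if (cnt < 1 || cnt > J)
        stop("source count out of range [1, J_available]")
      idx <- if (cnt == J) seq_len(J)
             else if (sampling == "even")
               unique(round(seq(1, J, length.out = cnt + 1L)[-(cnt + 1L)]))
             else with_scene_seed(sample_seed, sort(sample.int(J, cnt)))
      lm <- landmark_set(sc$landmarks$center,
                         sc$landmarks$raw_points[idx, , drop = FALSE],
                         xi = sc$landmarks$xi)
      fit <- geovote(sc$image, lm, control = control,
                     truth = sc$truth_region)
      rows[[length(rows) + 1L]] <-
        data.frame(family = sc$descriptor$family, seed = sc$descriptor$seed,
                   count = cnt, score = fit$score, dice = fit$dice_standard)
    }
  }
  do.call(rbind, rows)
}
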