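uniform_cost <- function(n = 48L, n_angles = 32L, mu = 1) {
  feat <- compute_edge_features(matrix(0.5, n, n), sigma = 1)
  build_elastica_cost(feat, mu = mu, n_angles = n_angles)
}

test_that("straight travel under uniform cost has near-Euclidean energy", {
  cost <- uniform_cost(48)
  ld <- elastica_distance(cost, tau = 2, c(24, 14))
  expect_equal(min(ld$values[24, 34, ]), 20, tolerance = 0.03)
  p <- elastica_path_to_point(cost, tau = 2, c(24, 14), c(24, 34))
  expect_equal(p$points[1, ], c(24, 14))
  expect_equal(p$points[nrow(p$points), ], c(24, 34))
  expect_lt(max(abs(p$points[, 1] - 24)), 1.01)
})

test_that("elastica distance is monotone nondecreasing in tau", {
  cost <- uniform_cost(32)
  lds <- lapply(c(1, 2, 4), function(tau)
    elastica_distance(cost, tau, c(16, 16))$values)
  v1 <- apply(lds[[1]], c(1, 2), min)
  v2 <- apply(lds[[2]], c(1, 2), min)
  v4 <- apply(lds[[3]], c(1, 2), min)
  expect_true(all(v2 >= v1 - 1e-9))
  expect_true(all(v4 >= v2 - 1e-9))
  # a target requiring a turn grows with tau, and exceeds Euclidean length
  src <- c(16, 16)
  corner <- c(4, 4)
  d <- vapply(lds, function(v) min(v[corner[1], corner[2], ]), numeric(1))
  eu <- sqrt(sum((corner - src)^2))
  expect_true(all(diff(d) >= -1e-9))
  expect_gt(d[3], eu)
})

test_that("tau -> 0 reduces the lifted distance to the planar weighted distance", {
  # orientation-independent cost field: a smooth radial slowdown bump
  n <- 40L
  g <- image_grid(n, n)
  rr <- row(matrix(0, n, n)); cc <- col(matrix(0, n, n))
  s <- 0.5 + 0.8 * exp(-((rr - 14)^2 + (cc - 26)^2) / 60)
  nA <- 32L
  cost <- geovote:::new_metric_field(
    "elastica_cost", g,
    cost_by_angle = array(rep(s, nA), dim = c(n, n, nA)),
    angles = 2 * pi * (seq_len(nA) - 1) / nA, mu = 1, n_angles = nA)
  ld <- elastica_distance(cost, tau = 1e-3, c(20, 20))
  proj <- apply(ld$values, c(1, 2), min)
  dm <- solve_eikonal(isotropic_metric(g, s), c(20, 20), rho = 2L)
  fin <- dm$values > 1
  rel <- abs(proj - dm$values)[fin] / dm$values[fin]
  expect_lt(max(rel), 0.03)
})

test_that("lifted distances re-integrate exactly along their motion primitives", {
  cost <- uniform_cost(32, n_angles = 32)
  ld <- elastica_distance(cost, tau = 2, c(16, 16))
  for (ep in list(c(4, 28), c(28, 5), c(10, 10))) {
    a <- which.min(ld$values[ep[1], ep[2], ])
    bt <- geovote:::backtrack_lifted(ld, ep[1], ep[2], a)
    e <- geovote:::elastica_energy_of_chain(cost, 2, bt$points, bt$angles)
    expect_equal(e, bt$value, tolerance = 1e-6)
  }
})

test_that("elastica paths prefer a cheap circular ridge over the straight line", {
  n <- 48L
  d <- disk_image(n, radius = 14)
  feat <- compute_edge_features(d$image, sigma = 1)
  cost <- build_elastica_cost(feat, mu = 3, n_angles = 32)
  start <- c(24, 24)
  # a point on the ridge, a quarter turn away
  end <- c(24 + 14, 24)
  p <- elastica_path_to_point(cost, tau = 1, start, end)
  # energy of the returned path must not exceed the straight-line energy
  ld <- elastica_distance(cost, tau = 1, start)
  straight <- discrete_path(rbind(start, end))
  # integrate the straight line's elastica energy (kappa = 0, travel south)
  ang_s <- which.min(abs(cost$angles - 3 * pi / 2))
  phi_line <- vapply(seq_len(nrow(straight$points)), function(i) {
    q <- round(straight$points[i, ])
    cost$cost_by_angle[q[1], q[2], ang_s]
  }, numeric(1))
  e_straight <- sum((phi_line[-1] + phi_line[-length(phi_line)]) / 2 *
                      geovote:::segment_lengths(straight$points))
  expect_lte(min(ld$values[end[1], end[2], ]), e_straight * (1 + 1e-4))
  # re-integration bound for the returned path
  expect_lte(p$metric_length, 1.05 * min(ld$values[end[1], end[2], ]) + 1e-9)
})

test_that("boundary paths land on the arg-min boundary pixel", {
  cost <- uniform_cost(32)
  p <- elastica_path_to_boundary(cost, tau = 2, c(16, 18))
  ep <- p$points[nrow(p$points), ]
  expect_true(ep[1] %in% c(1, 32) || ep[2] %in% c(1, 32))
  # start offset towards the east edge exits east, near the straight line
  p2 <- elastica_path_to_boundary(cost, tau = 2, c(16, 26))
  ep2 <- p2$points[nrow(p2$points), ]
  expect_equal(ep2[2], 32)
  expect_lt(abs(ep2[1] - 16), 3)
  # exhaustive arg-min check against the lifted distance map
  ld <- elastica_distance(cost, tau = 2, c(16, 26))
  proj <- apply(ld$values, c(1, 2), min)
  bd <- grid_boundary(cost$grid)
  bvals <- proj[cbind(bd[, 1], bd[, 2])]
  expect_equal(proj[ep2[1], ep2[2]], min(bvals), tolerance = 1e-12)
  expect_error(elastica_path_to_boundary(cost, tau = 2, c(1, 5)), "boundary")
})
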