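test_that("constant-metric distances match the closed form within 2%", {
  g <- image_grid(101, 101)
  dm <- solve_eikonal(isotropic_metric(g, 1), c(51, 51))
  # spot value at displacement (30, 40): true distance 50
  expect_equal(dm$values[81, 91], 50, tolerance = 0.02)
  # all pixels at distance >= 20 within 2%
  eu <- sqrt((row(dm$values) - 51)^2 + (col(dm$values) - 51)^2)
  far <- eu >= 20
  expect_lt(max(abs(dm$values[far] - eu[far]) / eu[far]), 0.02)
  expect_equal(dm$values[51, 51], 0)
})

test_that("distances are 1-homogeneous in the speed", {
  g <- image_grid(64, 64)
  d1 <- solve_eikonal(isotropic_metric(g, 1), c(32, 32))
  d2 <- solve_eikonal(isotropic_metric(g, 2), c(32, 32))
  expect_equal(d2$values, 2 * d1$values, tolerance = 1e-9)
})

test_that("solver matches the dense-stencil Dijkstra oracle on random fields", {
  for (seed in 1:3) {
    m <- random_riemannian(24, 24, seed)
    dm <- solve_eikonal(m, c(12, 12))
    oracle <- oracle_dijkstra(m, matrix(c(12, 12), 1), rho = 5L)
    rel <- abs(dm$values - oracle) / pmax(oracle, 1e-9)
    expect_lt(max(rel[-(12 + 23 * 24)]), 0.03)
  }
  for (seed in 4:5) {
    m <- random_aq(24, 24, seed)
    dm <- solve_eikonal(m, c(5, 7))
    oracle <- oracle_dijkstra(m, matrix(c(5, 7), 1), rho = 5L)
    rel <- abs(dm$values - oracle) / pmax(oracle, 1e-9)
    expect_lt(max(rel[oracle > 0]), 0.03)
  }
})

test_that("asymmetric metrics give direction-dependent distances; omega = 0 restores symmetry", {
  g <- image_grid(32, 32)
  one <- matrix(1, 32, 32); zero <- matrix(0, 32, 32)
  aq <- geovote:::new_metric_field("asymmetric_quadratic", g,
                                   Mrr = one, Mrc = zero, Mcc = one,
                                   wr = zero, wc = one)  # penalize +col travel
  a <- c(16, 8); b <- c(16, 24)
  dab <- solve_eikonal(aq, a)$values[b[1], b[2]]
  dba <- solve_eikonal(aq, b)$values[a[1], a[2]]
  expect_gt(dab, dba * 1.2)
  # with omega aligned along +col, U grows faster towards +col
  dm <- solve_eikonal(aq, c(16, 16))
  expect_gt(dm$values[16, 26], dm$values[16, 6])

  aq0 <- geovote:::new_metric_field("asymmetric_quadratic", g,
                                    Mrr = one, Mrc = zero, Mcc = one,
                                    wr = zero, wc = zero)
  d0ab <- solve_eikonal(aq0, a)$values[b[1], b[2]]
  d0ba <- solve_eikonal(aq0, b)$values[a[1], a[2]]
  expect_equal(d0ab, d0ba, tolerance = 1e-9)
})

test_that("backtracked geodesics reach sources, respect obstacles, re-integrate their length", {
  g <- image_grid(32, 32)
  m <- isotropic_metric(g, 1)
  dm <- solve_eikonal(m, c(16, 6))
  p <- backtrack_geodesic(dm, c(16, 16))
  expect_equal(p$points[1, ], c(16, 6))
  expect_equal(p$points[nrow(p$points), ], c(16, 16))
  expect_equal(p$euclidean_length, 10, tolerance = 0.5)

  # wall with a single gap: path must thread the gap and never touch the wall
  wall <- matrix(FALSE, 32, 32); wall[20, ] <- TRUE; wall[20, 16] <- FALSE
  dmw <- solve_eikonal(m, c(10, 16), obstacles = wall)
  pw <- backtrack_geodesic(dmw, c(28, 16))
  ras <- which(as.matrix(rasterize_path(pw, g)))
  expect_length(intersect(ras, which(wall)), 0)
  expect_true(any(abs(pw$points[, 1] - 20) < 1 & abs(pw$points[, 2] - 16) < 1))
  # its length agrees with the distance value
  expect_equal(pw$euclidean_length, dmw$values[28, 16], tolerance = 0.02)
  expect_error(backtrack_geodesic(
    solve_eikonal(m, c(10, 16),
                  obstacles = {w2 <- wall; w2[20, 16] <- TRUE; w2}),
    c(28, 16)), "unreachable")

  # metric length of backtracked paths brackets the distance value
  for (seed in 6:8) {
    mr <- random_riemannian(24, 24, seed)
    dmr <- solve_eikonal(mr, c(3, 3))
    for (ep in list(c(20, 20), c(24, 4), c(10, 22))) {
      pp <- backtrack_geodesic(dmr, ep)
      tot <- path_metric_length(mr, pp$points)
      U <- dmr$values[ep[1], ep[2]]
      expect_gte(tot, U * 0.99)
      expect_lte(tot, U * 1.03)
    }
  }
})

test_that("distance maps are metric-Lipschitz across 8-neighbours", {
  m <- random_riemannian(24, 24, 9)
  dm <- solve_eikonal(m, c(12, 12))
  U <- dm$values
  for (o in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    r <- 1:(24 - abs(o[1])); c <- 1:(24 - abs(o[2]))
    r2 <- r + abs(o[1]); c2 <- if (o[2] >= 0) c + o[2] else c - o[2]
    for (i in seq(1, 23, by = 3)) for (j in seq(1, 23, by = 3)) {
      i2 <- i + o[1]; j2 <- j + o[2]
      if (i2 < 1 || i2 > 24 || j2 < 1 || j2 > 24) next
      w <- path_metric_length(m, rbind(c(i, j), c(i2, j2)))
      expect_lte(abs(U[i, j] - U[i2, j2]), w + 1e-9)
    }
  }
})

test_that("terminal directions follow the tangent of the travel", {
  east <- discrete_path(cbind(5, seq(1, 11, by = 0.5)))
  expect_equal(terminal_direction(east), c(0, 1), tolerance = 1e-6)

  qc <- quarter_circle_path()
  expect_equal(terminal_direction(qc), c(-1, 0), tolerance = 0.1)

  # two paths meeting head-on have near-antiparallel terminal directions
  west <- discrete_path(cbind(5, seq(21, 11, by = -0.5)))
  expect_lte(sum(terminal_direction(east) * terminal_direction(west)), -0.9)

  expect_error(terminal_direction(discrete_path(rbind(c(1, 1), c(1, 2)))),
               "too short")
})
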