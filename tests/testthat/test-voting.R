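test_that("farthest point sampling picks extremes with lexicographic ties", {
  g <- image_grid(16, 16)
  eps <- farthest_point_sampling(g, c(1, 1), K = 1)
  expect_equal(unname(eps$points[1, ]), c(16, 16))

  # seed = full central column: the first sample is a mid-row border pixel;
  # the lexicographic rule picks the left one
  seed <- cbind(1:16, 8)
  eps2 <- farthest_point_sampling(g, seed, K = 1)
  arg <- unname(eps2$points[1, ])
  dm <- solve_eikonal(isotropic_metric(g, 1), seed)
  expect_equal(dm$values[arg[1], arg[2]], max(dm$values), tolerance = 1e-12)
  cand <- which(dm$values == max(dm$values), arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  expect_equal(arg, unname(cand[1, ]))
})

test_that("farthest point distances are non-increasing along the sampling", {
  g <- image_grid(24, 24)
  eps <- farthest_point_sampling(g, rbind(c(12, 12)), K = 10)
  expect_equal(nrow(eps$points), 10)
  expect_true(all(diff(eps$dist_at_selection) <= 1e-9))
  # recompute each selection distance from scratch
  pts <- rbind(c(12, 12))
  for (k in 1:10) {
    dm <- solve_eikonal(isotropic_metric(g, 1), pts)
    q <- unname(eps$points[k, ])
    expect_equal(dm$values[q[1], q[2]], eps$dist_at_selection[k],
                 tolerance = 1e-9)
    expect_equal(dm$values[q[1], q[2]], max(dm$values), tolerance = 1e-9)
    pts <- rbind(pts, q)
  }
  expect_error(farthest_point_sampling(g, c(1, 1), K = 24 * 24 + 1), "K")
})

make_voting_fixture <- function(n = 64L, radius = 18) {
  d <- disk_image(n, radius = radius)
  feat <- compute_edge_features(d$image, sigma = 1)
  cost <- build_elastica_cost(feat, mu = 1, n_angles = 32)
  aq <- build_aq_metrics(feat, mu = 4, eta = 1)
  pj <- c(d$center[1] - radius, d$center[2])
  cut <- build_cut(d$center, pj, cost, tau = 2)
  list(d = d, feat = feat, cost = cost, aq = aq, cut = cut,
       grid = feat$grid)
}

test_that("symmetric metrics tie and the tie rule selects the first metric", {
  fx <- make_voting_fixture()
  aq0 <- build_aq_metrics(fx$feat, mu = 4, eta = 0)
  eps <- farthest_point_sampling(fx$grid,
                                 which(as.matrix(fx$cut$barrier),
                                       arr.ind = TRUE), K = 12)
  res <- competition_voting_paths(fx$cut, aq0, eps)
  expect_true(all(res$selected == 0L))
})

test_that("voting paths start at their offsets, end at endpoints, avoid the barrier", {
  fx <- make_voting_fixture()
  eps <- farthest_point_sampling(fx$grid,
                                 which(as.matrix(fx$cut$barrier),
                                       arr.ind = TRUE), K = 20)
  res <- competition_voting_paths(fx$cut, fx$aq, eps)
  barrier_idx <- which(as.matrix(fx$cut$barrier))
  q <- res$endpoints_used
  nright <- sum(res$side == "r")
  for (i in seq_along(res$paths)) {
    p <- res$paths[[i]]
    start <- p$points[1, ]
    off <- if (res$side[i] == "r") fx$cut$offset_r else fx$cut$offset_l
    expect_lt(sqrt(sum((start - off)^2)), 1 + 1e-9)
    k <- if (res$side[i] == "r") i else i - nright
    expect_equal(unname(p$points[nrow(p$points), ]), unname(q[k, ]))
    ras <- which(as.matrix(rasterize_path(p, fx$grid)))
    expect_length(intersect(ras, barrier_idx), 0)
  }
})

test_that("vote accumulation counts path coverage exactly", {
  g <- image_grid(16, 16)
  p1 <- discrete_path(cbind(8, 2:12))
  v1 <- accumulate_votes(list(list(p1)), g)
  expect_equal(sum(v1$total), 11)
  expect_equal(max(v1$total), 1)
  expect_equal(v1$n_paths, 1)

  v2 <- accumulate_votes(list(list(p1, p1)), g)
  expect_equal(max(v2$total), 2)
  expect_equal(sum(v2$total > 0), 11)

  # vote conservation across sources
  p2 <- discrete_path(cbind(2:12, 5))
  v3 <- accumulate_votes(list(list(p1), list(p2, p1)), g)
  expect_equal(v3$total, v3$per_source[[1]] + v3$per_source[[2]])
  expect_equal(sum(v3$per_source[[2]]),
               sum(as.matrix(rasterize_path(p2, g))) +
                 sum(as.matrix(rasterize_path(p1, g))))
  expect_error(accumulate_votes(list(list()), g), "at least one")
})

test_that("votes concentrate on the boundary band of a clean disk", {
  fx <- make_voting_fixture()
  eps <- farthest_point_sampling(fx$grid,
                                 which(as.matrix(fx$cut$barrier),
                                       arr.ind = TRUE), K = 50)
  res <- competition_voting_paths(fx$cut, fx$aq, eps)
  votes <- accumulate_votes(list(res$paths), fx$grid)
  expect_lte(max(votes$total), 2 * 50)
  rr <- row(votes$total); cc <- col(votes$total)
  dist_c <- sqrt((rr - fx$d$ctr[1])^2 + (cc - fx$d$ctr[2])^2)
  band <- abs(dist_c - fx$d$radius) <= 2
  far <- abs(dist_c - fx$d$radius) >= 5
  expect_gt(max(votes$total[band]), max(votes$total[far]))
})

test_that("the flow-consistency filter keeps antiparallel arrivals only", {
  east <- discrete_path(cbind(10, seq(1, 15, by = 0.5)))
  west <- discrete_path(cbind(10, seq(29, 15, by = -0.5)))
  north <- discrete_path(cbind(seq(24, 10, by = -0.5), 15))
  kept <- flow_consistency_filter(list(list(g0 = east, g1 = west)), -0.5)
  expect_true(kept$kept)
  expect_length(kept$paths, 2)
  dropped <- flow_consistency_filter(list(list(g0 = east, g1 = north)), -0.5)
  expect_false(dropped$kept)
  expect_length(dropped$paths, 0)
  # two halves of a circle meeting at the antipode arrive antiparallel
  th <- seq(0, pi, length.out = 80)
  upper <- discrete_path(cbind(16 - 10 * sin(th), 16 + 10 * cos(th)))
  lower <- discrete_path(cbind(16 + 10 * sin(th), 16 + 10 * cos(th)))
  both <- flow_consistency_filter(list(list(g0 = upper, g1 = lower)), -0.5)
  expect_lte(both$T, -0.9)
  expect_true(both$kept)
  expect_error(flow_consistency_filter(list(), 0.2), "zeta")
})
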