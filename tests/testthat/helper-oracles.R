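# Independent oracles used by the derived-value tests. Kept deliberately
# naive: plain-R Dijkstra with repeated linear-minimum selection, geometric
# cell-intersection rasterization, direct metric evaluation.

# Dense-stencil Dijkstra on a metric_field, matching the midpoint-averaged
# edge-weight contract but sharing no code with the package solver.
oracle_dijkstra <- function(metric, sources, rho = 5L, obstacle = NULL) {
  nr <- metric$grid$shape[[1]]; nc <- metric$grid$shape[[2]]
  gcd2 <- function(a, b) { while (b) { t <- a %% b; a <- b; b <- t }; a }
  offs <- list()
  for (dr in -rho:rho) for (dc in -rho:rho) {
    if (dr == 0 && dc == 0) next
    if (gcd2(abs(dr), abs(dc)) != 1) next
    offs[[length(offs) + 1L]] <- c(dr, dc)
  }
  weight <- function(p, q) oracle_edge_weight(metric, p, q)
  dist <- matrix(Inf, nr, nc)
  done <- matrix(FALSE, nr, nc)
  if (!is.null(obstacle)) done[as.matrix(obstacle)] <- TRUE
  for (k in seq_len(nrow(sources))) dist[sources[k, 1], sources[k, 2]] <- 0
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    i <- cand[which.min(dist[cand])]
    done[i] <- TRUE
    p <- c((i - 1L) %% nr + 1L, (i - 1L) %/% nr + 1L)
    for (o in offs) {
      q <- p + o
      if (q[1] < 1 || q[1] > nr || q[2] < 1 || q[2] > nc) next
      if (done[q[1], q[2]]) next
      nd <- dist[p[1], p[2]] + weight(p, q)
      if (nd < dist[q[1], q[2]]) dist[q[1], q[2]] <- nd
    }
  }
  dist
}

# Brute-force supercover: a pixel is covered iff some polyline segment
# intersects its closed unit cell, decided by dense sampling plus explicit
# segment/cell-edge checks.
oracle_supercover <- function(points, nr, nc) {
  hit <- matrix(FALSE, nr, nc)
  seg_rect <- function(p0, p1, r, c) {
    # closed-cell (touching counts) intersection via fine sampling of the
    # segment; the tolerance matches the sampling step, so test geometries
    # must keep true clearances well above 2e-3 px
    L <- max(sqrt(sum((p1 - p0)^2)), 1e-12)
    t <- seq(0, 1, length.out = max(2L, ceiling(L / 0.002)))
    pr <- p0[1] + t * (p1[1] - p0[1]); pc <- p0[2] + t * (p1[2] - p0[2])
    any(pr >= r - 0.5 - 2e-3 & pr <= r + 0.5 + 2e-3 &
        pc >= c - 0.5 - 2e-3 & pc <= c + 0.5 + 2e-3)
  }
  for (i in seq_len(nrow(points) - 1L)) {
    p0 <- points[i, ]; p1 <- points[i + 1L, ]
    for (r in max(1, floor(min(p0[1], p1[1])) - 1):min(nr, ceiling(max(p0[1], p1[1])) + 1))
      for (c in max(1, floor(min(p0[2], p1[2])) - 1):min(nc, ceiling(max(p0[2], p1[2])) + 1))
        if (!hit[r, c] && seg_rect(p0, p1, r, c)) hit[r, c] <- TRUE
  }
  hit
}

# Smooth random positive-definite tensor field for solver/oracle
# comparisons: eigenvalues in [0.6, 1.8], orientation varying on a scale of
# several pixels (the stencil contract assumes slowly varying fields).
random_riemannian <- function(nr, nc, seed) {
  set.seed(seed)
  smooth_field <- function() {
    m <- matrix(rnorm(nr * nc), nr, nc)
    k <- outer(dnorm(-6:6, sd = 3), dnorm(-6:6, sd = 3))
    f <- as.matrix(EBImage::filter2(m, k / sum(k), boundary = "replicate"))
    f / max(abs(f))
  }
  th <- smooth_field() * 1.5
  l1 <- 0.7 + 0.8 * stats::plogis(3 * smooth_field())
  l2 <- 0.7 + 0.8 * stats::plogis(3 * smooth_field())
  vr <- cos(th); vc <- sin(th)
  geovote:::new_metric_field("riemannian", image_grid(nr, nc),
    Mrr = l1 * vr^2 + l2 * vc^2,
    Mrc = (l1 - l2) * vr * vc,
    Mcc = l1 * vc^2 + l2 * vr^2, mu = 1)
}

random_aq <- function(nr, nc, seed, scale = 0.5) {
  m <- random_riemannian(nr, nc, seed)
  set.seed(seed + 1000)
  k <- outer(dnorm(-6:6, sd = 3), dnorm(-6:6, sd = 3)); k <- k / sum(k)
  sm <- function() {
    f <- as.matrix(EBImage::filter2(matrix(rnorm(nr * nc), nr, nc), k,
                                    boundary = "replicate"))
    f / max(abs(f))
  }
  geovote:::new_metric_field("asymmetric_quadratic", m$grid,
                             Mrr = m$Mrr, Mrc = m$Mrc, Mcc = m$Mcc,
                             wr = sm() * scale, wc = sm() * scale,
                             mu = 1, eta = scale)
}

# Line-integral edge weight between two points: midpoint quadrature over
# unit-length pieces with bilinear field interpolation (the solver
# contract's weight, written independently in R).
oracle_edge_weight <- function(metric, p, q) {
  e <- q - p
  len <- sqrt(sum(e^2))
  K <- max(1L, ceiling(len - 1e-9))
  bil <- function(f, r, c) {
    nr <- nrow(f); nc <- ncol(f)
    r0 <- min(max(floor(r), 1), nr - 1); c0 <- min(max(floor(c), 1), nc - 1)
    fr <- min(max(r - r0, 0), 1); fc <- min(max(c - c0, 0), 1)
    (1 - fr) * ((1 - fc) * f[r0, c0] + fc * f[r0, c0 + 1]) +
      fr * ((1 - fc) * f[r0 + 1, c0] + fc * f[r0 + 1, c0 + 1])
  }
  seg <- e / K
  tot <- 0
  for (k in seq_len(K)) {
    mid <- p + (k - 0.5) * seg
    if (metric$kind == "isotropic") {
      tot <- tot + bil(metric$speed, mid[1], mid[2]) * len / K
    } else {
      Mrr <- bil(metric$Mrr, mid[1], mid[2])
      Mrc <- bil(metric$Mrc, mid[1], mid[2])
      Mcc <- bil(metric$Mcc, mid[1], mid[2])
      v <- seg[1]^2 * Mrr + 2 * seg[1] * seg[2] * Mrc + seg[2]^2 * Mcc
      if (metric$kind == "asymmetric_quadratic") {
        s <- bil(metric$wr, mid[1], mid[2]) * seg[1] +
             bil(metric$wc, mid[1], mid[2]) * seg[2]
        if (s > 0) v <- v + s^2
      }
      tot <- tot + sqrt(max(v, 0))
    }
  }
  tot
}

# Discrete metric length of a polyline under the line-integral edge weight.
path_metric_length <- function(metric, pts) {
  tot <- 0
  for (i in seq_len(nrow(pts) - 1))
    tot <- tot + oracle_edge_weight(metric, pts[i, ], pts[i + 1, ])
  tot
}

# 8-connectivity check of a logical mask.
is_8_connected <- function(mask) {
  idx <- which(mask)
  if (length(idx) <= 1L) return(TRUE)
  nr <- nrow(mask)
  lab <- as.matrix(EBImage::bwlabel(matrix(as.numeric(mask), nr)))
  # bwlabel is 4-connected in EBImage? merge labels linked by 8-neighbours
  r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
  comp <- seq_along(idx)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  key <- paste(r, c)
  pos <- setNames(seq_along(idx), key)
  for (i in seq_along(idx))
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      j <- pos[paste(r[i] + dr, c[i] + dc)]
      if (!is.na(j)) { a <- find(i); b <- find(j); if (a != b) comp[a] <- b }
    }
  length(unique(vapply(seq_along(idx), find, integer(1)))) == 1L
}
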