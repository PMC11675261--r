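// Label-setting (Dijkstra) eikonal solvers on pixel grids, an
// orientation-lifted variant for curvature-penalized paths, farthest point
// sampling, and supercover polyline rasterization.
//
// Conventions shared with the R side:
//  - pixels are (row, col), 0-based here; R wrappers convert to 1-based;
//  - R-matrix linear index = r + nr*c (column-major); deterministic
//    tie-breaking uses lexicographic (row, col) rank = r*nc + c;
//  - a direction angle theta maps to the unit vector (dr, dc) =
//    (-sin theta, cos theta), so theta = 0 points along +col.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdlib>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct HeapNode {
  double d;
  int idx;   // linear storage index
  int rank;  // lexicographic (row, col) rank for deterministic ties
};
struct HeapCmp {
  bool operator()(const HeapNode& a, const HeapNode& b) const {
    if (a.d != b.d) return a.d > b.d;
    return a.rank > b.rank;
  }
};

static int igcd(int a, int b) {
  a = std::abs(a); b = std::abs(b);
  while (b) { int t = a % b; a = b; b = t; }
  return a;
}

static bool seg_hits_cell(double r0, double c0, double r1, double c1,
                          double rlo, double rhi, double clo, double chi);

// Primitive integer vectors within Chebyshev radius rho, with, per move,
// the intermediate cells its segment supercover touches (excluding the two
// endpoints). Moves are blocked when any such cell is an obstacle, so no
// path segment can hop over or graze an obstacle set.
static void make_stencil(int rho, std::vector<int>& sdr, std::vector<int>& sdc,
                         std::vector<double>& slen,
                         std::vector<std::vector<std::pair<int,int>>>* cross =
                           nullptr) {
  sdr.clear(); sdc.clear(); slen.clear();
  if (cross) cross->clear();
  for (int dr = -rho; dr <= rho; ++dr)
    for (int dc = -rho; dc <= rho; ++dc) {
      if (dr == 0 && dc == 0) continue;
      if (igcd(dr, dc) != 1) continue;
      sdr.push_back(dr); sdc.push_back(dc);
      slen.push_back(std::sqrt((double)(dr * dr + dc * dc)));
      if (cross) {
        std::vector<std::pair<int,int>> cells;
        for (int r = std::min(0, dr) - 1; r <= std::max(0, dr) + 1; ++r)
          for (int c = std::min(0, dc) - 1; c <= std::max(0, dc) + 1; ++c) {
            if ((r == 0 && c == 0) || (r == dr && c == dc)) continue;
            if (seg_hits_cell(0, 0, dr, dc,
                              r - 0.5, r + 0.5, c - 0.5, c + 0.5))
              cells.push_back({r, c});
          }
        cross->push_back(cells);
      }
    }
}

static inline bool move_blocked(const std::vector<std::pair<int,int>>& cells,
                                int r, int c, int nr, int nc,
                                const LogicalVector& obstacle) {
  for (const auto& rc : cells) {
    int rr = r + rc.first, cc = c + rc.second;
    if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
    if (obstacle[rr + nr * cc]) return true;
  }
  return false;
}

// Metric weight of the move from pixel a along e=(dr,dc): the line
// integral of the metric along the segment, by midpoint quadrature over
// ceil(len) equal pieces with bilinear field interpolation. kind:
// 0 isotropic, 1 Riemannian, 2 asymmetric quadratic (one-sided in the
// travel direction).
struct MetricData {
  int kind, nr, nc;
  const double *speed, *mrr, *mrc, *mcc, *wr, *wc;
};

static inline double bilin(const double* f, int nr, int nc,
                           double r, double c) {
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  if (r0 < 0) r0 = 0; if (r0 > nr - 2) r0 = nr - 2;
  if (c0 < 0) c0 = 0; if (c0 > nc - 2) c0 = nc - 2;
  double fr = r - r0, fc = c - c0;
  if (fr < 0) fr = 0; if (fr > 1) fr = 1;
  if (fc < 0) fc = 0; if (fc > 1) fc = 1;
  const double* p = f + r0 + nr * c0;
  return (1 - fr) * ((1 - fc) * p[0] + fc * p[nr]) +
         fr * ((1 - fc) * p[1] + fc * p[nr + 1]);
}

static inline double edge_weight(const MetricData& m, int ra, int ca,
                                 double dr, double dc, double len) {
  int K = (int)std::ceil(len - 1e-9);
  if (K < 1) K = 1;
  double tot = 0.0, seglen = len / K;
  double er = dr / K, ec = dc / K;
  for (int k = 0; k < K; ++k) {
    double r = ra + (k + 0.5) * er, c = ca + (k + 0.5) * ec;
    if (m.kind == 0) {
      tot += bilin(m.speed, m.nr, m.nc, r, c) * seglen;
    } else {
      double mrr = bilin(m.mrr, m.nr, m.nc, r, c);
      double mrc = bilin(m.mrc, m.nr, m.nc, r, c);
      double mcc = bilin(m.mcc, m.nr, m.nc, r, c);
      double q = er * (mrr * er + mrc * ec) + ec * (mrc * er + mcc * ec);
      if (m.kind == 2) {
        double s = bilin(m.wr, m.nr, m.nc, r, c) * er +
                   bilin(m.wc, m.nr, m.nc, r, c) * ec;
        if (s > 0) q += s * s;
      }
      tot += std::sqrt(q > 0 ? q : 0);
    }
  }
  return tot;
}

// [[Rcpp::export]]
List cpp_solve_grid(int nr, int nc, int kind,
                    NumericVector speed,
                    NumericVector mrr, NumericVector mrc, NumericVector mcc,
                    NumericVector wr, NumericVector wc,
                    IntegerMatrix sources, LogicalVector obstacle,
                    int rho, bool track_euclid) {
  const int n = nr * nc;
  std::vector<int> sdr, sdc; std::vector<double> slen;
  std::vector<std::vector<std::pair<int,int>>> cross;
  make_stencil(rho, sdr, sdc, slen, &cross);
  const int ns = (int)sdr.size();

  MetricData m;
  m.kind = kind; m.nr = nr; m.nc = nc;
  m.speed = speed.size() ? &speed[0] : nullptr;
  m.mrr = mrr.size() ? &mrr[0] : nullptr;
  m.mrc = mrc.size() ? &mrc[0] : nullptr;
  m.mcc = mcc.size() ? &mcc[0] : nullptr;
  m.wr = wr.size() ? &wr[0] : nullptr;
  m.wc = wc.size() ? &wc[0] : nullptr;

  const bool has_obs = obstacle.size() == n;
  NumericVector dist(n, INF);
  IntegerVector pred(n, -1);
  NumericVector eu(track_euclid ? n : 0, INF);

  std::priority_queue<HeapNode, std::vector<HeapNode>, HeapCmp> pq;
  for (int k = 0; k < sources.nrow(); ++k) {
    int r = sources(k, 0), c = sources(k, 1);
    int idx = r + nr * c;
    if (has_obs && obstacle[idx]) stop("source pixel lies on an obstacle");
    dist[idx] = 0.0;
    if (track_euclid) eu[idx] = 0.0;
    pq.push({0.0, idx, r * nc + c});
  }
  if (pq.empty()) stop("empty source set");

  std::vector<char> done(n, 0);
  while (!pq.empty()) {
    HeapNode top = pq.top(); pq.pop();
    if (done[top.idx]) continue;
    done[top.idx] = 1;
    int r = top.idx % nr, c = top.idx / nr;
    double d0 = dist[top.idx];
    for (int s = 0; s < ns; ++s) {
      int r2 = r + sdr[s], c2 = c + sdc[s];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      int idx2 = r2 + nr * c2;
      if (done[idx2]) continue;
      if (has_obs && (obstacle[idx2] ||
                      move_blocked(cross[s], r, c, nr, nc, obstacle)))
        continue;
      double w = edge_weight(m, r, c, (double)sdr[s], (double)sdc[s],
                             slen[s]);
      double nd = d0 + w;
      if (nd < dist[idx2] - 1e-12) {
        dist[idx2] = nd;
        pred[idx2] = top.idx;
        if (track_euclid) eu[idx2] = eu[top.idx] + slen[s];
        pq.push({nd, idx2, r2 * nc + c2});
      }
    }
  }

  return List::create(_["dist"] = dist, _["pred"] = pred, _["eu"] = eu);
}

// Orientation-lifted solver for the elastica energy. States are
// (pixel, angle bin); a motion primitive is a primitive integer move e
// within Chebyshev radius rho whose terminal orientation is the angle of e
// snapped to the nearest bin; its curvature is the wrapped orientation
// change divided by |e| and its cost is phi_mid * |e| * (1 + tau^2 kappa^2).
// phi is an (nr, nc, nA) array; state storage index = r + nr*(c + nc*a).
// [[Rcpp::export]]
List cpp_solve_lifted(int nr, int nc, int nA, NumericVector phi, double tau,
                      IntegerMatrix sources, LogicalVector obstacle, int rho) {
  const int npix = nr * nc;
  const int n = npix * nA;
  const double twopi = 2.0 * M_PI;
  const double abin = twopi / nA;

  std::vector<int> sdr, sdc; std::vector<double> slen;
  std::vector<std::vector<std::pair<int,int>>> cross;
  make_stencil(rho, sdr, sdc, slen, &cross);
  const int ns = (int)sdr.size();

  // per-move terminal angle bin
  std::vector<int> mbin(ns);
  for (int s = 0; s < ns; ++s) {
    double th = std::atan2(-(double)sdr[s], (double)sdc[s]);
    if (th < 0) th += twopi;
    int b = (int)std::lround(th / abin) % nA;
    mbin[s] = b;
  }
  // per (source bin a, move s): curvature term factor and midpoint bin
  std::vector<double> curv(nA * ns);
  std::vector<int> midb(nA * ns);
  for (int a = 0; a < nA; ++a)
    for (int s = 0; s < ns; ++s) {
      double dth = (mbin[s] - a) * abin;
      while (dth > M_PI) dth -= twopi;
      while (dth <= -M_PI) dth += twopi;
      double kap = dth / slen[s];
      curv[a * ns + s] = 1.0 + tau * tau * kap * kap;
      double thmid = a * abin + 0.5 * dth;
      int b = (int)std::lround(thmid / abin);
      b %= nA; if (b < 0) b += nA;
      midb[a * ns + s] = b;
    }

  const bool has_obs = obstacle.size() == npix;
  NumericVector dist(n, INF);
  IntegerVector pred(n, -1);
  const double* ph = &phi[0];

  std::priority_queue<HeapNode, std::vector<HeapNode>, HeapCmp> pq;
  for (int k = 0; k < sources.nrow(); ++k) {
    int r = sources(k, 0), c = sources(k, 1), a = sources(k, 2);
    int idx = r + nr * (c + nc * a);
    if (has_obs && obstacle[r + nr * c]) stop("source pixel lies on an obstacle");
    dist[idx] = 0.0;
    pq.push({0.0, idx, (r * nc + c) * nA + a});
  }
  if (pq.empty()) stop("empty source set");

  std::vector<char> done(n, 0);
  while (!pq.empty()) {
    HeapNode top = pq.top(); pq.pop();
    if (done[top.idx]) continue;
    done[top.idx] = 1;
    int pix = top.idx % npix;
    int a = top.idx / npix;
    int r = pix % nr, c = pix / nr;
    double d0 = dist[top.idx];
    for (int s = 0; s < ns; ++s) {
      int r2 = r + sdr[s], c2 = c + sdc[s];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      int pix2 = r2 + nr * c2;
      if (has_obs && (obstacle[pix2] ||
                      move_blocked(cross[s], r, c, nr, nc, obstacle)))
        continue;
      int a2 = mbin[s];
      int idx2 = pix2 + npix * a2;
      if (done[idx2]) continue;
      int bm = midb[a * ns + s];
      double pmid = 0.5 * (ph[pix + npix * bm] + ph[pix2 + npix * bm]);
      double nd = d0 + pmid * slen[s] * curv[a * ns + s];
      if (nd < dist[idx2] - 1e-12) {
        dist[idx2] = nd;
        pred[idx2] = top.idx;
        pq.push({nd, idx2, (r2 * nc + c2) * nA + a2});
      }
    }
  }

  return List::create(_["dist"] = dist, _["pred"] = pred);
}

// Farthest point sampling under the grid metric (incremental Dijkstra).
// Returns the K selected pixels (0-based) and the distance of each to the
// set existing at its selection. Ties in the argmax broken by lexicographic
// (row, col) order.
// [[Rcpp::export]]
List cpp_fps(int nr, int nc, NumericVector speed, IntegerMatrix seed,
             int K, int rho, LogicalVector obstacle) {
  const int n = nr * nc;
  std::vector<int> sdr, sdc; std::vector<double> slen;
  make_stencil(rho, sdr, sdc, slen);
  const int ns = (int)sdr.size();
  const bool has_obs = obstacle.size() == n;
  MetricData m; m.kind = 0; m.nr = nr; m.nc = nc; m.speed = &speed[0];
  m.mrr = m.mrc = m.mcc = m.wr = m.wc = nullptr;

  NumericVector dist(n, INF);
  std::priority_queue<HeapNode, std::vector<HeapNode>, HeapCmp> pq;

  auto relax_from = [&](void) {
    std::vector<char> done(n, 0);
    while (!pq.empty()) {
      HeapNode top = pq.top(); pq.pop();
      if (done[top.idx] || top.d > dist[top.idx] + 1e-15) continue;
      done[top.idx] = 1;
      int r = top.idx % nr, c = top.idx / nr;
      double d0 = dist[top.idx];
      for (int s = 0; s < ns; ++s) {
        int r2 = r + sdr[s], c2 = c + sdc[s];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        int idx2 = r2 + nr * c2;
        if (has_obs && obstacle[idx2]) continue;
        double nd = d0 + edge_weight(m, r, c, (double)sdr[s],
                                     (double)sdc[s], slen[s]);
        if (nd < dist[idx2] - 1e-12) {
          dist[idx2] = nd;
          pq.push({nd, idx2, r2 * nc + c2});
        }
      }
    }
  };

  for (int k = 0; k < seed.nrow(); ++k) {
    int idx = seed(k, 0) + nr * seed(k, 1);
    dist[idx] = 0.0;
    pq.push({0.0, idx, seed(k, 0) * nc + seed(k, 1)});
  }
  relax_from();

  IntegerMatrix pts(K, 2);
  NumericVector dsel(K);
  int navail = 0;
  for (int i = 0; i < n; ++i)
    if (std::isfinite(dist[i]) && dist[i] > 0) ++navail;
  if (K > navail) stop("K exceeds the number of reachable free pixels");

  for (int k = 0; k < K; ++k) {
    double best = -1.0; int br = -1, bc = -1;
    for (int r = 0; r < nr; ++r)       // row-major scan => lexicographic ties
      for (int c = 0; c < nc; ++c) {
        double d = dist[r + nr * c];
        if (std::isfinite(d) && d > best) { best = d; br = r; bc = c; }
      }
    if (br < 0) stop("no reachable pixel left for sampling");
    pts(k, 0) = br; pts(k, 1) = bc;
    dsel[k] = best;
    int idx = br + nr * bc;
    dist[idx] = 0.0;
    pq.push({0.0, idx, br * nc + bc});
    relax_from();
  }
  return List::create(_["points"] = pts, _["dist"] = dsel);
}

// Closed segment/rectangle intersection (Liang-Barsky with tolerance).
static bool seg_hits_cell(double r0, double c0, double r1, double c1,
                          double rlo, double rhi, double clo, double chi) {
  const double eps = 1e-9;
  double t0 = 0.0, t1 = 1.0;
  double dr = r1 - r0, dc = c1 - c0;
  double p[4] = {-dr, dr, -dc, dc};
  double q[4] = {r0 - rlo + eps, rhi - r0 + eps, c0 - clo + eps, chi - c0 + eps};
  for (int i = 0; i < 4; ++i) {
    if (std::fabs(p[i]) < 1e-15) {
      if (q[i] < 0) return false;
    } else {
      double t = q[i] / p[i];
      if (p[i] < 0) { if (t > t0) t0 = t; }
      else          { if (t < t1) t1 = t; }
    }
  }
  return t0 <= t1 + eps;
}

// Supercover rasterization of a polyline: every pixel whose closed unit cell
// [r-1/2, r+1/2] x [c-1/2, c+1/2] is touched by any segment. Points are
// (row, col), 0-based, subpixel. Returns 0-based linear indices (r + nr*c).
// [[Rcpp::export]]
IntegerVector cpp_supercover(NumericMatrix pts, int nr, int nc) {
  std::vector<char> seen((size_t)nr * nc, 0);
  std::vector<int> out;
  const int np = pts.nrow();
  for (int i = 0; i + 1 < np || (np == 1 && i == 0); ++i) {
    double r0 = pts(i, 0), c0 = pts(i, 1);
    double r1 = (np == 1) ? r0 : pts(i + 1, 0);
    double c1 = (np == 1) ? c0 : pts(i + 1, 1);
    int rlo = (int)std::floor(std::min(r0, r1) - 0.5) - 1;
    int rhi = (int)std::ceil(std::max(r0, r1) + 0.5) + 1;
    int clo = (int)std::floor(std::min(c0, c1) - 0.5) - 1;
    int chi = (int)std::ceil(std::max(c0, c1) + 0.5) + 1;
    if (rlo < 0) rlo = 0; if (clo < 0) clo = 0;
    if (rhi >= nr) rhi = nr - 1; if (chi >= nc) chi = nc - 1;
    for (int r = rlo; r <= rhi; ++r)
      for (int c = clo; c <= chi; ++c) {
        size_t idx = (size_t)r + (size_t)nr * c;
        if (seen[idx]) continue;
        if (seg_hits_cell(r0, c0, r1, c1, r - 0.5, r + 0.5, c - 0.5, c + 0.5)) {
          seen[idx] = 1;
          out.push_back((int)idx);
        }
      }
    if (np == 1) break;
  }
  return wrap(out);
}
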