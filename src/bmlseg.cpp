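#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Polygon rasterization (even-odd ray cast, pixel centers at 0-based coords)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalMatrix cpp_polygon_fill(NumericVector px, NumericVector py,
                               int nx, int ny) {
  int n = px.size();
  LogicalMatrix out(nx, ny);
  for (int i = 0; i < nx; ++i) {
    double x = (double)i;
    for (int j = 0; j < ny; ++j) {
      double y = (double)j;
      bool inside = false;
      for (int a = 0, b = n - 1; a < n; b = a++) {
        if (((py[a] > y) != (py[b] > y)) &&
            (x < (px[b] - px[a]) * (y - py[a]) / (py[b] - py[a]) + px[a]))
          inside = !inside;
      }
      out(i, j) = inside;
    }
  }
  return out;
}

static inline double cross2(double ox, double oy, double ax, double ay,
                            double bx, double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

static bool seg_intersect(double p1x, double p1y, double p2x, double p2y,
                          double q1x, double q1y, double q2x, double q2y) {
  double d1 = cross2(q1x, q1y, q2x, q2y, p1x, p1y);
  double d2 = cross2(q1x, q1y, q2x, q2y, p2x, p2y);
  double d3 = cross2(p1x, p1y, p2x, p2y, q1x, q1y);
  double d4 = cross2(p1x, p1y, p2x, p2y, q2x, q2y);
  return ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
         ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0));
}

// proper self-intersection of the closed polygon (adjacent segments skipped)
// [[Rcpp::export]]
bool cpp_self_intersects(NumericVector px, NumericVector py) {
  int n = px.size();
  if (n < 4) return false;
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    for (int j = i + 2; j < n; ++j) {
      int j2 = (j + 1) % n;
      if (j2 == i) continue;  // wrap-around adjacency
      if (seg_intersect(px[i], py[i], px[i2], py[i2],
                        px[j], py[j], px[j2], py[j2]))
        return true;
    }
  }
  return false;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing (replicate padding), sigma in pixels per axis
// ---------------------------------------------------------------------------

static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    s += k[i + r];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;
  return k;
}

// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix img, double sigma_x,
                                double sigma_y) {
  int nx = img.nrow(), ny = img.ncol();
  NumericMatrix tmp(nx, ny), out(nx, ny);
  if (sigma_x > 0) {
    std::vector<double> kx = gauss_kernel(sigma_x);
    int r = ((int)kx.size() - 1) / 2;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double s = 0.0;
        for (int o = -r; o <= r; ++o) {
          int ii = i + o;
          if (ii < 0) ii = 0;
          if (ii >= nx) ii = nx - 1;
          s += kx[o + r] * img(ii, j);
        }
        tmp(i, j) = s;
      }
  } else {
    tmp = clone(img);
  }
  if (sigma_y > 0) {
    std::vector<double> ky = gauss_kernel(sigma_y);
    int r = ((int)ky.size() - 1) / 2;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double s = 0.0;
        for (int o = -r; o <= r; ++o) {
          int jj = j + o;
          if (jj < 0) jj = 0;
          if (jj >= ny) jj = ny - 1;
          s += ky[o + r] * tmp(i, jj);
        }
        out(i, j) = s;
      }
  } else {
    out = clone(tmp);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Morphological geodesic active contour (2D, balloon off)
// ---------------------------------------------------------------------------

// curvature morphology: sup-inf / inf-sup over 4 line segments of length 3
static const int LINES[4][2][2] = {
  {{0, -1}, {0, 1}}, {{-1, 0}, {1, 0}}, {{-1, -1}, {1, 1}}, {{-1, 1}, {1, -1}}};

static IntegerMatrix op_SI(const IntegerMatrix& u) {
  int nx = u.nrow(), ny = u.ncol();
  IntegerMatrix out(nx, ny);
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j) {
      if (i == 0 || j == 0 || i == nx - 1 || j == ny - 1) {
        out(i, j) = u(i, j);
        continue;
      }
      int best = 0;
      for (int l = 0; l < 4 && best == 0; ++l) {
        int a = u(i + LINES[l][0][0], j + LINES[l][0][1]);
        int b = u(i + LINES[l][1][0], j + LINES[l][1][1]);
        int v = u(i, j);
        int m = std::min(v, std::min(a, b));
        if (m > best) best = m;
      }
      out(i, j) = best;
    }
  return out;
}

static IntegerMatrix op_IS(const IntegerMatrix& u) {
  int nx = u.nrow(), ny = u.ncol();
  IntegerMatrix out(nx, ny);
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j) {
      if (i == 0 || j == 0 || i == nx - 1 || j == ny - 1) {
        out(i, j) = u(i, j);
        continue;
      }
      int best = 1;
      for (int l = 0; l < 4 && best == 1; ++l) {
        int a = u(i + LINES[l][0][0], j + LINES[l][0][1]);
        int b = u(i + LINES[l][1][0], j + LINES[l][1][1]);
        int v = u(i, j);
        int m = std::max(v, std::max(a, b));
        if (m < best) best = m;
      }
      out(i, j) = best;
    }
  return out;
}

// [[Rcpp::export]]
List cpp_morph_gac(IntegerMatrix init, NumericMatrix g, int max_iters,
                   double tol, int smoothing) {
  int nx = init.nrow(), ny = init.ncol();
  NumericMatrix dgx(nx, ny), dgy(nx, ny);
  for (int i = 1; i < nx - 1; ++i)
    for (int j = 1; j < ny - 1; ++j) {
      dgx(i, j) = 0.5 * (g(i + 1, j) - g(i - 1, j));
      dgy(i, j) = 0.5 * (g(i, j + 1) - g(i, j - 1));
    }
  IntegerMatrix u = clone(init);
  for (int i = 0; i < nx; ++i) { u(i, 0) = 0; u(i, ny - 1) = 0; }
  for (int j = 0; j < ny; ++j) { u(0, j) = 0; u(nx - 1, j) = 0; }
  int si_toggle = 0, consec = 0, it = 0;
  bool converged = false;
  std::vector<unsigned long long> hist;  // state hashes for cycle detection
  for (it = 1; it <= max_iters; ++it) {
    IntegerMatrix u_prev = clone(u);
    // image attachment: move boundary along grad(g)
    IntegerMatrix unew = clone(u);
    for (int i = 1; i < nx - 1; ++i)
      for (int j = 1; j < ny - 1; ++j) {
        double dux = 0.5 * (double)(u(i + 1, j) - u(i - 1, j));
        double duy = 0.5 * (double)(u(i, j + 1) - u(i, j - 1));
        if (dux == 0.0 && duy == 0.0) continue;
        double aux = dgx(i, j) * dux + dgy(i, j) * duy;
        if (aux > 0) unew(i, j) = 1;
        else if (aux < 0) unew(i, j) = 0;
      }
    u = unew;
    // curvature smoothing
    for (int s = 0; s < smoothing; ++s) {
      if (si_toggle % 2 == 0) u = op_SI(op_IS(u));
      else u = op_IS(op_SI(u));
      ++si_toggle;
    }
    long changed = 0, area = 0;
    unsigned long long h = 1469598103934665603ULL;  // FNV-1a over the state
    for (int i = 0; i < nx; ++i)
      for (int j = 0; j < ny; ++j) {
        if (u(i, j) != u_prev(i, j)) ++changed;
        if (u(i, j)) ++area;
        h ^= (unsigned long long)(u(i, j) + 1);
        h *= 1099511628211ULL;
      }
    if (area == 0) break;
    if (changed == 0) { converged = true; break; }
    // morphological updates can settle into short limit cycles: treat a
    // revisited state within the recent history as converged
    bool cycled = false;
    for (size_t q = 0; q < hist.size(); ++q)
      if (hist[q] == h) { cycled = true; break; }
    if (cycled) { converged = true; break; }
    hist.push_back(h);
    if (hist.size() > 8) hist.erase(hist.begin());
    if ((double)changed < tol * (double)area) {
      if (++consec >= 5) { converged = true; break; }
    } else {
      consec = 0;
    }
  }
  return List::create(_["u"] = u, _["iters"] = it, _["converged"] = converged);
}

// keep the foreground component (8-conn) with most overlap with init; fill
// holes (background 4-conn components not touching the image border)
// [[Rcpp::export]]
IntegerMatrix cpp_clean_slice(IntegerMatrix u, IntegerMatrix init) {
  int nx = u.nrow(), ny = u.ncol();
  IntegerMatrix lab(nx, ny);
  int nlab = 0;
  std::vector<long> overlap(1, 0), size(1, 0);
  const int dx8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dy8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j) {
      if (!u(i, j) || lab(i, j)) continue;
      ++nlab;
      overlap.push_back(0);
      size.push_back(0);
      std::queue<std::pair<int, int> > q;
      q.push(std::make_pair(i, j));
      lab(i, j) = nlab;
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        ++size[nlab];
        if (init(p.first, p.second)) ++overlap[nlab];
        for (int d = 0; d < 8; ++d) {
          int a = p.first + dx8[d], b = p.second + dy8[d];
          if (a < 0 || b < 0 || a >= nx || b >= ny) continue;
          if (u(a, b) && !lab(a, b)) {
            lab(a, b) = nlab;
            q.push(std::make_pair(a, b));
          }
        }
      }
    }
  if (nlab == 0) return IntegerMatrix(nx, ny);
  int keep = 1;
  for (int l = 2; l <= nlab; ++l)
    if (overlap[l] > overlap[keep] ||
        (overlap[l] == overlap[keep] && size[l] > size[keep]))
      keep = l;
  IntegerMatrix out(nx, ny);
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j) out(i, j) = (lab(i, j) == keep) ? 1 : 0;
  // hole fill: 4-conn background flood from border
  IntegerMatrix bg(nx, ny);
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < nx; ++i) {
    if (!out(i, 0)) { bg(i, 0) = 1; q.push(std::make_pair(i, 0)); }
    if (!out(i, ny - 1)) { bg(i, ny - 1) = 1; q.push(std::make_pair(i, ny - 1)); }
  }
  for (int j = 0; j < ny; ++j) {
    if (!out(0, j) && !bg(0, j)) { bg(0, j) = 1; q.push(std::make_pair(0, j)); }
    if (!out(nx - 1, j) && !bg(nx - 1, j)) {
      bg(nx - 1, j) = 1;
      q.push(std::make_pair(nx - 1, j));
    }
  }
  const int dx4[4] = {1, -1, 0, 0};
  const int dy4[4] = {0, 0, 1, -1};
  while (!q.empty()) {
    std::pair<int, int> p = q.front();
    q.pop();
    for (int d = 0; d < 4; ++d) {
      int a = p.first + dx4[d], b = p.second + dy4[d];
      if (a < 0 || b < 0 || a >= nx || b >= ny) continue;
      if (!out(a, b) && !bg(a, b)) {
        bg(a, b) = 1;
        q.push(std::make_pair(a, b));
      }
    }
  }
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j)
      if (!out(i, j) && !bg(i, j)) out(i, j) = 1;
  return out;
}

// ---------------------------------------------------------------------------
// Min s-t cut on a pixel graph (Dinic max-flow), used by the narrow-band
// region-based curve evolution: node v pays cap_s[v] when labelled 0 and
// cap_t[v] when labelled 1; neighbour pairs pay cap_pair when discordant.
// Returns TRUE for nodes on the source side (label 1) of a minimum cut.
// ---------------------------------------------------------------------------

struct DinicGraph {
  std::vector<int> to, nxt, head, level, it;
  std::vector<double> cap;
  int n;
  explicit DinicGraph(int n_) : head(n_, -1), n(n_) {}
  void add_edge(int u, int v, double c, double c_rev) {
    to.push_back(v); cap.push_back(c); nxt.push_back(head[u]);
    head[u] = (int)to.size() - 1;
    to.push_back(u); cap.push_back(c_rev); nxt.push_back(head[v]);
    head[v] = (int)to.size() - 1;
  }
  bool bfs(int s, int t) {
    level.assign(n, -1);
    std::queue<int> q;
    level[s] = 0;
    q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int e = head[u]; e != -1; e = nxt[e])
        if (cap[e] > 1e-12 && level[to[e]] < 0) {
          level[to[e]] = level[u] + 1;
          q.push(to[e]);
        }
    }
    return level[t] >= 0;
  }
  double dfs(int u, int t, double f) {
    if (u == t) return f;
    for (int &e = it[u]; e != -1; e = nxt[e]) {
      int v = to[e];
      if (cap[e] > 1e-12 && level[v] == level[u] + 1) {
        double d = dfs(v, t, std::min(f, cap[e]));
        if (d > 0) { cap[e] -= d; cap[e ^ 1] += d; return d; }
      }
    }
    return 0;
  }
  void maxflow(int s, int t) {
    while (bfs(s, t)) {
      it = head;
      while (dfs(s, t, R_PosInf) > 0) {}
    }
  }
};

// [[Rcpp::export]]
LogicalVector cpp_mincut(int n, NumericVector cap_s, NumericVector cap_t,
                         IntegerVector pa, IntegerVector pb,
                         double cap_pair) {
  int s = n, t = n + 1;
  DinicGraph G(n + 2);
  for (int v = 0; v < n; ++v) {
    if (cap_s[v] > 0) G.add_edge(s, v, cap_s[v], 0.0);
    if (cap_t[v] > 0) G.add_edge(v, t, cap_t[v], 0.0);
  }
  for (int e = 0; e < pa.size(); ++e)
    G.add_edge(pa[e] - 1, pb[e] - 1, cap_pair, cap_pair);
  G.maxflow(s, t);
  // source side of the residual graph
  LogicalVector lab(n, false);
  std::vector<char> vis(n + 2, 0);
  std::queue<int> q;
  vis[s] = 1;
  q.push(s);
  while (!q.empty()) {
    int u = q.front(); q.pop();
    for (int e = G.head[u]; e != -1; e = G.nxt[e])
      if (G.cap[e] > 1e-12 && !vis[G.to[e]]) {
        vis[G.to[e]] = 1;
        q.push(G.to[e]);
      }
  }
  for (int v = 0; v < n; ++v) lab[v] = vis[v] != 0;
  return lab;
}

// discrete two-phase energy at the current labelling (class means refit)
// [[Rcpp::export]]
double cpp_cv_energy(NumericVector I, IntegerVector domain, IntegerVector u,
                     IntegerVector dims, double mu) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  double S1 = 0, S0 = 0, Sall = 0;
  long n1 = 0, n0 = 0, ndom = 0;
  for (long v = 0; v < n; ++v) {
    if (!domain[v]) continue;
    ++ndom;
    Sall += I[v];
    if (u[v]) { S1 += I[v]; ++n1; }
    else { S0 += I[v]; ++n0; }
  }
  if (ndom == 0) return 0.0;
  double cbar = Sall / (double)ndom;
  double c1 = (n1 > 0) ? S1 / (double)n1 : cbar;
  double c0 = (n0 > 0) ? S0 / (double)n0 : cbar;
  double E = 0.0;
  const long strx = 1, stry = nx;
  for (long v = 0; v < n; ++v) {
    if (!domain[v]) continue;
    double d = I[v] - (u[v] ? c1 : c0);
    E += d * d;
    int i = (int)(v % nx);
    int j = (int)((v / nx) % ny);
    if (i < nx - 1 && domain[v + strx] && u[v] != u[v + strx]) E += mu;
    if (j < ny - 1 && domain[v + stry] && u[v] != u[v + stry]) E += mu;
  }
  return E;
}

// in-plane 4-neighbour discordant-pair count within domain (boundary length)
// [[Rcpp::export]]
double cpp_perimeter(IntegerVector domain, IntegerVector u, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  const long strx = 1, stry = nx;
  long P = 0;
  for (long v = 0; v < n; ++v) {
    if (!domain[v]) continue;
    int i = (int)(v % nx);
    int j = (int)((v / nx) % ny);
    if (i < nx - 1 && domain[v + strx] && u[v] != u[v + strx]) ++P;
    if (j < ny - 1 && domain[v + stry] && u[v] != u[v + stry]) ++P;
  }
  return (double)P;
}

// ---------------------------------------------------------------------------
// 3D connected components (6- or 26-connectivity), BFS labelling
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dims,
                          int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<long> offs;
  std::vector<int> odx, ody, odz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        odx.push_back(dx);
        ody.push_back(dy);
        odz.push_back(dz);
      }
  int nlab = 0;
  std::queue<long> q;
  for (long v = 0; v < n; ++v) {
    if (!mask[v] || lab[v]) continue;
    ++nlab;
    lab[v] = nlab;
    q.push(v);
    while (!q.empty()) {
      long w = q.front();
      q.pop();
      int i = (int)(w % nx);
      int j = (int)((w / nx) % ny);
      int k = (int)(w / ((long)nx * ny));
      for (size_t d = 0; d < odx.size(); ++d) {
        int a = i + odx[d], b = j + ody[d], c = k + odz[d];
        if (a < 0 || b < 0 || c < 0 || a >= nx || b >= ny || c >= nz) continue;
        long w2 = (long)a + (long)nx * ((long)b + (long)ny * c);
        if (mask[w2] && !lab[w2]) {
          lab[w2] = nlab;
          q.push(w2);
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Minimum pairwise anisotropic (world-mm) distance between two voxel sets
// (coordinates are voxel indices, any consistent base)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_min_dist_mm(NumericMatrix A, NumericMatrix B, NumericVector spacing) {
  double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  double best = R_PosInf;
  for (int i = 0; i < A.nrow(); ++i) {
    for (int j = 0; j < B.nrow(); ++j) {
      double ddx = (A(i, 0) - B(j, 0)) * dx;
      double ddy = (A(i, 1) - B(j, 1)) * dy;
      double ddz = (A(i, 2) - B(j, 2)) * dz;
      double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (d2 < best) {
        best = d2;
        if (best == 0.0) return 0.0;
      }
    }
  }
  return std::sqrt(best);
}
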