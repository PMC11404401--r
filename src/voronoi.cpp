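// Periodic Voronoi tessellation by per-cell half-plane clipping.
//
// Each cell is built in coordinates relative to its generator: start from a
// rectangle strictly larger than the periodic box and clip by the bisector
// half-plane of every other generator image, in order of increasing distance.
// Once the squared distance of the next candidate exceeds four times the
// squared radius of the farthest polygon vertex, no further candidate can cut
// the polygon, so the cell is complete (the classic security-radius bound).
// The generator's own periodic images take part in the clipping; if one of
// them contributes an edge, the cell wraps around the box and the input is
// rejected.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <map>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

inline double wrap01(double x, double L) {
  double y = x - L * std::floor(x / L);
  return (y >= L) ? y - L : y;
}

struct Cand {
  double d2;
  int j;        // generator index (0-based)
  double qx, qy; // position relative to the cell's generator
};

struct Poly {
  std::vector<double> x, y; // vertices, CCW
  std::vector<int> lab;     // lab[k]: generator that produced edge k->k+1 (-2 = bounding box)
};

inline bool cand_less(const Cand &a, const Cand &b) {
  if (a.d2 != b.d2) return a.d2 < b.d2;
  return a.j < b.j;
}

// Clip polygon by { p : p . q <= d2 / 2 }. Points on the plane (within eps)
// count as inside, so grazing bisectors (vertex-only contacts) do not edit the
// polygon; those contacts are recovered from shared vertices afterwards.
void clip(Poly &P, double qx, double qy, double d2, int label) {
  const size_t m = P.x.size();
  if (m == 0) return;
  const double half = 0.5 * d2;
  const double eps = 1e-12 * d2 + 1e-300;
  std::vector<double> s(m);
  bool any_out = false, any_in = false;
  for (size_t k = 0; k < m; ++k) {
    s[k] = P.x[k] * qx + P.y[k] * qy - half;
    if (s[k] > eps) any_out = true; else any_in = true;
  }
  if (!any_out) return;
  Poly out;
  out.x.reserve(m + 2); out.y.reserve(m + 2); out.lab.reserve(m + 2);
  if (!any_in) { P = out; return; }
  for (size_t k = 0; k < m; ++k) {
    size_t k2 = (k + 1) % m;
    bool ain = s[k] <= eps, bin = s[k2] <= eps;
    if (ain && bin) {
      out.x.push_back(P.x[k]); out.y.push_back(P.y[k]); out.lab.push_back(P.lab[k]);
    } else if (ain && !bin) {
      out.x.push_back(P.x[k]); out.y.push_back(P.y[k]); out.lab.push_back(P.lab[k]);
      double t = s[k] / (s[k] - s[k2]);
      out.x.push_back(P.x[k] + t * (P.x[k2] - P.x[k]));
      out.y.push_back(P.y[k] + t * (P.y[k2] - P.y[k]));
      out.lab.push_back(label);
    } else if (!ain && bin) {
      double t = s[k] / (s[k] - s[k2]);
      out.x.push_back(P.x[k] + t * (P.x[k2] - P.x[k]));
      out.y.push_back(P.y[k] + t * (P.y[k2] - P.y[k]));
      out.lab.push_back(P.lab[k]);
    }
  }
  P = out;
}

double max_r2(const Poly &P) {
  double m = 0.0;
  for (size_t k = 0; k < P.x.size(); ++k) {
    double r2 = P.x[k] * P.x[k] + P.y[k] * P.y[k];
    if (r2 > m) m = r2;
  }
  return m;
}

// Merge consecutive vertices closer than tol. A sub-tolerance edge is a
// grazing (vertex-only) contact: its label is dropped here and the contact is
// recovered by the shared-vertex pass.
void dedupe(Poly &P, double tol) {
  const size_t m = P.x.size();
  if (m < 3) return;
  Poly out;
  for (size_t k = 0; k < m; ++k) {
    if (!out.x.empty()) {
      double dx = P.x[k] - out.x.back(), dy = P.y[k] - out.y.back();
      if (std::sqrt(dx * dx + dy * dy) < tol) {
        // tiny edge out.back -> v[k]: keep out.back, its outgoing edge is now
        // the edge that started at v[k]
        out.lab.back() = P.lab[k];
        continue;
      }
    }
    out.x.push_back(P.x[k]); out.y.push_back(P.y[k]); out.lab.push_back(P.lab[k]);
  }
  while (out.x.size() >= 3) {
    double dx = out.x.front() - out.x.back(), dy = out.y.front() - out.y.back();
    if (std::sqrt(dx * dx + dy * dy) < tol) {
      out.x.pop_back(); out.y.pop_back(); out.lab.pop_back();
    } else break;
  }
  P = out;
}

struct Grid {
  int nx, ny;
  double cw, ch, Lx, Ly;
  std::vector<std::vector<int>> bins;
  Grid(const NumericMatrix &pts, double Lx_, double Ly_, double target) {
    Lx = Lx_; Ly = Ly_;
    nx = std::max(1, (int)std::floor(Lx / target));
    ny = std::max(1, (int)std::floor(Ly / target));
    cw = Lx / nx; ch = Ly / ny;
    bins.assign((size_t)nx * ny, {});
    for (int i = 0; i < pts.nrow(); ++i) {
      double x = wrap01(pts(i, 0), Lx);
      double y = wrap01(pts(i, 1), Ly);
      int bx = std::min(nx - 1, (int)(x / cw));
      int by = std::min(ny - 1, (int)(y / ch));
      bins[(size_t)by * nx + bx].push_back(i);
    }
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_voronoi(NumericMatrix pts, double Lx, double Ly, double tol) {
  const int n = pts.nrow();
  if (n < 1) stop("no generators supplied");
  const double scale = std::max(Lx, Ly);
  const double tol_len = tol; // absolute merge tolerance on coordinates

  // wrapped copies of the generators
  std::vector<double> px(n), py(n);
  for (int i = 0; i < n; ++i) {
    double x = wrap01(pts(i, 0), Lx);
    double y = wrap01(pts(i, 1), Ly);
    px[i] = x; py[i] = y;
  }

  const double spacing = std::sqrt(Lx * Ly / n);
  const bool brute = (n <= 512);
  Grid *grid = nullptr;
  if (!brute) grid = new Grid(pts, Lx, Ly, std::max(spacing, scale / 64.0));

  std::vector<std::map<int, double>> adj(n);
  List verts(n);
  NumericVector area(n), perim(n);
  NumericMatrix centroid(n, 2);

  // all cell vertices, wrapped, for the shared-vertex pass
  std::vector<double> vx_all, vy_all;
  std::vector<int> vcell;

  for (int i = 0; i < n; ++i) {
    std::vector<Cand> cands;
    if (brute) {
      for (int j = 0; j < n; ++j)
        for (int sx = -1; sx <= 1; ++sx)
          for (int sy = -1; sy <= 1; ++sy) {
            if (j == i && sx == 0 && sy == 0) continue;
            double qx = px[j] + sx * Lx - px[i];
            double qy = py[j] + sy * Ly - py[i];
            double d2 = qx * qx + qy * qy;
            if (j != i && d2 < tol_len * tol_len)
              stop("duplicate generators (points %d and %d coincide under minimum image)",
                   i + 1, j + 1);
            cands.push_back({d2, j, qx, qy});
          }
    } else {
      // gather within an expanding radius using the grid
      double R = 4.0 * spacing;
      bool done = false;
      while (!done) {
        cands.clear();
        // own periodic images are always candidates
        for (int sx = -1; sx <= 1; ++sx)
          for (int sy = -1; sy <= 1; ++sy) {
            if (sx == 0 && sy == 0) continue;
            double qx = sx * Lx, qy = sy * Ly;
            cands.push_back({qx * qx + qy * qy, i, qx, qy});
          }
        int rx = (int)std::ceil(R / grid->cw) + 1;
        int ry = (int)std::ceil(R / grid->ch) + 1;
        int bx0 = (int)(px[i] / grid->cw), by0 = (int)(py[i] / grid->ch);
        if (2 * rx + 1 >= grid->nx || 2 * ry + 1 >= grid->ny) {
          // fall back to all points
          for (int j = 0; j < n; ++j)
            for (int sx = -1; sx <= 1; ++sx)
              for (int sy = -1; sy <= 1; ++sy) {
                if (j == i && sx == 0 && sy == 0) continue;
                double qx = px[j] + sx * Lx - px[i];
                double qy = py[j] + sy * Ly - py[i];
                cands.push_back({qx * qx + qy * qy, j, qx, qy});
              }
          R = 2.0 * scale; // everything gathered
        } else {
          for (int bx = bx0 - rx; bx <= bx0 + rx; ++bx)
            for (int by = by0 - ry; by <= by0 + ry; ++by) {
              int wx = ((bx % grid->nx) + grid->nx) % grid->nx;
              int wy = ((by % grid->ny) + grid->ny) % grid->ny;
              double shx = std::floor((double)bx / grid->nx) * Lx;
              double shy = std::floor((double)by / grid->ny) * Ly;
              for (int j : grid->bins[(size_t)wy * grid->nx + wx]) {
                if (j == i && shx == 0.0 && shy == 0.0) continue;
                double qx = px[j] + shx - px[i];
                double qy = py[j] + shy - py[i];
                double d2 = qx * qx + qy * qy;
                if (d2 > R * R) continue;
                if (j != i && d2 < tol_len * tol_len)
                  stop("duplicate generators (points %d and %d coincide under minimum image)",
                       i + 1, j + 1);
                cands.push_back({d2, j, qx, qy});
              }
            }
        }
        std::sort(cands.begin(), cands.end(), cand_less);
        // tentative clip to test the security radius against R
        Poly P;
        double hw = 0.6 * Lx, hh = 0.6 * Ly;
        P.x = {-hw, hw, hw, -hw}; P.y = {-hh, -hh, hh, hh}; P.lab = {-2, -2, -2, -2};
        double mr2 = max_r2(P);
        for (const Cand &c : cands) {
          if (c.d2 > 4.0 * mr2 * (1.0 + 1e-12)) break;
          clip(P, c.qx, c.qy, c.d2, c.j);
          mr2 = max_r2(P);
        }
        if (4.0 * mr2 <= R * R || R >= 1.9 * scale) done = true; else R *= 1.7;
      }
      std::sort(cands.begin(), cands.end(), cand_less);
    }

    if (brute) std::sort(cands.begin(), cands.end(), cand_less);

    Poly P;
    double hw = 0.6 * Lx, hh = 0.6 * Ly;
    P.x = {-hw, hw, hw, -hw}; P.y = {-hh, -hh, hh, hh}; P.lab = {-2, -2, -2, -2};
    double mr2 = max_r2(P);
    for (const Cand &c : cands) {
      if (c.d2 > 4.0 * mr2 * (1.0 + 1e-12)) break;
      clip(P, c.qx, c.qy, c.d2, c.j);
      if (P.x.size() < 3) stop("generator %d produced an empty cell", i + 1);
      mr2 = max_r2(P);
    }
    dedupe(P, tol_len);
    const size_t m = P.x.size();
    if (m < 3) stop("generator %d produced a degenerate cell", i + 1);

    double A = 0.0, Pm = 0.0, cx = 0.0, cy = 0.0;
    for (size_t k = 0; k < m; ++k) {
      size_t k2 = (k + 1) % m;
      if (P.lab[k] == -2)
        stop("tessellation unbounded for generator %d (box too small)", i + 1);
      if (P.lab[k] == i)
        stop("cell of generator %d touches its own periodic image (box too small relative to point sparsity)",
             i + 1);
      double cr = P.x[k] * P.y[k2] - P.x[k2] * P.y[k];
      A += cr;
      cx += (P.x[k] + P.x[k2]) * cr;
      cy += (P.y[k] + P.y[k2]) * cr;
      double dx = P.x[k2] - P.x[k], dy = P.y[k2] - P.y[k];
      double el = std::sqrt(dx * dx + dy * dy);
      Pm += el;
      adj[i][P.lab[k]] += el;
    }
    A *= 0.5;
    if (A <= 0) stop("generator %d produced a non-positive-area cell", i + 1);
    cx = cx / (6.0 * A) + px[i];
    cy = cy / (6.0 * A) + py[i];
    area[i] = A; perim[i] = Pm;
    centroid(i, 0) = cx; centroid(i, 1) = cy;

    NumericMatrix V(m, 2);
    for (size_t k = 0; k < m; ++k) {
      V(k, 0) = P.x[k] + px[i];
      V(k, 1) = P.y[k] + py[i];
      double wx = wrap01(V(k, 0), Lx);
      double wy = wrap01(V(k, 1), Ly);
      if (wx > Lx - tol_len) wx -= Lx;
      if (wy > Ly - tol_len) wy -= Ly;
      vx_all.push_back(wx); vy_all.push_back(wy); vcell.push_back(i);
    }
    verts[i] = V;
  }
  if (grid) delete grid;

  // symmetrize edge-sharing adjacency (average the two independent length
  // estimates; they agree to rounding)
  for (int i = 0; i < n; ++i) {
    for (auto &kv : adj[i]) {
      int j = kv.first;
      if (j <= i) continue;
      auto it = adj[j].find(i);
      if (it != adj[j].end()) {
        double l = 0.5 * (kv.second + it->second);
        kv.second = l; it->second = l;
      } else {
        adj[j][i] = kv.second;
      }
    }
  }

  // shared-vertex pass: cells with a common vertex are neighbors even without
  // a shared edge (vertex-only contact, length 0)
  {
    std::unordered_map<long long, std::vector<int>> buckets;
    const double h = std::max(tol_len, 1e-300);
    auto key = [&](double x, double y) {
      long long kx = (long long)std::llround(x / h);
      long long ky = (long long)std::llround(y / h);
      return (kx * 2654435761LL) ^ (ky + 1442695040888963407LL);
    };
    const size_t nv = vx_all.size();
    for (size_t v = 0; v < nv; ++v) buckets[key(vx_all[v], vy_all[v])].push_back((int)v);
    for (size_t v = 0; v < nv; ++v) {
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy) {
          auto it = buckets.find(key(vx_all[v] + dx * h, vy_all[v] + dy * h));
          if (it == buckets.end()) continue;
          for (int w : it->second) {
            if ((size_t)w <= v) continue;
            int ci = vcell[v], cj = vcell[w];
            if (ci == cj) continue;
            double ddx = vx_all[v] - vx_all[w], ddy = vy_all[v] - vy_all[w];
            if (ddx * ddx + ddy * ddy > 4.0 * tol_len * tol_len) continue;
            int a = std::min(ci, cj), b = std::max(ci, cj);
            if (adj[a].find(b) == adj[a].end()) { adj[a][b] = 0.0; adj[b][a] = 0.0; }
          }
        }
    }
  }

  List nbr(n), len(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector ids(adj[i].size());
    NumericVector ls(adj[i].size());
    int k = 0;
    for (auto &kv : adj[i]) { ids[k] = kv.first + 1; ls[k] = kv.second; ++k; }
    nbr[i] = ids; len[i] = ls;
  }

  return List::create(_["vertices"] = verts, _["area"] = area, _["perimeter"] = perim,
                      _["centroid"] = centroid, _["neighbors"] = nbr,
                      _["edge_lengths"] = len);
}
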