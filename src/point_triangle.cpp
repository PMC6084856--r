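// Exact point-to-triangle distance queries: a brute-force reference path
// and a uniform-grid accelerated path defined to return identical results.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct V3 {
  double x, y, z;
};
inline V3 sub(const V3 &a, const V3 &b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline double dot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 add(const V3 &a, const V3 &b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline V3 scale(const V3 &a, double s) { return {a.x * s, a.y * s, a.z * s}; }

// Closest point on triangle (a,b,c) to p (Voronoi-region case analysis).
inline V3 closest_on_triangle(const V3 &p, const V3 &a, const V3 &b,
                              const V3 &c) {
  V3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) return a;
  V3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    return add(a, scale(ab, v));
  }
  V3 cp = sub(p, c);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    return add(a, scale(ac, w));
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return add(b, scale(sub(c, b), w));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return add(a, add(scale(ab, v), scale(ac, w)));
}

inline V3 row(const NumericMatrix &m, int i) {
  return {m(i, 0), m(i, 1), m(i, 2)};
}

struct TriSet {
  const NumericMatrix &verts;
  const IntegerMatrix &faces;
  double d2(const V3 &p, int t, V3 &foot) const {
    V3 a = row(verts, faces(t, 0) - 1);
    V3 b = row(verts, faces(t, 1) - 1);
    V3 c = row(verts, faces(t, 2) - 1);
    foot = closest_on_triangle(p, a, b, c);
    V3 d = sub(p, foot);
    return dot(d, d);
  }
};

struct Grid {
  double ox, oy, oz, cell;
  int nx, ny, nz;
  std::vector<std::vector<int>> bins;

  void build(const NumericMatrix &verts, const IntegerMatrix &faces) {
    double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = 0; i < verts.nrow(); ++i)
      for (int k = 0; k < 3; ++k) {
        lo[k] = std::min(lo[k], verts(i, k));
        hi[k] = std::max(hi[k], verts(i, k));
      }
    int m = faces.nrow();
    double ext = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1e-9});
    int target = (int)std::ceil(std::cbrt((double)std::max(m, 1)));
    target = std::min(std::max(target, 1), 64);
    cell = ext / target;
    ox = lo[0]; oy = lo[1]; oz = lo[2];
    nx = std::max(1, (int)std::floor((hi[0] - lo[0]) / cell) + 1);
    ny = std::max(1, (int)std::floor((hi[1] - lo[1]) / cell) + 1);
    nz = std::max(1, (int)std::floor((hi[2] - lo[2]) / cell) + 1);
    bins.assign((size_t)nx * ny * nz, {});
    for (int t = 0; t < m; ++t) {
      double tlo[3] = {R_PosInf, R_PosInf, R_PosInf};
      double thi[3] = {R_NegInf, R_NegInf, R_NegInf};
      for (int j = 0; j < 3; ++j) {
        int v = faces(t, j) - 1;
        for (int k = 0; k < 3; ++k) {
          tlo[k] = std::min(tlo[k], verts(v, k));
          thi[k] = std::max(thi[k], verts(v, k));
        }
      }
      int i0 = clampi((tlo[0] - ox) / cell, nx), i1 = clampi((thi[0] - ox) / cell, nx);
      int j0 = clampi((tlo[1] - oy) / cell, ny), j1 = clampi((thi[1] - oy) / cell, ny);
      int k0 = clampi((tlo[2] - oz) / cell, nz), k1 = clampi((thi[2] - oz) / cell, nz);
      for (int i = i0; i <= i1; ++i)
        for (int j = j0; j <= j1; ++j)
          for (int k = k0; k <= k1; ++k)
            bins[idx(i, j, k)].push_back(t);
    }
  }
  static int clampi(double v, int n) {
    int i = (int)std::floor(v);
    return std::min(std::max(i, 0), n - 1);
  }
  size_t idx(int i, int j, int k) const {
    return ((size_t)k * ny + j) * nx + i;
  }

  // Exact nearest triangle via expanding-ring search.
  void query(const V3 &p, const TriSet &tris, double &best_d2, int &best_t,
             V3 &best_foot) const {
    int ci = clampi((p.x - ox) / cell, nx);
    int cj = clampi((p.y - oy) / cell, ny);
    int ck = clampi((p.z - oz) / cell, nz);
    best_d2 = R_PosInf;
    best_t = -1;
    int maxr = std::max({nx, ny, nz});
    for (int r = 0; r <= maxr; ++r) {
      // lower bound on distance from p to any cell in ring r
      if (r > 0) {
        double ring_lb = (r - 1) * cell; // conservative
        if (ring_lb > 0 && ring_lb * ring_lb > best_d2) break;
      }
      bool any = false;
      for (int i = std::max(0, ci - r); i <= std::min(nx - 1, ci + r); ++i)
        for (int j = std::max(0, cj - r); j <= std::min(ny - 1, cj + r); ++j)
          for (int k = std::max(0, ck - r); k <= std::min(nz - 1, ck + r); ++k) {
            if (std::max({std::abs(i - ci), std::abs(j - cj),
                          std::abs(k - ck)}) != r)
              continue;
            any = true;
            for (int t : bins[idx(i, j, k)]) {
              V3 foot;
              double d2 = tris.d2(p, t, foot);
              if (d2 < best_d2 ||
                  (d2 == best_d2 && best_t >= 0 && t < best_t)) {
                best_d2 = d2;
                best_t = t;
                best_foot = foot;
              }
            }
          }
      if (!any && best_t >= 0) break;
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".point_surface_distance")]]
List point_surface_distance(NumericMatrix points, NumericMatrix verts,
                            IntegerMatrix faces, bool accelerate) {
  int n = points.nrow();
  TriSet tris{verts, faces};
  NumericVector dist(n);
  NumericMatrix foot(n, 3);
  IntegerVector tri(n);
  if (accelerate && faces.nrow() > 32) {
    Grid g;
    g.build(verts, faces);
    for (int i = 0; i < n; ++i) {
      V3 p = row(points, i), bf;
      double bd2;
      int bt;
      g.query(p, tris, bd2, bt, bf);
      dist[i] = std::sqrt(bd2);
      foot(i, 0) = bf.x; foot(i, 1) = bf.y; foot(i, 2) = bf.z;
      tri[i] = bt + 1;
    }
  } else {
    for (int i = 0; i < n; ++i) {
      V3 p = row(points, i), bf = {0, 0, 0};
      double bd2 = R_PosInf;
      int bt = -1;
      for (int t = 0; t < faces.nrow(); ++t) {
        V3 f;
        double d2 = tris.d2(p, t, f);
        if (d2 < bd2) {
          bd2 = d2;
          bt = t;
          bf = f;
        }
      }
      dist[i] = std::sqrt(bd2);
      foot(i, 0) = bf.x; foot(i, 1) = bf.y; foot(i, 2) = bf.z;
      tri[i] = bt + 1;
    }
  }
  return List::create(_["distance"] = dist, _["foot"] = foot,
                      _["triangle"] = tri);
}

// Nearest vertex of `verts` for each query point; ties -> lowest index.
// [[Rcpp::export(name = ".nearest_vertex")]]
IntegerVector nearest_vertex(NumericMatrix points, NumericMatrix verts) {
  int n = points.nrow(), m = verts.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double bd = R_PosInf;
    int bj = 0;
    for (int j = 0; j < m; ++j) {
      double dx = points(i, 0) - verts(j, 0);
      double dy = points(i, 1) - verts(j, 1);
      double dz = points(i, 2) - verts(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < bd) {
        bd = d;
        bj = j;
      }
    }
    out[i] = bj + 1;
  }
  return out;
}

// Barycentric point location: best tet per query (largest minimum
// barycentric coordinate), with the coordinates for interpolation.
// [[Rcpp::export(name = ".locate_in_tets")]]
List locate_in_tets(NumericMatrix points, NumericMatrix nodes,
                    IntegerMatrix tets) {
  int n = points.nrow(), m = tets.nrow();
  IntegerVector tet(n);
  NumericMatrix bary(n, 4);
  NumericVector quality(n); // min barycentric coord of chosen tet
  // Precompute inverse matrices
  std::vector<double> inv(9 * (size_t)m);
  std::vector<double> orig(3 * (size_t)m);
  for (int e = 0; e < m; ++e) {
    int n0 = tets(e, 0) - 1, n1 = tets(e, 1) - 1, n2 = tets(e, 2) - 1,
        n3 = tets(e, 3) - 1;
    double D[9];
    for (int k = 0; k < 3; ++k) {
      D[3 * k + 0] = nodes(n1, k) - nodes(n0, k);
      D[3 * k + 1] = nodes(n2, k) - nodes(n0, k);
      D[3 * k + 2] = nodes(n3, k) - nodes(n0, k);
      orig[3 * (size_t)e + k] = nodes(n0, k);
    }
    double d = D[0] * (D[4] * D[8] - D[5] * D[7]) -
               D[1] * (D[3] * D[8] - D[5] * D[6]) +
               D[2] * (D[3] * D[7] - D[4] * D[6]);
    double *A = &inv[9 * (size_t)e];
    A[0] = (D[4] * D[8] - D[5] * D[7]) / d;
    A[1] = (D[2] * D[7] - D[1] * D[8]) / d;
    A[2] = (D[1] * D[5] - D[2] * D[4]) / d;
    A[3] = (D[5] * D[6] - D[3] * D[8]) / d;
    A[4] = (D[0] * D[8] - D[2] * D[6]) / d;
    A[5] = (D[2] * D[3] - D[0] * D[5]) / d;
    A[6] = (D[3] * D[7] - D[4] * D[6]) / d;
    A[7] = (D[1] * D[6] - D[0] * D[7]) / d;
    A[8] = (D[0] * D[4] - D[1] * D[3]) / d;
  }
  for (int i = 0; i < n; ++i) {
    double best_q = R_NegInf;
    int best_e = 0;
    double best_b[4] = {0, 0, 0, 0};
    for (int e = 0; e < m; ++e) {
      const double *A = &inv[9 * (size_t)e];
      double r0 = points(i, 0) - orig[3 * (size_t)e + 0];
      double r1 = points(i, 1) - orig[3 * (size_t)e + 1];
      double r2 = points(i, 2) - orig[3 * (size_t)e + 2];
      double b1 = A[0] * r0 + A[1] * r1 + A[2] * r2;
      double b2 = A[3] * r0 + A[4] * r1 + A[5] * r2;
      double b3 = A[6] * r0 + A[7] * r1 + A[8] * r2;
      double b0 = 1.0 - b1 - b2 - b3;
      double q = std::min(std::min(b0, b1), std::min(b2, b3));
      if (q > best_q) {
        best_q = q;
        best_e = e;
        best_b[0] = b0; best_b[1] = b1; best_b[2] = b2; best_b[3] = b3;
      }
      if (q >= 0) break; // strictly inside: no better tet exists
    }
    tet[i] = best_e + 1;
    quality[i] = best_q;
    for (int k = 0; k < 4; ++k) bary(i, k) = best_b[k];
  }
  return List::create(_["tet"] = tet, _["bary"] = bary,
                      _["quality"] = quality);
}
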