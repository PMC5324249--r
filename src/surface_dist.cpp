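// Exact closest point on a triangle mesh for a set of query points.
// Triangles are binned into a uniform grid by bounding box; each query
// expands its search shell until the current best distance certifies the
// result, so the answer equals the brute-force minimum over all faces.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};
inline Vec3 operator-(const Vec3& a, const Vec3& b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 operator+(const Vec3& a, const Vec3& b) {
  return {a.x + b.x, a.y + b.y, a.z + b.z};
}
inline Vec3 operator*(double s, const Vec3& a) {
  return {s * a.x, s * a.y, s * a.z};
}
inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

// Ericson, Real-Time Collision Detection: closest point on triangle abc to p
Vec3 closest_on_tri(const Vec3& p, const Vec3& a, const Vec3& b,
                    const Vec3& c) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return a + v * ab;
  }
  Vec3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return a + w * ac;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + w * (c - b);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + v * ab + w * ac;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_closest_on_surface")]]
List cpp_closest_on_surface(NumericMatrix P, NumericMatrix V,
                            IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  std::vector<Vec3> tv(3 * nf);
  double lo[3] = {1e30, 1e30, 1e30}, hi[3] = {-1e30, -1e30, -1e30};
  double mean_ext = 0.0;
  for (int t = 0; t < nf; ++t) {
    double tlo[3] = {1e30, 1e30, 1e30}, thi[3] = {-1e30, -1e30, -1e30};
    for (int c = 0; c < 3; ++c) {
      Vec3 v = {V(F(t, c) - 1, 0), V(F(t, c) - 1, 1), V(F(t, c) - 1, 2)};
      tv[3 * t + c] = v;
      const double xyz[3] = {v.x, v.y, v.z};
      for (int d = 0; d < 3; ++d) {
        tlo[d] = std::min(tlo[d], xyz[d]);
        thi[d] = std::max(thi[d], xyz[d]);
      }
    }
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], tlo[d]);
      hi[d] = std::max(hi[d], thi[d]);
      mean_ext += (thi[d] - tlo[d]) / (3.0 * nf);
    }
  }
  double h = std::max(mean_ext * 2.0, 1e-9);
  int nc[3];
  for (int d = 0; d < 3; ++d)
    nc[d] = std::max(1, std::min(256, (int)std::ceil((hi[d] - lo[d]) / h)));
  // final cell size from clamped counts
  double cs[3];
  for (int d = 0; d < 3; ++d)
    cs[d] = std::max((hi[d] - lo[d]) / nc[d], 1e-9);
  auto cell_of = [&](double x, int d) {
    int c = (int)std::floor((x - lo[d]) / cs[d]);
    return std::max(0, std::min(nc[d] - 1, c));
  };
  const long ncell = (long)nc[0] * nc[1] * nc[2];
  std::vector<std::vector<int>> bins(ncell);
  for (int t = 0; t < nf; ++t) {
    int c0[3], c1[3];
    for (int d = 0; d < 3; ++d) {
      double tlo = 1e30, thi = -1e30;
      for (int c = 0; c < 3; ++c) {
        const Vec3& v = tv[3 * t + c];
        const double xyz[3] = {v.x, v.y, v.z};
        tlo = std::min(tlo, xyz[d]);
        thi = std::max(thi, xyz[d]);
      }
      c0[d] = cell_of(tlo, d);
      c1[d] = cell_of(thi, d);
    }
    for (int k = c0[2]; k <= c1[2]; ++k)
      for (int j = c0[1]; j <= c1[1]; ++j)
        for (int i = c0[0]; i <= c1[0]; ++i)
          bins[i + nc[0] * (j + (long)nc[1] * k)].push_back(t);
  }

  NumericVector dist(np);
  NumericMatrix closest(np, 3);
  IntegerVector face(np);
  std::vector<int> stamp(nf, -1);

  for (int q = 0; q < np; ++q) {
    Vec3 p = {P(q, 0), P(q, 1), P(q, 2)};
    const double pxyz[3] = {p.x, p.y, p.z};
    int pc[3];
    for (int d = 0; d < 3; ++d) pc[d] = cell_of(pxyz[d], d);
    double best = std::numeric_limits<double>::infinity();
    Vec3 bestpt = {0, 0, 0};
    int bestface = -1;
    const double hmin = std::min(cs[0], std::min(cs[1], cs[2]));
    int max_ring = nc[0] + nc[1] + nc[2];

    for (int ring = 0; ring <= max_ring; ++ring) {
      // certified: every unvisited cell is at least (ring-1)*hmin away
      if (bestface >= 0 && (double)(ring - 1) * hmin > best) break;
      bool any_cell = false;
      int i0 = pc[0] - ring, i1 = pc[0] + ring;
      int j0 = pc[1] - ring, j1 = pc[1] + ring;
      int k0 = pc[2] - ring, k1 = pc[2] + ring;
      for (int k = k0; k <= k1; ++k) {
        if (k < 0 || k >= nc[2]) continue;
        for (int j = j0; j <= j1; ++j) {
          if (j < 0 || j >= nc[1]) continue;
          for (int i = i0; i <= i1; ++i) {
            if (i < 0 || i >= nc[0]) continue;
            // shell only
            if (ring > 0 && i != i0 && i != i1 && j != j0 && j != j1 &&
                k != k0 && k != k1)
              continue;
            any_cell = true;
            const std::vector<int>& cand =
                bins[i + nc[0] * (j + (long)nc[1] * k)];
            for (int t : cand) {
              if (stamp[t] == q) continue;
              stamp[t] = q;
              Vec3 cp = closest_on_tri(p, tv[3 * t], tv[3 * t + 1],
                                       tv[3 * t + 2]);
              Vec3 dvec = p - cp;
              double d2 = dot(dvec, dvec);
              if (d2 < best * best || bestface < 0) {
                double dd = std::sqrt(d2);
                if (dd < best) {
                  best = dd;
                  bestpt = cp;
                  bestface = t;
                }
              }
            }
          }
        }
      }
      if (!any_cell && bestface >= 0 && ring > 0) break;
    }
    dist[q] = best;
    closest(q, 0) = bestpt.x;
    closest(q, 1) = bestpt.y;
    closest(q, 2) = bestpt.z;
    face[q] = bestface + 1;  // 1-based
  }
  return List::create(_["distance"] = dist, _["closest"] = closest,
                      _["face"] = face);
}
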