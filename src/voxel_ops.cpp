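// Voxel-grid primitives: 26-connectivity labeling, anisotropic Euclidean
// distance transform, separable Gaussian smoothing, and ray-parity
// voxelization of a closed triangle mesh.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long)ny * k);
}

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long n = (long)nx * ny * nz;
  IntegerVector labels(n, 0);
  int next = 0;
  std::vector<long> stack;
  for (long start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next;
    stack.push_back(start);
    labels[start] = next;
    while (!stack.empty()) {
      long v = stack.back(); stack.pop_back();
      int i = v % nx, j = (v / nx) % ny, k = v / ((long)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            long w = idx3(ii, jj, kk, nx, ny);
            if (mask[w] && labels[w] == 0) {
              labels[w] = next;
              stack.push_back(w);
            }
          }
    }
  }
  return labels;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher), grid step h.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double h, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  const double h2 = h * h;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * v[k] * v[k])) /
          (2.0 * h2 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = h2 * dq * dq + f[v[k]];
  }
}

// Distance (mm) from each foreground voxel center to the nearest background
// voxel center; background voxels get 0.  Voxels beyond the grid count as
// background (the half-voxel border is treated as wall).
// [[Rcpp::export(name = ".cpp_edt")]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long n = (long)nx * ny * nz;
  const double INF = 1e30;
  std::vector<double> d(n);
  for (long v = 0; v < n; ++v) d[v] = mask[v] ? INF : 0.0;

  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> g(f.size());
  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = d[idx3(i, j, k, nx, ny)];
      dt1d(f, g, spacing[0], nx);
      for (int i = 0; i < nx; ++i) d[idx3(i, j, k, nx, ny)] = g[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = d[idx3(i, j, k, nx, ny)];
      dt1d(f, g, spacing[1], ny);
      for (int j = 0; j < ny; ++j) d[idx3(i, j, k, nx, ny)] = g[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = d[idx3(i, j, k, nx, ny)];
      dt1d(f, g, spacing[2], nz);
      for (int k = 0; k < nz; ++k) d[idx3(i, j, k, nx, ny)] = g[k];
    }
  NumericVector out(n);
  for (long v = 0; v < n; ++v) out[v] = std::sqrt(d[v]);
  return out;
}

// [[Rcpp::export(name = ".cpp_gaussian_smooth3")]]
NumericVector cpp_gaussian_smooth3(NumericVector values, IntegerVector dim,
                                   double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long n = (long)nx * ny * nz;
  if (sigma <= 0) return clone(values);
  int radius = (int)std::ceil(3.0 * sigma);
  std::vector<double> kern(2 * radius + 1);
  double s = 0.0;
  for (int t = -radius; t <= radius; ++t) {
    kern[t + radius] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += kern[t + radius];
  }
  for (auto& k : kern) k /= s;

  std::vector<double> a(values.begin(), values.end()), b(n);
  const int nd[3] = {nx, ny, nz};
  const long strides[3] = {1, nx, (long)nx * ny};
  for (int axis = 0; axis < 3; ++axis) {
    const int len = nd[axis];
    const long str = strides[axis];
    for (long v = 0; v < n; ++v) {
      int pos;
      if (axis == 0) pos = v % nx;
      else if (axis == 1) pos = (v / nx) % ny;
      else pos = v / ((long)nx * ny);
      double acc = 0.0, wsum = 0.0;
      for (int t = -radius; t <= radius; ++t) {
        int p = pos + t;
        if (p < 0 || p >= len) continue;  // renormalized at edges
        acc += kern[t + radius] * a[v + (long)t * str];
        wsum += kern[t + radius];
      }
      b[v] = acc / wsum;
    }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

// Inside/outside of a closed mesh at every voxel center, by parity of
// +x ray crossings.  Ray origins are jittered off exact vertex/edge hits.
// [[Rcpp::export(name = ".cpp_voxelize_parity")]]
LogicalVector cpp_voxelize_parity(NumericMatrix V, IntegerMatrix F,
                                  IntegerVector dim, NumericVector spacing,
                                  NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nf = F.nrow();
  const long n = (long)nx * ny * nz;
  LogicalVector out(n, false);

  // bin triangles by their (y, z) voxel-row footprint
  std::vector<std::vector<int>> rows((long)ny * nz);
  for (int t = 0; t < nf; ++t) {
    double ymin = 1e30, ymax = -1e30, zmin = 1e30, zmax = -1e30;
    for (int c = 0; c < 3; ++c) {
      const int vi = F(t, c);
      ymin = std::min(ymin, V(vi, 1)); ymax = std::max(ymax, V(vi, 1));
      zmin = std::min(zmin, V(vi, 2)); zmax = std::max(zmax, V(vi, 2));
    }
    int j0 = std::max(0, (int)std::floor((ymin - origin[1]) / spacing[1]) - 1);
    int j1 = std::min(ny - 1, (int)std::ceil((ymax - origin[1]) / spacing[1]) + 1);
    int k0 = std::max(0, (int)std::floor((zmin - origin[2]) / spacing[2]) - 1);
    int k1 = std::min(nz - 1, (int)std::ceil((zmax - origin[2]) / spacing[2]) + 1);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        rows[j + (long)ny * k].push_back(t);
  }

  const double eps = 1e-7;
  std::vector<double> hits;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      const std::vector<int>& cand = rows[j + (long)ny * k];
      if (cand.empty()) continue;
      // deterministic sub-voxel jitter to dodge edge-exact hits
      const double ry = origin[1] + j * spacing[1] + eps * (1.0 + (j % 7));
      const double rz = origin[2] + k * spacing[2] + eps * (1.0 + (k % 11));
      hits.clear();
      for (int t : cand) {
        const int a = F(t, 0), b = F(t, 1), c = F(t, 2);
        // 2D (y,z) barycentric test, then solve for x
        const double ay = V(a, 1) - ry, az = V(a, 2) - rz;
        const double by = V(b, 1) - ry, bz = V(b, 2) - rz;
        const double cy = V(c, 1) - ry, cz = V(c, 2) - rz;
        const double d1 = ay * bz - az * by;
        const double d2 = by * cz - bz * cy;
        const double d3 = cy * az - cz * ay;
        const bool pos = d1 > 0 || d2 > 0 || d3 > 0;
        const bool neg = d1 < 0 || d2 < 0 || d3 < 0;
        if (pos && neg) continue;          // outside triangle
        const double area = d1 + d2 + d3;
        if (area == 0.0) continue;         // ray in triangle plane
        const double w1 = d2 / area, w2 = d3 / area, w3 = d1 / area;
        hits.push_back(w1 * V(a, 0) + w2 * V(b, 0) + w3 * V(c, 0));
      }
      if (hits.empty()) continue;
      std::sort(hits.begin(), hits.end());
      for (int i = 0; i < nx; ++i) {
        const double x = origin[0] + i * spacing[0];
        size_t cnt = std::lower_bound(hits.begin(), hits.end(), x) -
                     hits.begin();
        // inside when an odd number of crossings lies behind the center
        if ((hits.size() - cnt) % 2 == 1)
          out[idx3(i, j, k, nx, ny)] = true;
      }
    }
  }
  return out;
}
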