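// Isosurface extraction on a regular grid by tetrahedral decomposition
// (six tetrahedra per cube sharing the 0-7 diagonal) with linear edge
// interpolation.  Vertices are welded on shared tetrahedron edges, so the
// surface is watertight wherever the foreground stays off the grid border.
// Triangle winding is chosen so normals point from high values to low
// (outward for a bright-inside lumen).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct MeshAcc {
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  std::unordered_map<uint64_t, int> edge_vertex;
};

// permutation parity of 4 distinct small ints
inline bool odd_perm(const int p[4]) {
  int inv = 0;
  for (int i = 0; i < 4; ++i)
    for (int j = i + 1; j < 4; ++j)
      if (p[i] > p[j]) ++inv;
  return inv % 2 == 1;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_isosurface")]]
List cpp_isosurface(NumericVector values, IntegerVector dim, double level,
                    NumericVector spacing, NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  auto gid = [&](int i, int j, int k) -> long {
    return i + nx * (j + (long)ny * k);
  };
  MeshAcc m;

  // global corner index of a welded vertex on edge (ga, gb), interpolated
  auto edge_point = [&](long ga, long gb, double fa, double fb) -> int {
    uint64_t key = ga < gb ? ((uint64_t)ga << 32) | (uint64_t)gb
                           : ((uint64_t)gb << 32) | (uint64_t)ga;
    auto it = m.edge_vertex.find(key);
    if (it != m.edge_vertex.end()) return it->second;
    double t = (level - fa) / (fb - fa);
    int ia = ga % nx, ja = (ga / nx) % ny, ka = ga / ((long)nx * ny);
    int ib = gb % nx, jb = (gb / nx) % ny, kb = gb / ((long)nx * ny);
    m.vx.push_back(origin[0] + spacing[0] * (ia + t * (ib - ia)));
    m.vy.push_back(origin[1] + spacing[1] * (ja + t * (jb - ja)));
    m.vz.push_back(origin[2] + spacing[2] * (ka + t * (kb - ka)));
    int id = (int)m.vx.size() - 1;
    m.edge_vertex[key] = id;
    return id;
  };

  auto emit = [&](int a, int b, int c) {
    m.tri.push_back(a); m.tri.push_back(b); m.tri.push_back(c);
  };

  // six positively oriented tetrahedra sharing corners 0 and 7
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
    {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};

  long corner[8];
  double f[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          corner[c] = gid(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1));
          f[c] = values[corner[c]];
          (f[c] > level ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int loc[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int nin = 0, in_ix[4], out_ix[4];
          int nout = 0;
          for (int c = 0; c < 4; ++c)
            if (f[loc[c]] > level) in_ix[nin++] = c; else out_ix[nout++] = c;
          if (nin == 0 || nin == 4) continue;

          // canonical (a,b,c,d): inside vertices first, then outside, with
          // even parity relative to the tet's stored (positive) order
          int perm[4];
          if (nin == 1) {
            perm[0] = in_ix[0];
            perm[1] = out_ix[0]; perm[2] = out_ix[1]; perm[3] = out_ix[2];
            if (odd_perm(perm)) std::swap(perm[2], perm[3]);
            long A = corner[loc[perm[0]]];
            double fA = f[loc[perm[0]]];
            int e1 = edge_point(A, corner[loc[perm[1]]], fA, f[loc[perm[1]]]);
            int e2 = edge_point(A, corner[loc[perm[2]]], fA, f[loc[perm[2]]]);
            int e3 = edge_point(A, corner[loc[perm[3]]], fA, f[loc[perm[3]]]);
            emit(e1, e2, e3);
          } else if (nin == 3) {
            perm[0] = out_ix[0];
            perm[1] = in_ix[0]; perm[2] = in_ix[1]; perm[3] = in_ix[2];
            if (odd_perm(perm)) std::swap(perm[2], perm[3]);
            long A = corner[loc[perm[0]]];
            double fA = f[loc[perm[0]]];
            int e1 = edge_point(A, corner[loc[perm[1]]], fA, f[loc[perm[1]]]);
            int e2 = edge_point(A, corner[loc[perm[2]]], fA, f[loc[perm[2]]]);
            int e3 = edge_point(A, corner[loc[perm[3]]], fA, f[loc[perm[3]]]);
            emit(e1, e3, e2);  // reversed: normal toward the outside vertex
          } else {  // nin == 2
            perm[0] = in_ix[0]; perm[1] = in_ix[1];
            perm[2] = out_ix[0]; perm[3] = out_ix[1];
            if (odd_perm(perm)) std::swap(perm[2], perm[3]);
            long A = corner[loc[perm[0]]], B = corner[loc[perm[1]]];
            long C = corner[loc[perm[2]]], D = corner[loc[perm[3]]];
            double fA = f[loc[perm[0]]], fB = f[loc[perm[1]]];
            double fC = f[loc[perm[2]]], fD = f[loc[perm[3]]];
            int ac = edge_point(A, C, fA, fC);
            int ad = edge_point(A, D, fA, fD);
            int bd = edge_point(B, D, fB, fD);
            int bc = edge_point(B, C, fB, fC);
            emit(ac, ad, bd);
            emit(ac, bd, bc);
          }
        }
      }

  const int nv = (int)m.vx.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = m.vx[v]; V(v, 1) = m.vy[v]; V(v, 2) = m.vz[v];
  }
  const int nf = (int)m.tri.size() / 3;
  IntegerMatrix Fm(nf, 3);
  for (int t = 0; t < nf; ++t) {
    Fm(t, 0) = m.tri[3 * t] + 1;      // 1-based for R
    Fm(t, 1) = m.tri[3 * t + 1] + 1;
    Fm(t, 2) = m.tri[3 * t + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}
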