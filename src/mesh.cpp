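#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Isosurface area by marching tetrahedra: each cube is split into six
// tetrahedra around the main diagonal; within a tetrahedron the isosurface of
// the trilinear field is approximated by the linear interpolant, giving a
// triangle (1 vertex on one side) or a quad (2/2 split). Areas accumulate in
// physical units via the per-axis spacing.

namespace {

struct P3 { double z, y, x; };

inline P3 lerp(const P3& a, const P3& b, double fa, double fb, double level) {
  const double t = (level - fa) / (fb - fa);
  return {a.z + t * (b.z - a.z), a.y + t * (b.y - a.y), a.x + t * (b.x - a.x)};
}

inline double tri_area(const P3& a, const P3& b, const P3& c) {
  const double u[3] = {b.z - a.z, b.y - a.y, b.x - a.x};
  const double v[3] = {c.z - a.z, c.y - a.y, c.x - a.x};
  const double w[3] = {u[1] * v[2] - u[2] * v[1], u[2] * v[0] - u[0] * v[2],
                       u[0] * v[1] - u[1] * v[0]};
  return 0.5 * std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
}

}  // namespace

// [[Rcpp::export(name = ".cpp_isosurface_area")]]
double cpp_isosurface_area(NumericVector arr, IntegerVector dims,
                           NumericVector spacing, double level) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  // cube corner offsets (z, y, x)
  static const int corner[8][3] = {{0, 0, 0}, {0, 0, 1}, {0, 1, 0}, {0, 1, 1},
                                   {1, 0, 0}, {1, 0, 1}, {1, 1, 0}, {1, 1, 1}};
  // six tetrahedra sharing the diagonal corner0 - corner7
  static const int tets[6][4] = {{0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
                                 {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};
  double area = 0.0;
  double f[8];
  P3 p[8];
  for (int x = 0; x < nx - 1; ++x)
    for (int y = 0; y < ny - 1; ++y)
      for (int z = 0; z < nz - 1; ++z) {
        for (int c = 0; c < 8; ++c) {
          const int zz = z + corner[c][0], yy = y + corner[c][1],
                    xx = x + corner[c][2];
          f[c] = arr[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)];
          p[c] = {zz * dz, yy * dy, xx * dx};
        }
        for (int t = 0; t < 6; ++t) {
          const int* v = tets[t];
          int above[4], n_above = 0, below[4], n_below = 0;
          for (int c = 0; c < 4; ++c) {
            if (f[v[c]] >= level) above[n_above++] = v[c];
            else below[n_below++] = v[c];
          }
          if (n_above == 0 || n_above == 4) continue;
          if (n_above == 1 || n_above == 3) {
            const int lone = (n_above == 1) ? above[0] : below[0];
            const int* other = (n_above == 1) ? below : above;
            P3 q0 = lerp(p[lone], p[other[0]], f[lone], f[other[0]], level);
            P3 q1 = lerp(p[lone], p[other[1]], f[lone], f[other[1]], level);
            P3 q2 = lerp(p[lone], p[other[2]], f[lone], f[other[2]], level);
            area += tri_area(q0, q1, q2);
          } else {
            // 2-2 split: quad with vertices on the four crossing edges
            const int a0 = above[0], a1 = above[1], b0 = below[0],
                      b1 = below[1];
            P3 q00 = lerp(p[a0], p[b0], f[a0], f[b0], level);
            P3 q01 = lerp(p[a0], p[b1], f[a0], f[b1], level);
            P3 q10 = lerp(p[a1], p[b0], f[a1], f[b0], level);
            P3 q11 = lerp(p[a1], p[b1], f[a1], f[b1], level);
            area += tri_area(q00, q01, q11) + tri_area(q00, q11, q10);
          }
        }
      }
  return area;
}
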