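#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher lower
// envelope of parabolas), separable per axis, anisotropic spacing supported.
// Returns the distance from each foreground voxel to the nearest background
// voxel centre, in physical units; 0 on background.

static void dt1d(const std::vector<double>& f, std::vector<double>& d, double h) {
  const int n = f.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> cand;
  cand.reserve(n);
  for (int i = 0; i < n; ++i)
    if (f[i] < INF) cand.push_back(i);
  if (cand.empty()) {
    std::fill(d.begin(), d.end(), INF);
    return;
  }
  const int m = cand.size();
  std::vector<int> v(m);
  std::vector<double> zb(m + 1);
  int k = 0;
  v[0] = cand[0];
  zb[0] = -INF;
  zb[1] = INF;
  const double h2 = h * h;
  for (int ci = 1; ci < m; ++ci) {
    int q = cand[ci];
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + h2 * (double)q * q) - (f[p] + h2 * (double)p * p)) /
          (2.0 * h2 * (q - p));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = (q - v[k]) * h;
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".cpp_edt")]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nz * ny * nx;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector sq(ntot);
  bool any_bg = false;
  for (R_xlen_t i = 0; i < ntot; ++i) {
    sq[i] = mask[i] ? INF : 0.0;
    if (!mask[i]) any_bg = true;
  }
  if (!any_bg) stop("mask has no background voxel; distance undefined");

  const int ns[3] = {nz, ny, nx};
  const R_xlen_t strides[3] = {1, (R_xlen_t)nz, (R_xlen_t)nz * ny};
  for (int axis = 0; axis < 3; ++axis) {
    const int n = ns[axis];
    const R_xlen_t stride = strides[axis];
    const int d1 = (axis == 0) ? ny : nz;
    const int d2 = (axis == 2) ? ny : nx;
    const R_xlen_t s1 = (axis == 0) ? (R_xlen_t)nz : 1;
    const R_xlen_t s2 = (axis == 2) ? (R_xlen_t)nz : (R_xlen_t)nz * ny;
    std::vector<double> f(n), d(n);
    for (int j2 = 0; j2 < d2; ++j2) {
      for (int j1 = 0; j1 < d1; ++j1) {
        const R_xlen_t base = j1 * s1 + j2 * s2;
        for (int i = 0; i < n; ++i) f[i] = sq[base + i * stride];
        dt1d(f, d, spacing[axis]);
        for (int i = 0; i < n; ++i) sq[base + i * stride] = d[i];
      }
    }
  }
  for (R_xlen_t i = 0; i < ntot; ++i) sq[i] = std::sqrt(sq[i]);
  return sq;
}
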