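#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Axis convention throughout src/: arrays are column-major with dim = (nz, ny, nx);
// axis 0 = z (stride 1), axis 1 = y (stride nz), axis 2 = x (stride nz*ny).

static inline int reflect_index(int i, int n) {
  // scipy-style "reflect" ((d c b a | a b c d | d c b a)); safe for any kernel
  // length via iteration
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// [[Rcpp::export(name = ".cpp_correlate_axis")]]
NumericVector cpp_correlate_axis(NumericVector arr, IntegerVector dims,
                                 NumericVector kernel, int axis) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int klen = kernel.size();
  const int c = (klen - 1) / 2;
  NumericVector out(arr.size());
  const double* kern = REAL(kernel);
  const double* src = REAL(arr);
  double* dst = REAL(out);

  if (axis == 0) {
    // contiguous lines along z
    const int n = nz;
    const int lo = std::min(c, n);
    const int hi = std::max(lo, n - (klen - 1 - c));
    const R_xlen_t nlines = (R_xlen_t)ny * nx;
    for (R_xlen_t l = 0; l < nlines; ++l) {
      const double* lp = src + l * nz;
      double* op = dst + l * nz;
      int i = 0;
      for (; i < lo; ++i) {
        double acc = 0.0;
        for (int k = 0; k < klen; ++k)
          acc += kern[k] * lp[reflect_index(i + k - c, n)];
        op[i] = acc;
      }
      for (; i < hi; ++i) {
        double acc = 0.0;
        const double* w = lp + i - c;
        for (int k = 0; k < klen; ++k) acc += kern[k] * w[k];
        op[i] = acc;
      }
      for (; i < n; ++i) {
        double acc = 0.0;
        for (int k = 0; k < klen; ++k)
          acc += kern[k] * lp[reflect_index(i + k - c, n)];
        op[i] = acc;
      }
    }
    return out;
  }

  // axes 1 and 2: accumulate kernel taps over contiguous blocks so memory
  // access stays sequential (axis 1: blocks of nz per fixed (y, x);
  // axis 2: whole z-y planes)
  const int n = (axis == 1) ? ny : nx;
  const R_xlen_t block = (axis == 1) ? (R_xlen_t)nz : (R_xlen_t)nz * ny;
  const int nouter = (axis == 1) ? nx : 1;
  const R_xlen_t outer_stride = (R_xlen_t)nz * ((axis == 1) ? ny : 0);

  for (int o = 0; o < nouter; ++o) {
    const double* sp = src + o * outer_stride;
    double* op = dst + o * outer_stride;
    for (int i = 0; i < n; ++i) {
      double* orow = op + i * block;
      // first tap initialises, the rest accumulate
      {
        const double* srow = sp + (R_xlen_t)reflect_index(i - c, n) * block;
        const double k0 = kern[0];
        for (R_xlen_t b = 0; b < block; ++b) orow[b] = k0 * srow[b];
      }
      for (int k = 1; k < klen; ++k) {
        const double* srow = sp + (R_xlen_t)reflect_index(i + k - c, n) * block;
        const double kk = kern[k];
        for (R_xlen_t b = 0; b < block; ++b) orow[b] += kk * srow[b];
      }
    }
  }
  return out;
}
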