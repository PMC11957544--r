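#include <Rcpp.h>
using namespace Rcpp;

// Perona-Malik anisotropic diffusion, explicit scheme, 6-neighbour stencil,
// exponential conductance g(d) = exp(-(d/kappa)^2), zero-flux boundaries.
// Pairwise fluxes are antisymmetric, so total intensity is conserved exactly
// (up to float rounding).

// [[Rcpp::export(name = ".cpp_perona_malik")]]
NumericVector cpp_perona_malik(NumericVector arr, IntegerVector dims,
                               int n_iter, double kappa, double lambda) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t sz = 1, sy = nz, sx = (R_xlen_t)nz * ny;
  NumericVector cur = clone(arr);
  NumericVector nxt(arr.size());
  const double inv_k2 = 1.0 / (kappa * kappa);

  for (int it = 0; it < n_iter; ++it) {
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        R_xlen_t i = y * sy + x * sx;
        for (int z = 0; z < nz; ++z, ++i) {
          const double v = cur[i];
          double acc = 0.0;
          if (z > 0)      { double d = cur[i - sz] - v; acc += d * std::exp(-d * d * inv_k2); }
          if (z < nz - 1) { double d = cur[i + sz] - v; acc += d * std::exp(-d * d * inv_k2); }
          if (y > 0)      { double d = cur[i - sy] - v; acc += d * std::exp(-d * d * inv_k2); }
          if (y < ny - 1) { double d = cur[i + sy] - v; acc += d * std::exp(-d * d * inv_k2); }
          if (x > 0)      { double d = cur[i - sx] - v; acc += d * std::exp(-d * d * inv_k2); }
          if (x < nx - 1) { double d = cur[i + sx] - v; acc += d * std::exp(-d * d * inv_k2); }
          nxt[i] = v + lambda * acc;
        }
      }
    }
    std::swap(cur, nxt);
  }
  return cur;
}
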