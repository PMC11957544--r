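#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closed-form eigen decomposition of the symmetric 3x3 Hessian per voxel
// (trigonometric method), eigenvalues sorted by |lambda1| <= |lambda2| <=
// |lambda3| (Frangi convention), optional eigenvector of the smallest-|lambda|
// eigenvalue (tube axis).

static inline void eig_sym3(double a11, double a22, double a33, double a12,
                            double a13, double a23, double ev[3]) {
  const double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 == 0.0) {
    ev[0] = a11; ev[1] = a22; ev[2] = a33;
    return;
  }
  const double q = (a11 + a22 + a33) / 3.0;
  const double b11 = a11 - q, b22 = a22 - q, b33 = a33 - q;
  const double p2 = b11 * b11 + b22 * b22 + b33 * b33 + 2.0 * p1;
  const double p = std::sqrt(p2 / 6.0);
  // det(B)/2 with B = (A - qI)/p
  const double c11 = b11 / p, c22 = b22 / p, c33 = b33 / p;
  const double c12 = a12 / p, c13 = a13 / p, c23 = a23 / p;
  double r = (c11 * (c22 * c33 - c23 * c23) - c12 * (c12 * c33 - c23 * c13) +
              c13 * (c12 * c23 - c22 * c13)) / 2.0;
  r = std::max(-1.0, std::min(1.0, r));
  const double phi = std::acos(r) / 3.0;
  const double e1 = q + 2.0 * p * std::cos(phi);
  const double e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
  const double e2 = 3.0 * q - e1 - e3;
  ev[0] = e1; ev[1] = e2; ev[2] = e3;
}

static inline void eigvec3(double a11, double a22, double a33, double a12,
                           double a13, double a23, double lambda, double v[3]) {
  // rows of (A - lambda I); eigenvector = cross product of the two most
  // independent rows
  const double r1[3] = {a11 - lambda, a12, a13};
  const double r2[3] = {a12, a22 - lambda, a23};
  const double r3[3] = {a13, a23, a33 - lambda};
  double c12[3] = {r1[1] * r2[2] - r1[2] * r2[1],
                   r1[2] * r2[0] - r1[0] * r2[2],
                   r1[0] * r2[1] - r1[1] * r2[0]};
  double c13[3] = {r1[1] * r3[2] - r1[2] * r3[1],
                   r1[2] * r3[0] - r1[0] * r3[2],
                   r1[0] * r3[1] - r1[1] * r3[0]};
  double c23[3] = {r2[1] * r3[2] - r2[2] * r3[1],
                   r2[2] * r3[0] - r2[0] * r3[2],
                   r2[0] * r3[1] - r2[1] * r3[0]};
  double n12 = c12[0] * c12[0] + c12[1] * c12[1] + c12[2] * c12[2];
  double n13 = c13[0] * c13[0] + c13[1] * c13[1] + c13[2] * c13[2];
  double n23 = c23[0] * c23[0] + c23[1] * c23[1] + c23[2] * c23[2];
  const double* best = c12;
  double nb = n12;
  if (n13 > nb) { best = c13; nb = n13; }
  if (n23 > nb) { best = c23; nb = n23; }
  if (nb <= 0.0) { v[0] = 1.0; v[1] = 0.0; v[2] = 0.0; return; }
  const double inv = 1.0 / std::sqrt(nb);
  v[0] = best[0] * inv; v[1] = best[1] * inv; v[2] = best[2] * inv;
}

// h: list of the six Hessian components as full-volume vectors in the order
// (zz, yy, xx, zy, zx, yx). Axis 1 of eigenvectors refers to z, 2 to y, 3 to x.

// [[Rcpp::export(name = ".cpp_hessian_eigen")]]
List cpp_hessian_eigen(NumericVector hzz, NumericVector hyy, NumericVector hxx,
                       NumericVector hzy, NumericVector hzx, NumericVector hyx,
                       bool want_vectors) {
  const R_xlen_t n = hzz.size();
  NumericVector l1(n), l2(n), l3(n);
  NumericVector vz, vy, vx;
  if (want_vectors) {
    vz = NumericVector(n);
    vy = NumericVector(n);
    vx = NumericVector(n);
  }
  double ev[3], v[3];
  for (R_xlen_t i = 0; i < n; ++i) {
    eig_sym3(hzz[i], hyy[i], hxx[i], hzy[i], hzx[i], hyx[i], ev);
    // sort by absolute value
    double a = ev[0], b = ev[1], c = ev[2];
    if (std::abs(a) > std::abs(b)) std::swap(a, b);
    if (std::abs(b) > std::abs(c)) std::swap(b, c);
    if (std::abs(a) > std::abs(b)) std::swap(a, b);
    l1[i] = a; l2[i] = b; l3[i] = c;
    if (want_vectors) {
      eigvec3(hzz[i], hyy[i], hxx[i], hzy[i], hzx[i], hyx[i], a, v);
      vz[i] = v[0]; vy[i] = v[1]; vx[i] = v[2];
    }
  }
  if (want_vectors)
    return List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3,
                        _["vz"] = vz, _["vy"] = vy, _["vx"] = vx);
  return List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3);
}
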