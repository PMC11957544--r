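#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a binary mask, 6- or 26-connectivity,
// iterative BFS (no recursion), labels 1..K in scan order.

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nz * ny * nx;
  IntegerVector labels(ntot, 0);

  // neighbour offsets
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manh != 1) continue;
        nb.push_back({dz, dy, dx});
      }

  std::vector<R_xlen_t> stack;
  int next_label = 0;
  for (R_xlen_t i = 0; i < ntot; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next_label;
    labels[i] = next_label;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int z = cur % nz;
      int y = (cur / nz) % ny;
      int x = cur / ((R_xlen_t)nz * ny);
      for (size_t k = 0; k < nb.size(); ++k) {
        int zz = z + nb[k][0], yy = y + nb[k][1], xx = x + nb[k][2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[j] && labels[j] == 0) {
          labels[j] = next_label;
          stack.push_back(j);
        }
      }
    }
  }
  labels.attr("n_labels") = next_label;
  return labels;
}
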