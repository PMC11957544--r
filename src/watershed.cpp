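#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

namespace {

struct QEntry {
  double value;
  R_xlen_t order;  // FIFO tie-break for equal landscape values
  R_xlen_t index;
};
struct QCmp {
  bool operator()(const QEntry& a, const QEntry& b) const {
    if (a.value != b.value) return a.value > b.value;
    return a.order > b.order;
  }
};

inline void neighbours(int connectivity, std::vector<std::array<int, 3>>& nb) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manh != 1) continue;
        nb.push_back({dz, dy, dx});
      }
}

}  // namespace

// Marker-driven watershed by priority flood: markers grow into the unlabelled
// foreground in order of increasing landscape value; equal values resolved
// first-queued-first-served, which makes the result deterministic.

// [[Rcpp::export(name = ".cpp_watershed")]]
IntegerVector cpp_watershed(NumericVector landscape, IntegerVector markers,
                            LogicalVector mask, IntegerVector dims,
                            int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nz * ny * nx;
  std::vector<std::array<int, 3>> nb;
  neighbours(connectivity, nb);

  IntegerVector labels(ntot, 0);
  std::priority_queue<QEntry, std::vector<QEntry>, QCmp> pq;
  R_xlen_t order = 0;

  for (R_xlen_t i = 0; i < ntot; ++i) {
    if (markers[i] > 0 && mask[i]) {
      labels[i] = markers[i];
      pq.push({landscape[i], order++, i});
    }
  }

  while (!pq.empty()) {
    QEntry e = pq.top();
    pq.pop();
    const R_xlen_t cur = e.index;
    const int lab = labels[cur];
    int z = cur % nz;
    int y = (cur / nz) % ny;
    int x = cur / ((R_xlen_t)nz * ny);
    for (size_t k = 0; k < nb.size(); ++k) {
      int zz = z + nb[k][0], yy = y + nb[k][1], xx = x + nb[k][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
      if (!mask[j] || labels[j] != 0) continue;
      labels[j] = lab;
      pq.push({landscape[j], order++, j});
    }
  }
  return labels;
}

// Greyscale reconstruction by dilation (marker <= mask), hybrid raster /
// anti-raster sweeps followed by a FIFO queue (Vincent 1993). Used for
// h-extrema suppression.

// [[Rcpp::export(name = ".cpp_reconstruct_dilation")]]
NumericVector cpp_reconstruct_dilation(NumericVector marker, NumericVector mask,
                                       IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nz * ny * nx;
  NumericVector J(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) J[i] = std::min(marker[i], mask[i]);

  std::vector<std::array<int, 3>> nb;
  neighbours(6, nb);
  const size_t half = nb.size() / 2;  // nb is symmetric; first half = "minus" side

  auto idx_of = [&](int z, int y, int x) {
    return (R_xlen_t)z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
  };

  // forward sweep (N- neighbours), backward sweep (N+ neighbours)
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx_of(z, y, x);
        double m = J[i];
        for (size_t k = 0; k < half; ++k) {
          int zz = z + nb[k][0], yy = y + nb[k][1], xx = x + nb[k][2];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          m = std::max(m, J[idx_of(zz, yy, xx)]);
        }
        J[i] = std::min(m, mask[i]);
      }

  std::queue<R_xlen_t> fifo;
  for (int x = nx - 1; x >= 0; --x)
    for (int y = ny - 1; y >= 0; --y)
      for (int z = nz - 1; z >= 0; --z) {
        R_xlen_t i = idx_of(z, y, x);
        double m = J[i];
        for (size_t k = half; k < nb.size(); ++k) {
          int zz = z + nb[k][0], yy = y + nb[k][1], xx = x + nb[k][2];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          m = std::max(m, J[idx_of(zz, yy, xx)]);
        }
        J[i] = std::min(m, mask[i]);
        for (size_t k = half; k < nb.size(); ++k) {
          int zz = z + nb[k][0], yy = y + nb[k][1], xx = x + nb[k][2];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          R_xlen_t j = idx_of(zz, yy, xx);
          if (J[j] < J[i] && J[j] < mask[j]) {
            fifo.push(i);
            break;
          }
        }
      }

  while (!fifo.empty()) {
    R_xlen_t i = fifo.front();
    fifo.pop();
    int z = i % nz;
    int y = (i / nz) % ny;
    int x = i / ((R_xlen_t)nz * ny);
    for (size_t k = 0; k < nb.size(); ++k) {
      int zz = z + nb[k][0], yy = y + nb[k][1], xx = x + nb[k][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      R_xlen_t j = idx_of(zz, yy, xx);
      if (J[j] < J[i] && mask[j] != J[j]) {
        double v = std::min(J[i], mask[j]);
        if (v > J[j]) {
          J[j] = v;
          fifo.push(j);
        }
      }
    }
  }
  return J;
}

// Regional minima: connected iso-valued plateaus (26-connectivity) with no
// strictly lower neighbour. Returns a label field (1..K) of minima, 0 elsewhere.
// Voxels outside `mask` are ignored entirely.

// [[Rcpp::export(name = ".cpp_regional_minima")]]
IntegerVector cpp_regional_minima(NumericVector f, LogicalVector mask,
                                  IntegerVector dims, int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nz * ny * nx;
  std::vector<std::array<int, 3>> nb;
  neighbours(connectivity, nb);

  IntegerVector out(ntot, 0);
  std::vector<signed char> state(ntot, 0);  // 0 unseen, 1 in-plateau, 2 done
  std::vector<R_xlen_t> plateau, stack;
  int next_label = 0;

  for (R_xlen_t i = 0; i < ntot; ++i) {
    if (!mask[i] || state[i] != 0) continue;
    // flood the iso-valued plateau containing i
    const double v = f[i];
    bool is_min = true;
    plateau.clear();
    stack.clear();
    stack.push_back(i);
    state[i] = 1;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      plateau.push_back(cur);
      int z = cur % nz;
      int y = (cur / nz) % ny;
      int x = cur / ((R_xlen_t)nz * ny);
      for (size_t k = 0; k < nb.size(); ++k) {
        int zz = z + nb[k][0], yy = y + nb[k][1], xx = x + nb[k][2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (!mask[j]) continue;
        if (f[j] < v) { is_min = false; continue; }
        if (f[j] == v && state[j] == 0) {
          state[j] = 1;
          stack.push_back(j);
        }
      }
    }
    int lab = 0;
    if (is_min) lab = ++next_label;
    for (size_t k = 0; k < plateau.size(); ++k) {
      state[plateau[k]] = 2;
      out[plateau[k]] = lab;
    }
  }
  out.attr("n_labels") = next_label;
  return out;
}
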