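#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Threshold-free cluster enhancement of the non-negative part of a 3-D map.
// For each voxel v, sums e(h)^E * h^H * dh over thresholds h = dh, 2dh, ...,
// where e(h) is the size of the suprathreshold connected component holding v.
// Connectivity: 6 (faces) or 26 (faces+edges+corners).
// [[Rcpp::export]]
NumericVector tfce_positive_cpp(NumericVector x, IntegerVector dims,
                                double H, double E, double dh,
                                int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if (x.size() != n) stop("map length does not match dims");
  if (dh <= 0) stop("dh must be positive");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  NumericVector out(n);
  double mx = 0.0;
  for (int i = 0; i < n; ++i) {
    double v = x[i];
    if (ISNAN(v)) v = 0.0;
    if (v > mx) mx = v;
  }
  if (mx <= 0.0) return out;

  std::vector<double> val(n);
  for (int i = 0; i < n; ++i) val[i] = ISNAN(x[i]) ? 0.0 : x[i];

  // neighbour offsets
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  const int n_nb = (int)dxs.size();

  std::vector<int> label(n), stack, members;
  const int n_thresh = (int)std::floor(mx / dh + 1e-9);
  for (int t = 1; t <= n_thresh; ++t) {
    const double h = t * dh;
    const double hpow = std::pow(h, H) * dh;
    std::fill(label.begin(), label.end(), 0);
    int cur = 0;
    for (int seed = 0; seed < n; ++seed) {
      if (val[seed] < h || label[seed]) continue;
      ++cur;
      stack.clear(); members.clear();
      stack.push_back(seed); label[seed] = cur;
      while (!stack.empty()) {
        int i = stack.back(); stack.pop_back();
        members.push_back(i);
        int iz = i / (nx * ny), rem = i % (nx * ny);
        int iy = rem / nx, ix = rem % nx;
        for (int k = 0; k < n_nb; ++k) {
          int jx = ix + dxs[k], jy = iy + dys[k], jz = iz + dzs[k];
          if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
            continue;
          int j = jx + nx * (jy + ny * jz);
          if (val[j] >= h && !label[j]) {
            label[j] = cur;
            stack.push_back(j);
          }
        }
      }
      double add = std::pow((double)members.size(), E) * hpow;
      for (size_t m = 0; m < members.size(); ++m) out[members[m]] += add;
    }
  }
  return out;
}
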