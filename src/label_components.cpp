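#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labelling by breadth-first flood fill.
// Connectivity 6 (faces), 18 (faces+edges) or 26 (full neighbourhood).
// Labels are provisional (first-encounter order); the R side re-orders them.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector fg, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);

  std::vector<int> ox, oy, oz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }

  int next = 0;
  std::vector<R_xlen_t> queue;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!fg[start] || labels[start]) continue;
    ++next;
    labels[start] = next;
    queue.clear();
    queue.push_back(start);
    while (!queue.empty()) {
      R_xlen_t cur = queue.back();
      queue.pop_back();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / ((R_xlen_t)nx * ny);
      for (size_t k = 0; k < ox.size(); ++k) {
        int xx = x + ox[k], yy = y + oy[k], zz = z + oz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t nb = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (fg[nb] && !labels[nb]) {
          labels[nb] = next;
          queue.push_back(nb);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
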