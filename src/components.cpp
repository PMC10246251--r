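#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labelling on a flat logical array.
// Connectivity: 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
// Returns integer labels, 0 = background; labels are 1..n in first-voxel
// scan order, which makes the output deterministic.
// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nr = dims[0], nc = dims[1], ns = dims[2];
  const R_xlen_t n = (R_xlen_t)nr * nc * ns;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbour offsets in (di, dj, dk)
  std::vector<int> di, dj, dk;
  for (int z = -1; z <= 1; ++z)
    for (int y = -1; y <= 1; ++y)
      for (int x = -1; x <= 1; ++x) {
        int m = std::abs(x) + std::abs(y) + std::abs(z);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        di.push_back(x); dj.push_back(y); dk.push_back(z);
      }
  const int noff = (int)di.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next;
    labels[start] = next;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int k = (int)(v / ((R_xlen_t)nr * nc));
      int rem = (int)(v - (R_xlen_t)k * nr * nc);
      int j = rem / nr;
      int i = rem - j * nr;
      for (int o = 0; o < noff; ++o) {
        int ii = i + di[o], jj = j + dj[o], kk = k + dk[o];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc || kk < 0 || kk >= ns)
          continue;
        R_xlen_t w = (R_xlen_t)kk * nr * nc + (R_xlen_t)jj * nr + ii;
        if (mask[w] && labels[w] == 0) {
          labels[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("n") = next;
  return labels;
}
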