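#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// 3D connected-component labeling with 26-connectivity (iterative BFS).
// Returns an integer volume with components numbered 1..K in scan order.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(ntot, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t seed = 0; seed < ntot; ++seed) {
    if (!mask[seed] || lab[seed] != 0) continue;
    ++next;
    lab[seed] = next;
    stack.push_back(seed);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int x = cur % nx;
      int y = (cur / nx) % ny;
      int z = cur / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            R_xlen_t idx = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (mask[idx] && lab[idx] == 0) {
              lab[idx] = next;
              stack.push_back(idx);
            }
          }
        }
      }
    }
  }
  return lab;
}
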