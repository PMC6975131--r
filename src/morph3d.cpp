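#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3-D binary erosion with the 6-connected cross structuring element.
// [[Rcpp::export(name = ".erode6Cpp")]]
LogicalVector erode6Cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out(mask.size());
  auto at = [&](int i, int j, int k) { return mask[i + nx * (j + ny * k)]; };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int idx = i + nx * (j + ny * k);
        bool v = mask[idx];
        if (v) {
          // border voxels erode (background outside the grid)
          if (i == 0 || i == nx - 1 || j == 0 || j == ny - 1 ||
              k == 0 || k == nz - 1) v = false;
          else
            v = at(i - 1, j, k) && at(i + 1, j, k) &&
                at(i, j - 1, k) && at(i, j + 1, k) &&
                at(i, j, k - 1) && at(i, j, k + 1);
        }
        out[idx] = v;
      }
  return out;
}

// 26-connected component labeling of a binary mask (iterative flood fill).
// Labels are assigned in raster-scan order of the first voxel encountered.
// [[Rcpp::export(name = ".label26Cpp")]]
IntegerVector label26Cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start]) continue;
    ++next;
    stack.push_back(start);
    lab[start] = next;
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int i = cur % nx;
      const int j = (cur / nx) % ny;
      const int k = cur / ((R_xlen_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            const int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny ||
                kk < 0 || kk >= nz) continue;
            const R_xlen_t nb = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (mask[nb] && !lab[nb]) {
              lab[nb] = next;
              stack.push_back(nb);
            }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// One step of label dilation (6-connected) constrained to `allowed`:
// unlabeled allowed voxels adjacent to a label take the largest
// neighboring label (deterministic tie-break).
// [[Rcpp::export(name = ".dilateLabelsCpp")]]
IntegerVector dilateLabelsCpp(IntegerVector lab, LogicalVector allowed,
                              IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out = clone(lab);
  auto lb = [&](int i, int j, int k) -> int {
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return 0;
    return lab[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (lab[idx] || !allowed[idx]) continue;
        int best = 0;
        best = std::max(best, lb(i - 1, j, k));
        best = std::max(best, lb(i + 1, j, k));
        best = std::max(best, lb(i, j - 1, k));
        best = std::max(best, lb(i, j + 1, k));
        best = std::max(best, lb(i, j, k - 1));
        best = std::max(best, lb(i, j, k + 1));
        if (best) out[idx] = best;
      }
  out.attr("dim") = dims;
  return out;
}
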