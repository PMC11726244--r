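// 3D binary morphology for the brain-extraction surrogate:
// largest 6-connected foreground component and border-connected hole fill.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector largest_component3d(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> label(n, 0);
  IntegerVector out(n);
  int best_label = 0;
  R_xlen_t best_size = 0;
  int cur = 0;
  std::vector<R_xlen_t> stack;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || label[s]) continue;
    ++cur;
    R_xlen_t size = 0;
    stack.push_back(s);
    label[s] = cur;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      ++size;
      int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        int xx = x + dx[t], yy = y + dy[t], zz = z + dz[t];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[w] && !label[w]) { label[w] = cur; stack.push_back(w); }
      }
    }
    if (size > best_size) { best_size = size; best_label = cur; }
  }
  for (R_xlen_t s = 0; s < n; ++s) out[s] = label[s] == best_label ? 1 : 0;
  return out;
}

// Fill interior holes: background voxels not 6-connected to the border
// become foreground.
// [[Rcpp::export]]
IntegerVector fill_holes3d(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> outside(n, 0);
  std::vector<R_xlen_t> stack;

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (x != 0 && x != nx - 1 && y != 0 && y != ny - 1 &&
            z != 0 && z != nz - 1)
          continue;
        R_xlen_t v = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
        if (!mask[v] && !outside[v]) { outside[v] = 1; stack.push_back(v); }
      }
  while (!stack.empty()) {
    R_xlen_t v = stack.back(); stack.pop_back();
    int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
    const int dx[6] = {-1, 1, 0, 0, 0, 0};
    const int dy[6] = {0, 0, -1, 1, 0, 0};
    const int dz[6] = {0, 0, 0, 0, -1, 1};
    for (int t = 0; t < 6; ++t) {
      int xx = x + dx[t], yy = y + dy[t], zz = z + dz[t];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
      if (!mask[w] && !outside[w]) { outside[w] = 1; stack.push_back(w); }
    }
  }
  IntegerVector out(n);
  for (R_xlen_t s = 0; s < n; ++s) out[s] = (mask[s] || !outside[s]) ? 1 : 0;
  return out;
}
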