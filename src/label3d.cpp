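#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling with 26-connectivity.
// `mask` is a logical array in R's column-major layout with dim = c(nz, ny, nx).
// Labels are assigned in raster-scan order of each component's first voxel,
// so label k's first voxel precedes label k+1's in (x, y, z)-major order.
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector labels(n, 0);
  labels.attr("dim") = dims;
  int current = 0;
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    if (!mask[idx] || labels[idx] != 0) continue;
    ++current;
    labels[idx] = current;
    stack.push_back(idx);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int z = (int)(v % nz);
      int y = (int)((v / nz) % ny);
      int x = (int)(v / ((R_xlen_t)nz * ny));
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx;
        if (xx < 0 || xx >= nx) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            int zz = z + dz;
            if (zz < 0 || zz >= nz) continue;
            R_xlen_t w = (R_xlen_t)zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
            if (mask[w] && labels[w] == 0) {
              labels[w] = current;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  return labels;
}

// Fill 3D holes: background components (6-connectivity on the complement)
// not touching any face of the volume become foreground.
// [[Rcpp::export(name = ".fillholes3d_cpp")]]
LogicalVector fillholes3d_cpp(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<char> outside(n, 0);
  std::vector<R_xlen_t> stack;
  // seed from all boundary voxels that are background
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    int z = (int)(idx % nz);
    int y = (int)((idx / nz) % ny);
    int x = (int)(idx / ((R_xlen_t)nz * ny));
    bool boundary = (z == 0 || z == nz - 1 || y == 0 || y == ny - 1 ||
                     x == 0 || x == nx - 1);
    if (boundary && !mask[idx] && !outside[idx]) {
      outside[idx] = 1;
      stack.push_back(idx);
      while (!stack.empty()) {
        R_xlen_t v = stack.back();
        stack.pop_back();
        int vz = (int)(v % nz);
        int vy = (int)((v / nz) % ny);
        int vx = (int)(v / ((R_xlen_t)nz * ny));
        const int dz[6] = {-1, 1, 0, 0, 0, 0};
        const int dy[6] = {0, 0, -1, 1, 0, 0};
        const int dx[6] = {0, 0, 0, 0, -1, 1};
        for (int k = 0; k < 6; ++k) {
          int zz = vz + dz[k], yy = vy + dy[k], xx = vx + dx[k];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          R_xlen_t w = (R_xlen_t)zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
          if (!mask[w] && !outside[w]) {
            outside[w] = 1;
            stack.push_back(w);
          }
        }
      }
    }
  }
  LogicalVector filled(n);
  filled.attr("dim") = dims;
  for (R_xlen_t idx = 0; idx < n; ++idx)
    filled[idx] = mask[idx] || !outside[idx];
  return filled;
}
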