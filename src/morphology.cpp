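#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Volumes are R arrays in (z, y, x) column-major order: idx = z + nz*(y + ny*x).

static inline int vidx(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// 26-connected (or 6-connected) component labeling. Labels are dense from 1,
// assigned in scan order of each component's first-encountered voxel, so the
// result is deterministic for a given mask.
// [[Rcpp::export(name = ".label3_cpp")]]
IntegerVector label3_cpp(LogicalVector mask, IntegerVector dims, int connectivity = 26) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);

  std::vector<int> offz, offy, offx;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        if (connectivity == 6 && std::abs(dz) + std::abs(dy) + std::abs(dx) != 1) continue;
        offz.push_back(dz); offy.push_back(dy); offx.push_back(dx);
      }
  const int noff = (int)offz.size();

  std::vector<int> stack;
  int next = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = vidx(z, y, x, nz, ny);
        if (!mask[i] || lab[i]) continue;
        ++next;
        lab[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          int cur = stack.back(); stack.pop_back();
          int cz = cur % nz, rem = cur / nz, cy = rem % ny, cx = rem / ny;
          for (int o = 0; o < noff; ++o) {
            int zz = cz + offz[o], yy = cy + offy[o], xx = cx + offx[o];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            int j = vidx(zz, yy, xx, nz, ny);
            if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
        }
      }
  lab.attr("dim") = dims;
  lab.attr("n_components") = next;
  return lab;
}

// 2D labeling (8- or 4-connectivity) for per-slice operations; (h, w) matrix.
// [[Rcpp::export(name = ".label2_cpp")]]
IntegerVector label2_cpp(LogicalVector mask, IntegerVector dims, int connectivity = 8) {
  const int h = dims[0], w = dims[1];
  IntegerVector lab((R_xlen_t)h * w, 0);
  std::vector<int> offi, offj;
  for (int di = -1; di <= 1; ++di)
    for (int dj = -1; dj <= 1; ++dj) {
      if (di == 0 && dj == 0) continue;
      if (connectivity == 4 && std::abs(di) + std::abs(dj) != 1) continue;
      offi.push_back(di); offj.push_back(dj);
    }
  const int noff = (int)offi.size();
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      int p = i + h * j;
      if (!mask[p] || lab[p]) continue;
      ++next; lab[p] = next;
      stack.clear(); stack.push_back(p);
      while (!stack.empty()) {
        int cur = stack.back(); stack.pop_back();
        int ci = cur % h, cj = cur / h;
        for (int o = 0; o < noff; ++o) {
          int ii = ci + offi[o], jj = cj + offj[o];
          if (ii < 0 || ii >= h || jj < 0 || jj >= w) continue;
          int q = ii + h * jj;
          if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
        }
      }
    }
  lab.attr("dim") = dims;
  lab.attr("n_components") = next;
  return lab;
}

// Binary erosion with an explicit structuring element given as an n x 3 matrix
// of (dz, dy, dx) offsets. Voxels outside the volume count as background, so
// the mask is eroded at the borders (standard convention).
// [[Rcpp::export(name = ".erode3_cpp")]]
LogicalVector erode3_cpp(LogicalVector mask, IntegerVector dims, IntegerMatrix offsets) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int noff = offsets.nrow();
  LogicalVector out((R_xlen_t)nz * ny * nx, false);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = vidx(z, y, x, nz, ny);
        if (!mask[i]) continue;
        bool keep = true;
        for (int o = 0; o < noff; ++o) {
          int zz = z + offsets(o, 0), yy = y + offsets(o, 1), xx = x + offsets(o, 2);
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) { keep = false; break; }
          if (!mask[vidx(zz, yy, xx, nz, ny)]) { keep = false; break; }
        }
        if (keep) out[i] = true;
      }
  out.attr("dim") = dims;
  return out;
}

// Fill 3D holes: background voxels (6-connected) not reachable from the volume
// boundary are converted to foreground.
// [[Rcpp::export(name = ".fill_holes3_cpp")]]
LogicalVector fill_holes3_cpp(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<char> reach(n, 0);
  std::vector<int> stack;
  // seed from all boundary background voxels
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        if (z != 0 && z != nz - 1 && y != 0 && y != ny - 1 && x != 0 && x != nx - 1) continue;
        int i = vidx(z, y, x, nz, ny);
        if (!mask[i] && !reach[i]) { reach[i] = 1; stack.push_back(i); }
      }
  const int dz[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    int cur = stack.back(); stack.pop_back();
    int cz = cur % nz, rem = cur / nz, cy = rem % ny, cx = rem / ny;
    for (int o = 0; o < 6; ++o) {
      int zz = cz + dz[o], yy = cy + dy[o], xx = cx + dx[o];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      int j = vidx(zz, yy, xx, nz, ny);
      if (!mask[j] && !reach[j]) { reach[j] = 1; stack.push_back(j); }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] || !reach[i];
  out.attr("dim") = dims;
  return out;
}
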