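#include <Rcpp.h>
using namespace Rcpp;

// Resample a (z, y, x) volume onto a new lattice. The mapping aligns voxel
// centers of the two lattices on the same physical extent: for an axis with
// input spacing t_in and output spacing t_out, output index i maps to input
// coordinate (i + 0.5) * t_out / t_in - 0.5, clamped to the valid range.

static inline double src_coord(int i, double scale) {
  return (i + 0.5) * scale - 0.5;
}

// [[Rcpp::export(name = ".resample3_cpp")]]
NumericVector resample3_cpp(NumericVector x, IntegerVector dims_in,
                            IntegerVector dims_out, NumericVector scale,
                            bool nearest = false) {
  const int nz = dims_in[0], ny = dims_in[1], nx = dims_in[2];
  const int oz = dims_out[0], oy = dims_out[1], ox = dims_out[2];
  NumericVector out((R_xlen_t)oz * oy * ox);

  for (int k = 0; k < ox; ++k) {
    double fx = src_coord(k, scale[2]);
    if (fx < 0) fx = 0; if (fx > nx - 1) fx = nx - 1;
    int x0 = (int)std::floor(fx); int x1 = std::min(x0 + 1, nx - 1);
    double wx = fx - x0;
    for (int j = 0; j < oy; ++j) {
      double fy = src_coord(j, scale[1]);
      if (fy < 0) fy = 0; if (fy > ny - 1) fy = ny - 1;
      int y0 = (int)std::floor(fy); int y1 = std::min(y0 + 1, ny - 1);
      double wy = fy - y0;
      for (int i = 0; i < oz; ++i) {
        double fz = src_coord(i, scale[0]);
        if (fz < 0) fz = 0; if (fz > nz - 1) fz = nz - 1;
        int z0 = (int)std::floor(fz); int z1 = std::min(z0 + 1, nz - 1);
        double wz = fz - z0;
        double val;
        if (nearest) {
          int zz = wz < 0.5 ? z0 : z1, yy = wy < 0.5 ? y0 : y1, xx = wx < 0.5 ? x0 : x1;
          val = x[zz + nz * (yy + (R_xlen_t)ny * xx)];
        } else {
          double c00 = x[z0 + nz * (y0 + (R_xlen_t)ny * x0)] * (1 - wz) + x[z1 + nz * (y0 + (R_xlen_t)ny * x0)] * wz;
          double c10 = x[z0 + nz * (y1 + (R_xlen_t)ny * x0)] * (1 - wz) + x[z1 + nz * (y1 + (R_xlen_t)ny * x0)] * wz;
          double c01 = x[z0 + nz * (y0 + (R_xlen_t)ny * x1)] * (1 - wz) + x[z1 + nz * (y0 + (R_xlen_t)ny * x1)] * wz;
          double c11 = x[z0 + nz * (y1 + (R_xlen_t)ny * x1)] * (1 - wz) + x[z1 + nz * (y1 + (R_xlen_t)ny * x1)] * wz;
          double c0 = c00 * (1 - wy) + c10 * wy;
          double c1 = c01 * (1 - wy) + c11 * wy;
          val = c0 * (1 - wx) + c1 * wx;
        }
        out[i + oz * (j + (R_xlen_t)oy * k)] = val;
      }
    }
  }
  out.attr("dim") = dims_out;
  return out;
}
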