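#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Convolution primitives for the segmentation networks.
//
// Tensor layouts (R column-major arrays):
//   2D feature maps: (H, W, C)          index i + H*j + H*W*c
//   3D feature maps: (D, H, W, C)       index d + D*h + D*H*w + D*H*W*c
//   2D kernels:      (k, k, Cin, Cout)  depthwise: (k, k, C)
//   3D kernels:      (k, k, k, Cin, Cout)
//
// All convolutions use 'same' zero padding. Rather than materialising a full
// im2col matrix (prohibitive for 96^3 patches), forward/backward accumulate
// one GEMM per kernel offset on a gathered (N x Cin) buffer.

// ----------------------------------------------------------- 2D depthwise --

// [[Rcpp::export(name = ".dwconv2_fw_cpp")]]
NumericVector dwconv2_fw_cpp(NumericVector x, NumericVector w, int k, int dil) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int p = dil * (k - 1) / 2;
  NumericVector out(x.size());
  const double* px = REAL(x);
  const double* pw = REAL(w);
  double* po = REAL(out);
  for (int c = 0; c < C; ++c) {
    const double* plane = px + (R_xlen_t)c * H * W;
    double* oplane = po + (R_xlen_t)c * H * W;
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const double wv = pw[ki + k * kj + k * k * c];
        if (wv == 0) continue;
        const int di = ki * dil - p, dj = kj * dil - p;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int j = j0; j < j1; ++j) {
          const double* src = plane + (R_xlen_t)(j + dj) * H + (i0 + di);
          double* dst = oplane + (R_xlen_t)j * H + i0;
          for (int i = 0; i < i1 - i0; ++i) dst[i] += wv * src[i];
        }
      }
  }
  out.attr("dim") = xd;
  return out;
}

// [[Rcpp::export(name = ".dwconv2_bw_cpp")]]
List dwconv2_bw_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int k, int dil) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int p = dil * (k - 1) / 2;
  NumericVector dwv(w.size());
  NumericVector dxv(x.size());
  const double* px = REAL(x);
  const double* pw = REAL(w);
  const double* pdy = REAL(dy);
  double* pdw = REAL(dwv);
  double* pdx = REAL(dxv);
  for (int c = 0; c < C; ++c) {
    const double* plane = px + (R_xlen_t)c * H * W;
    const double* dplane = pdy + (R_xlen_t)c * H * W;
    double* dxplane = pdx + (R_xlen_t)c * H * W;
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int di = ki * dil - p, dj = kj * dil - p;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        double acc = 0;
        const double wv = pw[ki + k * kj + k * k * c];
        for (int j = j0; j < j1; ++j) {
          const double* src = plane + (R_xlen_t)(j + dj) * H + (i0 + di);
          const double* dyp = dplane + (R_xlen_t)j * H + i0;
          double* dxp = dxplane + (R_xlen_t)(j + dj) * H + (i0 + di);
          for (int i = 0; i < i1 - i0; ++i) {
            acc += src[i] * dyp[i];
            dxp[i] += wv * dyp[i];
          }
        }
        pdw[ki + k * kj + k * k * c] = acc;
      }
  }
  dwv.attr("dim") = w.attr("dim");
  dxv.attr("dim") = xd;
  return List::create(_["dw"] = dwv, _["dx"] = dxv);
}

// ----------------------------------------------------------- 2D pool / up --

// 2x2 max pooling, stride 2 (H, W even).
// [[Rcpp::export(name = ".maxpool2_fw_cpp")]]
List maxpool2_fw_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C);
  IntegerVector idx((R_xlen_t)Ho * Wo * C);
  const double* px = REAL(x);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = -1e300; int bidx = -1;
        for (int b = 0; b < 2; ++b)
          for (int a = 0; a < 2; ++a) {
            R_xlen_t ii = (2 * i + a) + (R_xlen_t)H * (2 * j + b) + (R_xlen_t)H * W * c;
            if (px[ii] > best) { best = px[ii]; bidx = (int)ii; }
          }
        R_xlen_t oi = i + (R_xlen_t)Ho * j + (R_xlen_t)Ho * Wo * c;
        y[oi] = best; idx[oi] = bidx;
      }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bw_cpp")]]
NumericVector maxpool2_bw_cpp(IntegerVector idx, NumericVector dy,
                              IntegerVector dims_in) {
  NumericVector dx((R_xlen_t)dims_in[0] * dims_in[1] * dims_in[2]);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  dx.attr("dim") = dims_in;
  return dx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export(name = ".up2_fw_cpp")]]
NumericVector up2_fw_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  NumericVector y((R_xlen_t)4 * H * W * C);
  const double* px = REAL(x);
  double* py = REAL(y);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double v = px[i + (R_xlen_t)H * j + (R_xlen_t)H * W * c];
        for (int b = 0; b < 2; ++b)
          for (int a = 0; a < 2; ++a)
            py[(2 * i + a) + (R_xlen_t)2 * H * (2 * j + b) + (R_xlen_t)4 * H * W * c] = v;
      }
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C);
  return y;
}

// [[Rcpp::export(name = ".up2_bw_cpp")]]
NumericVector up2_bw_cpp(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  const int H2 = yd[0], W2 = yd[1], C = yd[2];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector dx((R_xlen_t)H * W * C);
  const double* pdy = REAL(dy);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double s = 0;
        for (int b = 0; b < 2; ++b)
          for (int a = 0; a < 2; ++a)
            s += pdy[(2 * i + a) + (R_xlen_t)H2 * (2 * j + b) + (R_xlen_t)H2 * W2 * c];
        dx[i + (R_xlen_t)H * j + (R_xlen_t)H * W * c] = s;
      }
  dx.attr("dim") = IntegerVector::create(H, W, C);
  return dx;
}

// ---------------------------------------------------------------- 3D dense --

static inline void out_dims3(int D, int H, int W, int s, int& Do, int& Ho, int& Wo) {
  Do = (D + s - 1) / s; Ho = (H + s - 1) / s; Wo = (W + s - 1) / s;
}

static inline int pad_beg(int n, int no, int s, int k, int dil) {
  int tot = (no - 1) * s + (k - 1) * dil + 1 - n;
  if (tot < 0) tot = 0;
  return tot / 2;
}

// Gather shifted input (one kernel offset) into Xg (N_out x C); zero outside.
static void gather3(const double* px, int D, int H, int W, int C,
                    int Do, int Ho, int Wo, int s,
                    int od_off, int oh_off, int ow_off, arma::mat& Xg) {
  Xg.zeros();
  const R_xlen_t Nin = (R_xlen_t)D * H * W;
  auto lohi = [s](int off, int n, int no, int& lo, int& hi) {
    // valid out indices: 0 <= o*s + off < n
    lo = off < 0 ? (-off + s - 1) / s : 0;
    hi = std::min(no - 1, (n - 1 - off) / s);
  };
  int dlo, dhi, hlo, hhi, wlo, whi;
  lohi(od_off, D, Do, dlo, dhi);
  lohi(oh_off, H, Ho, hlo, hhi);
  lohi(ow_off, W, Wo, wlo, whi);
  if (dlo > dhi || hlo > hhi || wlo > whi) return;
  for (int c = 0; c < C; ++c) {
    const double* plane = px + Nin * c;
    double* col = Xg.colptr(c);
    for (int ow = wlo; ow <= whi; ++ow) {
      const int iw = ow * s + ow_off;
      for (int oh = hlo; oh <= hhi; ++oh) {
        const int ih = oh * s + oh_off;
        const double* src = plane + (R_xlen_t)D * (ih + (R_xlen_t)H * iw);
        double* dst = col + dlo + (R_xlen_t)Do * (oh + (R_xlen_t)Ho * ow);
        if (s == 1) {
          std::copy(src + dlo + od_off, src + dhi + 1 + od_off, dst);
        } else {
          for (int od = dlo; od <= dhi; ++od)
            dst[od - dlo] = src[od * s + od_off];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3_fw_cpp")]]
NumericVector conv3_fw_cpp(NumericVector x, NumericVector w, NumericVector b,
                           int k, int stride) {
  IntegerVector xd = x.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[4];
  int Do, Ho, Wo;
  out_dims3(D, H, W, stride, Do, Ho, Wo);
  const int N = Do * Ho * Wo;
  const int pd = pad_beg(D, Do, stride, k, 1);
  const int ph = pad_beg(H, Ho, stride, k, 1);
  const int pw_ = pad_beg(W, Wo, stride, k, 1);

  arma::mat Y(N, Cout, arma::fill::zeros);
  arma::mat Xg(N, C);
  arma::mat Wo_(C, Cout);
  const double* px = REAL(x);
  const double* pwv = REAL(w);
  const int kk = k * k, kkk = k * k * k;

  for (int kw = 0; kw < k; ++kw)
    for (int kh = 0; kh < k; ++kh)
      for (int kd = 0; kd < k; ++kd) {
        gather3(px, D, H, W, C, Do, Ho, Wo, stride,
                kd - pd, kh - ph, kw - pw_, Xg);
        for (int c = 0; c < C; ++c)
          for (int co = 0; co < Cout; ++co)
            Wo_(c, co) = pwv[kd + k * kh + kk * kw + (R_xlen_t)kkk * c + (R_xlen_t)kkk * C * co];
        Y += Xg * Wo_;
      }
  NumericVector out((R_xlen_t)N * Cout);
  double* po = REAL(out);
  const double* pb = REAL(b);
  for (int co = 0; co < Cout; ++co) {
    const double* yc = Y.colptr(co);
    double* oc = po + (R_xlen_t)co * N;
    for (int i = 0; i < N; ++i) oc[i] = yc[i] + pb[co];
  }
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, Cout);
  return out;
}

// [[Rcpp::export(name = ".conv3_bw_cpp")]]
List conv3_bw_cpp(NumericVector x, NumericVector w, NumericVector dy,
                  int k, int stride) {
  IntegerVector xd = x.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[4];
  int Do, Ho, Wo;
  out_dims3(D, H, W, stride, Do, Ho, Wo);
  const int N = Do * Ho * Wo;
  const int pd = pad_beg(D, Do, stride, k, 1);
  const int ph = pad_beg(H, Ho, stride, k, 1);
  const int pw_ = pad_beg(W, Wo, stride, k, 1);
  const int kk = k * k, kkk = k * k * k;

  const double* px = REAL(x);
  const double* pwv = REAL(w);
  arma::mat dY((double*)REAL(dy), N, Cout, false, true);

  NumericVector dwv(w.size());
  NumericVector dxv(x.size());
  double* pdw = REAL(dwv);
  double* pdx = REAL(dxv);
  arma::mat Xg(N, C);
  arma::mat Wo_(C, Cout);

  auto lohi = [stride](int off, int n, int no, int& lo, int& hi) {
    lo = off < 0 ? (-off + stride - 1) / stride : 0;
    hi = std::min(no - 1, (n - 1 - off) / stride);
  };

  for (int kw = 0; kw < k; ++kw)
    for (int kh = 0; kh < k; ++kh)
      for (int kd = 0; kd < k; ++kd) {
        const int od_off = kd - pd, oh_off = kh - ph, ow_off = kw - pw_;
        gather3(px, D, H, W, C, Do, Ho, Wo, stride, od_off, oh_off, ow_off, Xg);
        arma::mat dWo = Xg.t() * dY;
        for (int c = 0; c < C; ++c)
          for (int co = 0; co < Cout; ++co) {
            pdw[kd + k * kh + kk * kw + (R_xlen_t)kkk * c + (R_xlen_t)kkk * C * co] += dWo(c, co);
            Wo_(c, co) = pwv[kd + k * kh + kk * kw + (R_xlen_t)kkk * c + (R_xlen_t)kkk * C * co];
          }
        arma::mat G = dY * Wo_.t();   // N x C; scatter-add into dx
        int dlo, dhi, hlo, hhi, wlo, whi;
        lohi(od_off, D, Do, dlo, dhi);
        lohi(oh_off, H, Ho, hlo, hhi);
        lohi(ow_off, W, Wo, wlo, whi);
        if (dlo > dhi || hlo > hhi || wlo > whi) continue;
        for (int c = 0; c < C; ++c) {
          double* plane = pdx + (R_xlen_t)D * H * W * c;
          const double* col = G.colptr(c);
          for (int ow = wlo; ow <= whi; ++ow) {
            const int iw = ow * stride + ow_off;
            for (int oh = hlo; oh <= hhi; ++oh) {
              const int ih = oh * stride + oh_off;
              double* dst = plane + (R_xlen_t)D * (ih + (R_xlen_t)H * iw);
              const double* src = col + dlo + (R_xlen_t)Do * (oh + (R_xlen_t)Ho * ow);
              for (int od = dlo; od <= dhi; ++od)
                dst[od * stride + od_off] += src[od - dlo];
            }
          }
        }
      }
  NumericVector dbv(Cout);
  const double* pdy = REAL(dy);
  for (int co = 0; co < Cout; ++co) {
    const double* c0 = pdy + (R_xlen_t)co * N;
    double s = 0;
    for (int i = 0; i < N; ++i) s += c0[i];
    dbv[co] = s;
  }
  dwv.attr("dim") = wd;
  dxv.attr("dim") = xd;
  return List::create(_["dw"] = dwv, _["db"] = dbv, _["dx"] = dxv);
}

// ----------------------------------------------------------- 3D upsampling --

// [[Rcpp::export(name = ".up3_fw_cpp")]]
NumericVector up3_fw_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  NumericVector y((R_xlen_t)8 * D * H * W * C);
  const double* px = REAL(x);
  double* py = REAL(y);
  const int D2 = 2 * D, H2 = 2 * H;
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        for (int d = 0; d < D; ++d) {
          double v = px[d + (R_xlen_t)D * (h + (R_xlen_t)H * (w + (R_xlen_t)W * c))];
          for (int cw = 0; cw < 2; ++cw)
            for (int ch = 0; ch < 2; ++ch)
              for (int cd = 0; cd < 2; ++cd)
                py[(2 * d + cd) + (R_xlen_t)D2 * ((2 * h + ch) + (R_xlen_t)H2 * ((2 * w + cw) + (R_xlen_t)2 * W * c))] = v;
        }
  y.attr("dim") = IntegerVector::create(2 * D, 2 * H, 2 * W, C);
  return y;
}

// [[Rcpp::export(name = ".up3_bw_cpp")]]
NumericVector up3_bw_cpp(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  const int D2 = yd[0], H2 = yd[1], W2 = yd[2], C = yd[3];
  const int D = D2 / 2, H = H2 / 2, W = W2 / 2;
  NumericVector dx((R_xlen_t)D * H * W * C);
  const double* pdy = REAL(dy);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        for (int d = 0; d < D; ++d) {
          double s = 0;
          for (int cw = 0; cw < 2; ++cw)
            for (int ch = 0; ch < 2; ++ch)
              for (int cd = 0; cd < 2; ++cd)
                s += pdy[(2 * d + cd) + (R_xlen_t)D2 * ((2 * h + ch) + (R_xlen_t)H2 * ((2 * w + cw) + (R_xlen_t)W2 * c))];
          dx[d + (R_xlen_t)D * (h + (R_xlen_t)H * (w + (R_xlen_t)W * c))] = s;
        }
  dx.attr("dim") = IntegerVector::create(D, H, W, C);
  return dx;
}
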