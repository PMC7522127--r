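#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fused building blocks for the 2D network: the multi-rate depthwise branch
// stack with pointwise fusion, and per-channel (spatial) batch
// normalisation. Keeping the whole block in C++ avoids repeated R-level
// array copies, which dominate the runtime otherwise.

static void dw_accum(const double* __restrict__ px, const double* __restrict__ pw, double* __restrict__ po,
                     int H, int W, int C, int k, int dil) {
  const int p = dil * (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    const double* plane = px + (R_xlen_t)c * H * W;
    double* oplane = po + (R_xlen_t)c * H * W;
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const double wv = pw[ki + k * kj + k * k * c];
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
}

// x: (H, W, C); dws: list of (k,k,C) depthwise kernels (one per dilation
// rate); pw: (nr*C, Cout) pointwise weights; b: (Cout). Concat merge.
// [[Rcpp::export(name = ".sepdil_fw_cpp")]]
List sepdil_fw_cpp(NumericVector x, List dws, NumericMatrix pw,
                   NumericVector b, IntegerVector rates, int k) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int nr = rates.size();
  const int N = H * W;
  const int Cout = pw.ncol();
  NumericMatrix concat(N, nr * C);
  std::fill(concat.begin(), concat.end(), 0.0);
  for (int r = 0; r < nr; ++r) {
    NumericVector w = dws[r];
    dw_accum(REAL(x), REAL(w), REAL(concat) + (R_xlen_t)r * C * N,
             H, W, C, k, rates[r]);
  }
  arma::mat CM((double*)REAL(concat), N, nr * C, false, true);
  arma::mat PW((double*)REAL(pw), nr * C, Cout, false, true);
  arma::mat Y = CM * PW;
  NumericVector out((R_xlen_t)N * Cout);
  double* po = REAL(out);
  for (int co = 0; co < Cout; ++co) {
    const double* yc = Y.colptr(co);
    double* oc = po + (R_xlen_t)co * N;
    const double bc = b[co];
    for (int i = 0; i < N; ++i) oc[i] = yc[i] + bc;
  }
  out.attr("dim") = IntegerVector::create(H, W, Cout);
  return List::create(_["y"] = out, _["concat"] = concat);
}

static void dw_bw(const double* __restrict__ px, const double* __restrict__ pw, const double* __restrict__ pdy,
                  double* __restrict__ pdw, double* __restrict__ pdx, int H, int W, int C, int k,
                  int dil) {
  const int p = dil * (k - 1) / 2;
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
        pdw[ki + k * kj + k * k * c] += acc;
      }
  }
}

// [[Rcpp::export(name = ".sepdil_bw_cpp")]]
List sepdil_bw_cpp(NumericVector x, List dws, NumericMatrix pw,
                   NumericMatrix concat, NumericVector dy,
                   IntegerVector rates, int k) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int nr = rates.size();
  const int N = H * W;
  const int Cout = pw.ncol();
  arma::mat DY((double*)REAL(dy), N, Cout, false, true);
  arma::mat CM((double*)REAL(concat), N, nr * C, false, true);
  arma::mat PW((double*)REAL(pw), nr * C, Cout, false, true);
  arma::mat dPW = CM.t() * DY;
  arma::mat dCM = DY * PW.t();
  NumericVector db(Cout);
  for (int co = 0; co < Cout; ++co) {
    const double* c0 = REAL(dy) + (R_xlen_t)co * N;
    double s = 0;
    for (int i = 0; i < N; ++i) s += c0[i];
    db[co] = s;
  }
  NumericVector dx(x.size());
  List ddws(nr);
  for (int r = 0; r < nr; ++r) {
    NumericVector w = dws[r];
    NumericVector dwv(w.size());
    dw_bw(REAL(x), REAL(w), dCM.colptr((R_xlen_t)r * C),
          REAL(dwv), REAL(dx), H, W, C, k, rates[r]);
    dwv.attr("dim") = w.attr("dim");
    ddws[r] = dwv;
  }
  dx.attr("dim") = xd;
  NumericMatrix dpw_out(nr * C, Cout);
  std::copy(dPW.begin(), dPW.end(), dpw_out.begin());
  return List::create(_["dx"] = dx, _["ddw"] = ddws, _["dpw"] = dpw_out,
                      _["db"] = db);
}

// Per-channel batch norm over all leading (spatial) positions of the last
// axis. If train, statistics come from x itself; else from mu/var supplied.
// [[Rcpp::export(name = ".bn_fw_cpp")]]
List bn_fw_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
               NumericVector run_mu, NumericVector run_var, bool train,
               double eps) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[xd.size() - 1];
  R_xlen_t N = 1;
  for (int i = 0; i < xd.size() - 1; ++i) N *= xd[i];
  NumericVector y(x.size()), xhat(x.size());
  NumericVector mu(C), var(C), ivar(C);
  const double* px = REAL(x);
  for (int c = 0; c < C; ++c) {
    const double* col = px + N * c;
    double m, v;
    if (train) {
      double s = 0, s2 = 0;
      for (R_xlen_t i = 0; i < N; ++i) { s += col[i]; s2 += col[i] * col[i]; }
      m = s / N; v = s2 / N - m * m;
      if (v < 0) v = 0;
    } else { m = run_mu[c]; v = run_var[c]; }
    mu[c] = m; var[c] = v;
    const double iv = 1.0 / std::sqrt(v + eps);
    ivar[c] = iv;
    const double g = gamma[c], bb = beta[c];
    double* yc = REAL(y) + N * c;
    double* xh = REAL(xhat) + N * c;
    for (R_xlen_t i = 0; i < N; ++i) {
      const double h = (col[i] - m) * iv;
      xh[i] = h;
      yc[i] = g * h + bb;
    }
  }
  y.attr("dim") = xd;
  xhat.attr("dim") = xd;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["ivar"] = ivar,
                      _["mu"] = mu, _["var"] = var);
}

// [[Rcpp::export(name = ".bn_bw_cpp")]]
List bn_bw_cpp(NumericVector xhat, NumericVector ivar, NumericVector gamma,
               NumericVector dy, bool train) {
  IntegerVector xd = xhat.attr("dim");
  const int C = xd[xd.size() - 1];
  R_xlen_t N = 1;
  for (int i = 0; i < xd.size() - 1; ++i) N *= xd[i];
  NumericVector dx(xhat.size()), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* xh = REAL(xhat) + N * c;
    const double* dyc = REAL(dy) + N * c;
    double s1 = 0, s2 = 0;
    for (R_xlen_t i = 0; i < N; ++i) {
      s1 += dyc[i];
      s2 += dyc[i] * xh[i];
    }
    dbeta[c] = s1; dgamma[c] = s2;
    const double g = gamma[c], iv = ivar[c];
    double* dxc = REAL(dx) + N * c;
    if (train) {
      const double a = g * s1 / N, bterm = g * s2 / N;
      for (R_xlen_t i = 0; i < N; ++i)
        dxc[i] = iv * (g * dyc[i] - a - xh[i] * bterm);
    } else {
      for (R_xlen_t i = 0; i < N; ++i) dxc[i] = iv * g * dyc[i];
    }
  }
  dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Residual add + ReLU in one pass.
// [[Rcpp::export(name = ".add_relu_cpp")]]
NumericVector add_relu_cpp(NumericVector a, NumericVector b) {
  NumericVector y(a.size());
  const double* pa = REAL(a); const double* pb = REAL(b);
  double* py = REAL(y);
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    const double v = pa[i] + pb[i];
    py[i] = v > 0 ? v : 0;
  }
  y.attr("dim") = a.attr("dim");
  return y;
}

// dy masked by the positivity of y (ReLU backward).
// [[Rcpp::export(name = ".mask_pos_cpp")]]
NumericVector mask_pos_cpp(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  const double* pd = REAL(dy); const double* py = REAL(y);
  double* px = REAL(dx);
  for (R_xlen_t i = 0; i < dy.size(); ++i) px[i] = py[i] > 0 ? pd[i] : 0;
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// ------------------------------------------------------------- batched 2D --
// Evaluation-mode batched forward support. Batched feature maps use layout
// (H, W, B, C) -- channels last -- so pointwise convolutions and batch norm
// see an (H*W*B, C) matrix without reordering. Only the depthwise stack
// needs a dedicated kernel.

static void dw_accum_plane(const double* __restrict__ plane, const double* __restrict__ kern,
                           double* __restrict__ oplane, int H, int W, int k, int dil) {
  const int p = dil * (k - 1) / 2;
  for (int kj = 0; kj < k; ++kj)
    for (int ki = 0; ki < k; ++ki) {
      const double wv = kern[ki + k * kj];
      const int di = ki * dil - p, dj = kj * dil - p;
      const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
      const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
      for (int j = j0; j < j1; ++j) {
        const double* __restrict__ src = plane + (R_xlen_t)(j + dj) * H + (i0 + di);
        double* __restrict__ dst = oplane + (R_xlen_t)j * H + i0;
        for (int i = 0; i < i1 - i0; ++i) dst[i] += wv * src[i];
      }
    }
}

// x: (H, W, B, C); dws: list of (k,k,C); pw: (nr*C, Cout); returns
// (H, W, B, Cout).
// [[Rcpp::export(name = ".sepdil_fw_batch_cpp")]]
NumericVector sepdil_fw_batch_cpp(NumericVector x, List dws, NumericMatrix pw,
                                  NumericVector b, IntegerVector rates, int k) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], B = xd[2], C = xd[3];
  const int nr = rates.size();
  const int N = H * W;
  const R_xlen_t NB = (R_xlen_t)N * B;
  const int Cout = pw.ncol();
  arma::mat CM(NB, (R_xlen_t)nr * C, arma::fill::zeros);
  const double* px = REAL(x);
  for (int r = 0; r < nr; ++r) {
    NumericVector w = dws[r];
    const double* pwk = REAL(w);
    for (int c = 0; c < C; ++c) {
      double* col = CM.colptr((R_xlen_t)r * C + c);
      for (int bb = 0; bb < B; ++bb)
        dw_accum_plane(px + NB * c + (R_xlen_t)N * bb, pwk + k * k * c,
                       col + (R_xlen_t)N * bb, H, W, k, rates[r]);
    }
  }
  arma::mat PW((double*)REAL(pw), (R_xlen_t)nr * C, Cout, false, true);
  arma::mat Y = CM * PW;
  NumericVector out(NB * Cout);
  double* po = REAL(out);
  for (int co = 0; co < Cout; ++co) {
    const double* yc = Y.colptr(co);
    double* oc = po + NB * co;
    const double bc = b[co];
    for (R_xlen_t i = 0; i < NB; ++i) oc[i] = yc[i] + bc;
  }
  out.attr("dim") = IntegerVector::create(H, W, B, Cout);
  return out;
}
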