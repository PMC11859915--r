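// Numerical cores for the segmentation network.
//
// Tensor layout everywhere: column-major R array dim c(C, H, W, N), i.e.
// linear index c + C*(h + H*(w + W*n)). Channels are contiguous, which lets
// im2col move whole channel fibres with memcpy and keeps the 1x1-convolution
// fast path a single GEMM over the full batch.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out_dim(int in, int k, int stride, int pad, int dil) {
  return (in + 2 * pad - ((k - 1) * dil + 1)) / stride + 1;
}

// Reuse `out` when it already has the right length (buffer pool support);
// `zero` clears it for kernels that accumulate.
static NumericVector ensure_out(NumericVector out, R_xlen_t n, bool zero) {
  if (out.size() == n) {
    if (zero) std::memset(out.begin(), 0, sizeof(double) * n);
    return out;
  }
  return NumericVector(n);
}

// M: (C*kh*kw) x (OH*OW); row index k = c + C*(i + kh*j), col index oh + OH*ow
static void im2col(const double* x, int C, int H, int W,
                   int kh, int kw, int stride, int pad, int dil,
                   int OH, int OW, arma::mat& M) {
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      int col = oh + OH * ow;
      double* colp = M.colptr(col);
      for (int j = 0; j < kw; ++j) {
        int iw = ow * stride - pad + j * dil;
        for (int i = 0; i < kh; ++i) {
          int ih = oh * stride - pad + i * dil;
          double* dst = colp + (size_t)C * (i + kh * j);
          if (ih < 0 || ih >= H || iw < 0 || iw >= W) {
            std::memset(dst, 0, sizeof(double) * C);
          } else {
            std::memcpy(dst, x + (size_t)C * (ih + (size_t)H * iw),
                        sizeof(double) * C);
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& M, double* gx, int C, int H, int W,
                       int kh, int kw, int stride, int pad, int dil,
                       int OH, int OW) {
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      int col = oh + OH * ow;
      const double* colp = M.colptr(col);
      for (int j = 0; j < kw; ++j) {
        int iw = ow * stride - pad + j * dil;
        if (iw < 0 || iw >= W) continue;
        for (int i = 0; i < kh; ++i) {
          int ih = oh * stride - pad + i * dil;
          if (ih < 0 || ih >= H) continue;
          const double* src = colp + (size_t)C * (i + kh * j);
          double* dst = gx + (size_t)C * (ih + (size_t)H * iw);
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
}

// Single-precision im2col (element cast from the double source).
static void im2col_f(const double* x, int C, int H, int W,
                     int kh, int kw, int stride, int pad, int dil,
                     int OH, int OW, arma::fmat& M) {
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      int col = oh + OH * ow;
      float* colp = M.colptr(col);
      for (int j = 0; j < kw; ++j) {
        int iw = ow * stride - pad + j * dil;
        for (int i = 0; i < kh; ++i) {
          int ih = oh * stride - pad + i * dil;
          float* dst = colp + (size_t)C * (i + kh * j);
          if (ih < 0 || ih >= H || iw < 0 || iw >= W) {
            std::memset(dst, 0, sizeof(float) * C);
          } else {
            const double* src = x + (size_t)C * (ih + (size_t)H * iw);
            for (int c = 0; c < C; ++c) dst[c] = (float)src[c];
          }
        }
      }
    }
  }
}

static void col2im_add_f(const arma::fmat& M, double* gx, int C, int H,
                         int W, int kh, int kw, int stride, int pad, int dil,
                         int OH, int OW) {
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      int col = oh + OH * ow;
      const float* colp = M.colptr(col);
      for (int j = 0; j < kw; ++j) {
        int iw = ow * stride - pad + j * dil;
        if (iw < 0 || iw >= W) continue;
        for (int i = 0; i < kh; ++i) {
          int ih = oh * stride - pad + i * dil;
          if (ih < 0 || ih >= H) continue;
          const float* src = colp + (size_t)C * (i + kh * j);
          double* dst = gx + (size_t)C * (ih + (size_t)H * iw);
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
}

static arma::fmat to_f(const double* p, size_t nr, size_t nc) {
  arma::fmat F(nr, nc);
  float* fp = F.memptr();
  for (size_t i = 0; i < nr * nc; ++i) fp[i] = (float)p[i];
  return F;
}

static void from_f(const arma::fmat& F, double* p) {
  const float* fp = F.memptr();
  for (size_t i = 0; i < F.n_elem; ++i) p[i] = fp[i];
}

// GEMMs above this FLOP count run in single precision: training-scale
// convolutions get the ~2x sgemm speedup while small desk-test tensors
// keep full double precision.
static const double kFloatFlops = 2e6;

// Dense 2-D convolution. w: c(Cout, Cin, kh, kw); b: length Cout or 0.
// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, IntegerVector xd,
                           NumericVector w, IntegerVector wd,
                           NumericVector b, int stride, int pad, int dil,
                           NumericVector out = NumericVector(0)) {
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  const int Cout = wd[0], Cin = wd[1], kh = wd[2], kw = wd[3];
  if (Cin != C) stop("conv: channel mismatch (%d vs %d)", Cin, C);
  const int OH = conv_out_dim(H, kh, stride, pad, dil);
  const int OW = conv_out_dim(W, kw, stride, pad, dil);
  if (OH < 1 || OW < 1) stop("conv: empty output for %dx%d input", H, W);
  NumericVector y = ensure_out(out, (R_xlen_t)Cout * OH * OW * N, false);
  const size_t K = (size_t)Cin * kh * kw;
  const bool hasb = b.size() == Cout;
  const bool use_f =
      (double)Cout * K * OH * OW * N > kFloatFlops;
  if (kh == 1 && kw == 1 && stride == 1 && pad == 0) {
    const size_t P = (size_t)H * W * N;
    if (use_f) {
      arma::fmat Wf = to_f(w.begin(), Cout, K);
      arma::fmat Xf = to_f(x.begin(), C, P);
      arma::fmat Yf = Wf * Xf;
      if (hasb) {
        arma::fvec bf = arma::conv_to<arma::fvec>::from(
            arma::vec(const_cast<double*>(b.begin()), Cout, false));
        Yf.each_col() += bf;
      }
      from_f(Yf, y.begin());
    } else {
      arma::mat Wm(const_cast<double*>(w.begin()), Cout, K, false);
      arma::mat X(const_cast<double*>(x.begin()), C, P, false);
      arma::mat Y(y.begin(), Cout, P, false, true);
      Y = Wm * X;
      if (hasb) {
        arma::vec bv(const_cast<double*>(b.begin()), Cout, false);
        Y.each_col() += bv;
      }
    }
  } else if (use_f) {
    arma::fmat Wf = to_f(w.begin(), Cout, K);
    arma::fvec bf;
    if (hasb)
      bf = arma::conv_to<arma::fvec>::from(
          arma::vec(const_cast<double*>(b.begin()), Cout, false));
    arma::fmat M(K, (size_t)OH * OW);
    for (int n = 0; n < N; ++n) {
      im2col_f(x.begin() + (size_t)C * H * W * n, C, H, W, kh, kw, stride,
               pad, dil, OH, OW, M);
      arma::fmat Yf = Wf * M;
      if (hasb) Yf.each_col() += bf;
      from_f(Yf, y.begin() + (size_t)Cout * OH * OW * n);
    }
  } else {
    arma::mat Wm(const_cast<double*>(w.begin()), Cout, K, false);
    arma::vec bv;
    if (hasb) bv = arma::vec(const_cast<double*>(b.begin()), Cout, false);
    arma::mat M(K, (size_t)OH * OW);
    for (int n = 0; n < N; ++n) {
      im2col(x.begin() + (size_t)C * H * W * n, C, H, W, kh, kw, stride, pad,
             dil, OH, OW, M);
      arma::mat Y(y.begin() + (size_t)Cout * OH * OW * n, Cout,
                  (size_t)OH * OW, false, true);
      Y = Wm * M;
      if (hasb) Y.each_col() += bv;
    }
  }
  y.attr("dim") = IntegerVector::create(Cout, OH, OW, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, IntegerVector xd,
                  NumericVector w, IntegerVector wd,
                  NumericVector gy, bool has_bias,
                  int stride, int pad, int dil,
                  NumericVector gxout = NumericVector(0)) {
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  const int Cout = wd[0], Cin = wd[1], kh = wd[2], kw = wd[3];
  const int OH = conv_out_dim(H, kh, stride, pad, dil);
  const int OW = conv_out_dim(W, kw, stride, pad, dil);
  NumericVector gx = ensure_out(gxout, (R_xlen_t)C * H * W * N, true);
  NumericVector gw((R_xlen_t)Cout * Cin * kh * kw);
  const size_t K = (size_t)Cin * kh * kw;
  const bool use_f =
      (double)Cout * K * OH * OW * N > kFloatFlops;
  if (kh == 1 && kw == 1 && stride == 1 && pad == 0) {
    const size_t P = (size_t)H * W * N;
    if (use_f) {
      arma::fmat Wf = to_f(w.begin(), Cout, K);
      arma::fmat Xf = to_f(x.begin(), C, P);
      arma::fmat GYf = to_f(gy.begin(), Cout, P);
      arma::fmat GWf = GYf * Xf.t();
      arma::fmat GXf = Wf.t() * GYf;
      from_f(GWf, gw.begin());
      from_f(GXf, gx.begin());
    } else {
      arma::mat Wm(const_cast<double*>(w.begin()), Cout, K, false);
      arma::mat X(const_cast<double*>(x.begin()), C, P, false);
      arma::mat GY(const_cast<double*>(gy.begin()), Cout, P, false);
      arma::mat GW(gw.begin(), Cout, K, false, true);
      arma::mat GX(gx.begin(), C, P, false, true);
      GW = GY * X.t();
      GX = Wm.t() * GY;
    }
  } else if (use_f) {
    arma::fmat Wf = to_f(w.begin(), Cout, K);
    arma::fmat GWf(Cout, K, arma::fill::zeros);
    arma::fmat M(K, (size_t)OH * OW);
    for (int n = 0; n < N; ++n) {
      im2col_f(x.begin() + (size_t)C * H * W * n, C, H, W, kh, kw, stride,
               pad, dil, OH, OW, M);
      arma::fmat GYf = to_f(gy.begin() + (size_t)Cout * OH * OW * n, Cout,
                            (size_t)OH * OW);
      GWf += GYf * M.t();
      arma::fmat Gcol = Wf.t() * GYf;
      col2im_add_f(Gcol, gx.begin() + (size_t)C * H * W * n, C, H, W, kh, kw,
                   stride, pad, dil, OH, OW);
    }
    from_f(GWf, gw.begin());
  } else {
    arma::mat Wm(const_cast<double*>(w.begin()), Cout, K, false);
    arma::mat GW(gw.begin(), Cout, K, false, true);
    arma::mat M(K, (size_t)OH * OW);
    for (int n = 0; n < N; ++n) {
      im2col(x.begin() + (size_t)C * H * W * n, C, H, W, kh, kw, stride, pad,
             dil, OH, OW, M);
      arma::mat GY(const_cast<double*>(gy.begin()) + (size_t)Cout * OH * OW * n,
                   Cout, (size_t)OH * OW, false);
      GW += GY * M.t();
      arma::mat Gcol = Wm.t() * GY;
      col2im_add(Gcol, gx.begin() + (size_t)C * H * W * n, C, H, W, kh, kw,
                 stride, pad, dil, OH, OW);
    }
  }
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  List out = List::create(_["gx"] = gx, _["gw"] = gw);
  if (has_bias) {
    NumericVector gb(Cout);
    const double* gp = gy.begin();
    R_xlen_t P = (R_xlen_t)OH * OW * N;
    for (R_xlen_t p = 0; p < P; ++p)
      for (int c = 0; c < Cout; ++c) gb[c] += gp[c + (size_t)Cout * p];
    out["gb"] = gb;
  }
  return out;
}

// Activations: 0 = relu, 1 = relu6, 2 = hard-swish, 3 = sigmoid.
// [[Rcpp::export]]
NumericVector cpp_act_fwd(NumericVector x, int kind) {
  R_xlen_t n = x.size();
  NumericVector y(n);
  const double* xp = x.begin();
  double* yp = y.begin();
  switch (kind) {
  case 0:
    for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0;
    break;
  case 1:
    for (R_xlen_t i = 0; i < n; ++i) {
      double v = xp[i];
      yp[i] = v < 0 ? 0 : (v > 6 ? 6 : v);
    }
    break;
  case 2:
    for (R_xlen_t i = 0; i < n; ++i) {
      double v = xp[i];
      double r = v + 3;
      r = r < 0 ? 0 : (r > 6 ? 6 : r);
      yp[i] = v * r / 6;
    }
    break;
  case 3:
    for (R_xlen_t i = 0; i < n; ++i) yp[i] = 1 / (1 + std::exp(-xp[i]));
    break;
  default: stop("unknown activation kind");
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_act_bwd(NumericVector x, NumericVector y, NumericVector gy,
                          int kind) {
  R_xlen_t n = x.size();
  NumericVector gx(n);
  const double* xp = x.begin();
  const double* yp = y.begin();
  const double* gp = gy.begin();
  double* o = gx.begin();
  switch (kind) {
  case 0:
    for (R_xlen_t i = 0; i < n; ++i) o[i] = xp[i] > 0 ? gp[i] : 0;
    break;
  case 1:
    for (R_xlen_t i = 0; i < n; ++i)
      o[i] = (xp[i] > 0 && xp[i] < 6) ? gp[i] : 0;
    break;
  case 2:
    for (R_xlen_t i = 0; i < n; ++i) {
      double v = xp[i];
      o[i] = v <= -3 ? 0 : (v >= 3 ? gp[i] : gp[i] * (2 * v + 3) / 6);
    }
    break;
  case 3:
    for (R_xlen_t i = 0; i < n; ++i) o[i] = gp[i] * yp[i] * (1 - yp[i]);
    break;
  default: stop("unknown activation kind");
  }
  gx.attr("dim") = x.attr("dim");
  return gx;
}

// In-place activation forward for activations whose backward needs only
// the output (relu, relu6, sigmoid). Mutates and returns `x`; the tape
// only applies it to tensors with a single consumer.
// [[Rcpp::export]]
NumericVector cpp_act_fwd_ip(NumericVector x, int kind) {
  R_xlen_t n = x.size();
  double* xp = x.begin();
  switch (kind) {
  case 0:
    for (R_xlen_t i = 0; i < n; ++i) if (xp[i] < 0) xp[i] = 0;
    break;
  case 1:
    for (R_xlen_t i = 0; i < n; ++i) {
      if (xp[i] < 0) xp[i] = 0;
      else if (xp[i] > 6) xp[i] = 6;
    }
    break;
  case 3:
    for (R_xlen_t i = 0; i < n; ++i) xp[i] = 1 / (1 + std::exp(-xp[i]));
    break;
  default: stop("activation kind not supported in place");
  }
  return x;
}

// In-place activation backward from the output only; mutates gy.
// [[Rcpp::export]]
NumericVector cpp_act_bwd_ip(NumericVector y, NumericVector gy, int kind) {
  R_xlen_t n = y.size();
  const double* yp = y.begin();
  double* gp = gy.begin();
  switch (kind) {
  case 0:
    for (R_xlen_t i = 0; i < n; ++i) if (yp[i] <= 0) gp[i] = 0;
    break;
  case 1:
    for (R_xlen_t i = 0; i < n; ++i)
      if (yp[i] <= 0 || yp[i] >= 6) gp[i] = 0;
    break;
  case 3:
    for (R_xlen_t i = 0; i < n; ++i) gp[i] *= yp[i] * (1 - yp[i]);
    break;
  default: stop("activation kind not supported in place");
  }
  return gy;
}

// Per-channel mean and biased variance over (H, W, N).
// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x, IntegerVector xd) {
  const int C = xd[0];
  const R_xlen_t m = x.size() / C;
  NumericVector mean(C), var(C);
  const double* xp = x.begin();
  for (R_xlen_t p = 0; p < m; ++p) {
    const double* xc = xp + (size_t)C * p;
    for (int c = 0; c < C; ++c) {
      mean[c] += xc[c];
      var[c] += xc[c] * xc[c];
    }
  }
  for (int c = 0; c < C; ++c) {
    mean[c] /= m;
    var[c] = var[c] / m - mean[c] * mean[c];
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector cpp_bn_apply(NumericVector x, IntegerVector xd,
                           NumericVector gamma, NumericVector beta,
                           NumericVector mean, NumericVector invstd,
                           NumericVector out = NumericVector(0)) {
  const int C = xd[0];
  const R_xlen_t m = x.size() / C;
  NumericVector y = ensure_out(out, x.size(), false);
  std::vector<double> a(C), b(C);
  for (int c = 0; c < C; ++c) {
    a[c] = gamma[c] * invstd[c];
    b[c] = beta[c] - a[c] * mean[c];
  }
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t p = 0; p < m; ++p) {
    const double* xc = xp + (size_t)C * p;
    double* yc = yp + (size_t)C * p;
    for (int c = 0; c < C; ++c) yc[c] = a[c] * xc[c] + b[c];
  }
  y.attr("dim") = xd;
  return y;
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, IntegerVector xd, NumericVector gamma,
                NumericVector mean, NumericVector invstd, NumericVector gy,
                bool training) {
  const int C = xd[0];
  const R_xlen_t m = x.size() / C;
  // gx is written into gy in place: every element is read before it is
  // overwritten, and the tape hands each gradient to exactly one consumer.
  NumericVector gx = gy, dgamma(C), dbeta(C);
  const double* xp = x.begin();
  const double* gp = gy.begin();
  double* o = gx.begin();
  // first pass: per-channel sums of gy and gy * xhat
  for (R_xlen_t p = 0; p < m; ++p) {
    const double* xc = xp + (size_t)C * p;
    const double* gc = gp + (size_t)C * p;
    for (int c = 0; c < C; ++c) {
      dbeta[c] += gc[c];
      dgamma[c] += gc[c] * (xc[c] - mean[c]) * invstd[c];
    }
  }
  if (training) {
    std::vector<double> mg(C), mgx(C);
    for (int c = 0; c < C; ++c) {
      mg[c] = dbeta[c] / m;
      mgx[c] = dgamma[c] / m;
    }
    for (R_xlen_t p = 0; p < m; ++p) {
      const double* xc = xp + (size_t)C * p;
      const double* gc = gp + (size_t)C * p;
      double* oc = o + (size_t)C * p;
      for (int c = 0; c < C; ++c) {
        double xhat = (xc[c] - mean[c]) * invstd[c];
        oc[c] = gamma[c] * invstd[c] * (gc[c] - mg[c] - xhat * mgx[c]);
      }
    }
  } else {
    for (R_xlen_t p = 0; p < m; ++p) {
      const double* gc = gp + (size_t)C * p;
      double* oc = o + (size_t)C * p;
      for (int c = 0; c < C; ++c) oc[c] = gamma[c] * invstd[c] * gc[c];
    }
  }
  gx.attr("dim") = xd;
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Depthwise convolution, one filter per channel. w: c(C, 1, kh, kw).
// [[Rcpp::export]]
NumericVector cpp_dwconv_fwd(NumericVector x, IntegerVector xd,
                             NumericVector w, int kh, int kw,
                             int stride, int pad, int dil,
                             NumericVector out = NumericVector(0)) {
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  const int OH = conv_out_dim(H, kh, stride, pad, dil);
  const int OW = conv_out_dim(W, kw, stride, pad, dil);
  if (OH < 1 || OW < 1) stop("dwconv: empty output for %dx%d input", H, W);
  NumericVector y = ensure_out(out, (R_xlen_t)C * OH * OW * N, true);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)C * H * W * n;
    double* yn = yp + (size_t)C * OH * OW * n;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        double* yc = yn + (size_t)C * (oh + (size_t)OH * ow);
        for (int j = 0; j < kw; ++j) {
          int iw = ow * stride - pad + j * dil;
          if (iw < 0 || iw >= W) continue;
          for (int i = 0; i < kh; ++i) {
            int ih = oh * stride - pad + i * dil;
            if (ih < 0 || ih >= H) continue;
            const double* xc = xn + (size_t)C * (ih + (size_t)H * iw);
            const double* wc = wp + (size_t)C * (i + kh * j);
            for (int c = 0; c < C; ++c) yc[c] += xc[c] * wc[c];
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, OH, OW, N);
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv_bwd(NumericVector x, IntegerVector xd,
                    NumericVector w, int kh, int kw,
                    NumericVector gy, int stride, int pad, int dil,
                    NumericVector gxout = NumericVector(0)) {
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  const int OH = conv_out_dim(H, kh, stride, pad, dil);
  const int OW = conv_out_dim(W, kw, stride, pad, dil);
  NumericVector gx = ensure_out(gxout, (R_xlen_t)C * H * W * N, true);
  NumericVector gw((R_xlen_t)C * kh * kw);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gp = gy.begin();
  double* gxp = gx.begin();
  double* gwp = gw.begin();
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)C * H * W * n;
    const double* gn = gp + (size_t)C * OH * OW * n;
    double* gxn = gxp + (size_t)C * H * W * n;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const double* gc = gn + (size_t)C * (oh + (size_t)OH * ow);
        for (int j = 0; j < kw; ++j) {
          int iw = ow * stride - pad + j * dil;
          if (iw < 0 || iw >= W) continue;
          for (int i = 0; i < kh; ++i) {
            int ih = oh * stride - pad + i * dil;
            if (ih < 0 || ih >= H) continue;
            const double* xc = xn + (size_t)C * (ih + (size_t)H * iw);
            double* gxc = gxn + (size_t)C * (ih + (size_t)H * iw);
            const double* wc = wp + (size_t)C * (i + kh * j);
            double* gwc = gwp + (size_t)C * (i + kh * j);
            for (int c = 0; c < C; ++c) {
              gxc[c] += gc[c] * wc[c];
              gwc[c] += gc[c] * xc[c];
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = xd;
  gw.attr("dim") = IntegerVector::create(C, 1, kh, kw);
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

static void bilinear_coeffs(int In, int On, bool align, std::vector<int>& i0,
                            std::vector<int>& i1, std::vector<double>& a) {
  i0.resize(On); i1.resize(On); a.resize(On);
  for (int o = 0; o < On; ++o) {
    double s;
    if (align) {
      s = (On == 1) ? 0.0 : (double)o * (In - 1) / (On - 1);
    } else {
      s = ((double)o + 0.5) * In / On - 0.5;
      if (s < 0) s = 0;
    }
    int f = (int)std::floor(s);
    if (f > In - 1) f = In - 1;
    int c = f + 1;
    if (c > In - 1) c = In - 1;
    i0[o] = f; i1[o] = c;
    a[o] = s - f;
    if (a[o] < 0) a[o] = 0;
    if (a[o] > 1) a[o] = 1;
  }
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_fwd(NumericVector x, IntegerVector xd,
                               int OH, int OW, bool align,
                               NumericVector out = NumericVector(0)) {
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  std::vector<int> h0, h1, w0, w1;
  std::vector<double> ah, aw;
  bilinear_coeffs(H, OH, align, h0, h1, ah);
  bilinear_coeffs(W, OW, align, w0, w1, aw);
  NumericVector y = ensure_out(out, (R_xlen_t)C * OH * OW * N, false);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)C * H * W * n;
    double* yn = yp + (size_t)C * OH * OW * n;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const double* p00 = xn + (size_t)C * (h0[oh] + (size_t)H * w0[ow]);
        const double* p10 = xn + (size_t)C * (h1[oh] + (size_t)H * w0[ow]);
        const double* p01 = xn + (size_t)C * (h0[oh] + (size_t)H * w1[ow]);
        const double* p11 = xn + (size_t)C * (h1[oh] + (size_t)H * w1[ow]);
        double c00 = (1 - ah[oh]) * (1 - aw[ow]), c10 = ah[oh] * (1 - aw[ow]);
        double c01 = (1 - ah[oh]) * aw[ow], c11 = ah[oh] * aw[ow];
        double* yc = yn + (size_t)C * (oh + (size_t)OH * ow);
        for (int c = 0; c < C; ++c)
          yc[c] = c00 * p00[c] + c10 * p10[c] + c01 * p01[c] + c11 * p11[c];
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, OH, OW, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_bwd(NumericVector gy, IntegerVector yd,
                               int H, int W, bool align,
                               NumericVector out = NumericVector(0)) {
  const int C = yd[0], OH = yd[1], OW = yd[2], N = yd[3];
  std::vector<int> h0, h1, w0, w1;
  std::vector<double> ah, aw;
  bilinear_coeffs(H, OH, align, h0, h1, ah);
  bilinear_coeffs(W, OW, align, w0, w1, aw);
  NumericVector gx = ensure_out(out, (R_xlen_t)C * H * W * N, true);
  const double* gp = gy.begin();
  double* gxp = gx.begin();
  for (int n = 0; n < N; ++n) {
    const double* gn = gp + (size_t)C * OH * OW * n;
    double* gxn = gxp + (size_t)C * H * W * n;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        double* p00 = gxn + (size_t)C * (h0[oh] + (size_t)H * w0[ow]);
        double* p10 = gxn + (size_t)C * (h1[oh] + (size_t)H * w0[ow]);
        double* p01 = gxn + (size_t)C * (h0[oh] + (size_t)H * w1[ow]);
        double* p11 = gxn + (size_t)C * (h1[oh] + (size_t)H * w1[ow]);
        double c00 = (1 - ah[oh]) * (1 - aw[ow]), c10 = ah[oh] * (1 - aw[ow]);
        double c01 = (1 - ah[oh]) * aw[ow], c11 = ah[oh] * aw[ow];
        const double* gc = gn + (size_t)C * (oh + (size_t)OH * ow);
        for (int c = 0; c < C; ++c) {
          p00[c] += c00 * gc[c];
          p10[c] += c10 * gc[c];
          p01[c] += c01 * gc[c];
          p11[c] += c11 * gc[c];
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(C, H, W, N);
  return gx;
}

// Adaptive average pooling with floor/ceil bin edges.
// [[Rcpp::export]]
NumericVector cpp_adapt_pool_fwd(NumericVector x, IntegerVector xd,
                                 int OH, int OW,
                                 NumericVector out = NumericVector(0)) {
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  NumericVector y = ensure_out(out, (R_xlen_t)C * OH * OW * N, true);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)C * H * W * n;
    double* yn = yp + (size_t)C * OH * OW * n;
    for (int ow = 0; ow < OW; ++ow) {
      int ws = (ow * W) / OW, we = ((ow + 1) * W + OW - 1) / OW;
      for (int oh = 0; oh < OH; ++oh) {
        int hs = (oh * H) / OH, he = ((oh + 1) * H + OH - 1) / OH;
        double inv = 1.0 / ((we - ws) * (he - hs));
        double* yc = yn + (size_t)C * (oh + (size_t)OH * ow);
        for (int iw = ws; iw < we; ++iw)
          for (int ih = hs; ih < he; ++ih) {
            const double* xc = xn + (size_t)C * (ih + (size_t)H * iw);
            for (int c = 0; c < C; ++c) yc[c] += xc[c];
          }
        for (int c = 0; c < C; ++c) yc[c] *= inv;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, OH, OW, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_adapt_pool_bwd(NumericVector gy, IntegerVector yd,
                                 int H, int W,
                                 NumericVector out = NumericVector(0)) {
  const int C = yd[0], OH = yd[1], OW = yd[2], N = yd[3];
  NumericVector gx = ensure_out(out, (R_xlen_t)C * H * W * N, true);
  const double* gp = gy.begin();
  double* gxp = gx.begin();
  for (int n = 0; n < N; ++n) {
    const double* gn = gp + (size_t)C * OH * OW * n;
    double* gxn = gxp + (size_t)C * H * W * n;
    for (int ow = 0; ow < OW; ++ow) {
      int ws = (ow * W) / OW, we = ((ow + 1) * W + OW - 1) / OW;
      for (int oh = 0; oh < OH; ++oh) {
        int hs = (oh * H) / OH, he = ((oh + 1) * H + OH - 1) / OH;
        double inv = 1.0 / ((we - ws) * (he - hs));
        const double* gc = gn + (size_t)C * (oh + (size_t)OH * ow);
        for (int iw = ws; iw < we; ++iw)
          for (int ih = hs; ih < he; ++ih) {
            double* gxc = gxn + (size_t)C * (ih + (size_t)H * iw);
            for (int c = 0; c < C; ++c) gxc[c] += gc[c] * inv;
          }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(C, H, W, N);
  return gx;
}

// Directional (strip) means: z^h over width, z^w over height.
// [[Rcpp::export]]
NumericVector cpp_mean_w(NumericVector x, IntegerVector xd) {
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  NumericVector z((R_xlen_t)C * H * N);
  const double* xp = x.begin();
  double* zp = z.begin();
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W; ++w) {
      const double* col = xp + (size_t)C * H * (w + (size_t)W * n);
      double* zn = zp + (size_t)C * H * n;
      for (R_xlen_t i = 0; i < (R_xlen_t)C * H; ++i) zn[i] += col[i];
    }
  for (R_xlen_t i = 0; i < z.size(); ++i) zp[i] /= W;
  z.attr("dim") = IntegerVector::create(C, H, 1, N);
  return z;
}

// [[Rcpp::export]]
NumericVector cpp_mean_h(NumericVector x, IntegerVector xd) {
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  NumericVector z((R_xlen_t)C * W * N);
  const double* xp = x.begin();
  double* zp = z.begin();
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W; ++w) {
      double* zc = zp + (size_t)C * (w + (size_t)W * n);
      for (int h = 0; h < H; ++h) {
        const double* xc = xp + (size_t)C * (h + (size_t)H * (w + (size_t)W * n));
        for (int c = 0; c < C; ++c) zc[c] += xc[c];
      }
    }
  for (R_xlen_t i = 0; i < z.size(); ++i) zp[i] /= H;
  z.attr("dim") = IntegerVector::create(C, W, 1, N);
  return z;
}

// y[c,h,w,n] = x[c,h,w,n] * gh[c,h,n] * gw[c,w,n]
// [[Rcpp::export]]
NumericVector cpp_scale_hw_fwd(NumericVector x, IntegerVector xd,
                               NumericVector gh, NumericVector gw,
                               NumericVector out = NumericVector(0)) {
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  NumericVector y = ensure_out(out, (R_xlen_t)C * H * W * N, false);
  const double* xp = x.begin();
  const double* hp = gh.begin();
  const double* wp = gw.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W; ++w) {
      const double* wc = wp + (size_t)C * (w + (size_t)W * n);
      for (int h = 0; h < H; ++h) {
        const double* hc = hp + (size_t)C * (h + (size_t)H * n);
        size_t off = (size_t)C * (h + (size_t)H * (w + (size_t)W * n));
        for (int c = 0; c < C; ++c) yp[off + c] = xp[off + c] * hc[c] * wc[c];
      }
    }
  y.attr("dim") = xd;
  return y;
}

// [[Rcpp::export]]
List cpp_scale_hw_bwd(NumericVector x, IntegerVector xd,
                      NumericVector gh, NumericVector gw, NumericVector gy,
                      NumericVector out = NumericVector(0)) {
  const int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  NumericVector gx = ensure_out(out, (R_xlen_t)C * H * W * N, false);
  NumericVector ggh((R_xlen_t)C * H * N);
  NumericVector ggw((R_xlen_t)C * W * N);
  const double* xp = x.begin();
  const double* hp = gh.begin();
  const double* wp = gw.begin();
  const double* gp = gy.begin();
  double* gxp = gx.begin();
  double* ghp = ggh.begin();
  double* gwp = ggw.begin();
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W; ++w) {
      const double* wc = wp + (size_t)C * (w + (size_t)W * n);
      double* gwc = gwp + (size_t)C * (w + (size_t)W * n);
      for (int h = 0; h < H; ++h) {
        const double* hc = hp + (size_t)C * (h + (size_t)H * n);
        double* ghc = ghp + (size_t)C * (h + (size_t)H * n);
        size_t off = (size_t)C * (h + (size_t)H * (w + (size_t)W * n));
        for (int c = 0; c < C; ++c) {
          double g = gp[off + c], xv = xp[off + c];
          gxp[off + c] = g * hc[c] * wc[c];
          ghc[c] += g * xv * wc[c];
          gwc[c] += g * xv * hc[c];
        }
      }
    }
  gx.attr("dim") = xd;
  ggh.attr("dim") = IntegerVector::create(C, H, 1, N);
  ggw.attr("dim") = IntegerVector::create(C, W, 1, N);
  return List::create(_["gx"] = gx, _["ggh"] = ggh, _["ggw"] = ggw);
}

// Paired rotation about the image centre, output size preserved:
// bilinear sampling with reflection padding for the image (c(C,H,W)),
// nearest-neighbour (ties-to-even, matching R's round()) for the mask.
static inline int reflect_idx(long k, int n) {
  // map a 0-based integer coordinate into [0, n) by mirroring
  long m = k % (2L * n);
  if (m < 0) m += 2L * n;
  return m < n ? (int)m : (int)(2L * n - 1 - m);
}

// [[Rcpp::export]]
List cpp_rotate_pair(NumericVector img, IntegerVector id,
                     IntegerVector mask, int S1, int S2, double angle) {
  const int C = id[0], H = id[1], W = id[2];
  const double th = angle * M_PI / 180.0;
  const double cth = std::cos(th), sth = std::sin(th);
  const double cy = (S1 + 1) / 2.0, cx = (S2 + 1) / 2.0;
  NumericVector out((R_xlen_t)C * H * W);
  IntegerVector mout((R_xlen_t)S1 * S2);
  const double* ip = img.begin();
  double* op = out.begin();
  for (int cc = 0; cc < S2; ++cc) {
    for (int rr = 0; rr < S1; ++rr) {
      double r = (rr + 1) - cy, c = (cc + 1) - cx;
      double sr = cth * r - sth * c + cy;   // inverse map, 1-based coords
      double sc = sth * r + cth * c + cx;
      // nearest neighbour for the mask
      int mr = reflect_idx((long)std::nearbyint(sr) - 1, S1);
      int mc = reflect_idx((long)std::nearbyint(sc) - 1, S2);
      mout[rr + (R_xlen_t)S1 * cc] = mask[mr + (R_xlen_t)S1 * mc];
      // bilinear with reflected corners for the image
      double r0 = std::floor(sr), c0 = std::floor(sc);
      double ar = sr - r0, ac = sc - c0;
      int i0 = reflect_idx((long)r0 - 1, S1), i1 = reflect_idx((long)r0, S1);
      int j0 = reflect_idx((long)c0 - 1, S2), j1 = reflect_idx((long)c0, S2);
      double w00 = (1 - ar) * (1 - ac), w10 = ar * (1 - ac);
      double w01 = (1 - ar) * ac, w11 = ar * ac;
      for (int ch = 0; ch < C; ++ch) {
        const double* pl = ip;
        // layout c(C,H,W): idx ch + C*(h + H*w)
        double v = w00 * pl[ch + (size_t)C * (i0 + (size_t)H * j0)] +
                   w10 * pl[ch + (size_t)C * (i1 + (size_t)H * j0)] +
                   w01 * pl[ch + (size_t)C * (i0 + (size_t)H * j1)] +
                   w11 * pl[ch + (size_t)C * (i1 + (size_t)H * j1)];
        op[ch + (size_t)C * (rr + (size_t)H * cc)] = v;
      }
    }
  }
  out.attr("dim") = id;
  mout.attr("dim") = IntegerVector::create(S1, S2);
  return List::create(_["image"] = out, _["mask"] = mout);
}
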