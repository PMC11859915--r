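// Compiled single-precision training executor.
//
// The R side compiles the network into a flat instruction program (one
// instruction per layer op, SSA-style tensor ids); this VM executes the
// forward pass, the mixed Dice+Focal loss and its gradient, the backward
// pass, and the SGD update in one call per training step. Activations,
// gradients and parameter mirrors are float (standard mixed-precision
// practice); parameters, optimizer state and batch-norm running statistics
// stay double on the R side. The R tape implementation of the same graph
// is the double-precision reference that the tests compare against.
//
// Tensor layout matches the rest of the package: c(C, H, W, N).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

enum OpCode {
  OP_CONV = 0, OP_DWCONV = 1, OP_BN = 2, OP_ACT = 3, OP_ADD = 4,
  OP_MEANW = 5, OP_MEANH = 6, OP_CONCAT2 = 7, OP_SLICE2 = 8,
  OP_SCALEHW = 9, OP_CONCATCH = 10, OP_ADAPTPOOL = 11, OP_BILINEAR = 12,
  OP_DROPOUT = 13
};

struct Instr {
  int op = 0, out = -1;
  std::vector<int> ins;
  int kh = 1, kw = 1, stride = 1, pad = 0, dil = 1, hasb = 0;
  int kind = 0, from = 0, len = 0, oh = 0, ow = 0, align = 1;
  double rate = 0;
  int pw = -1, pb = -1, bm = -1, bv = -1;
};

struct VM {
  std::vector<Instr> prog;
  std::vector<std::array<int, 4>> dims;
  std::vector<size_t> tlen;
  std::vector<std::vector<float>> val, grad;
  std::vector<std::vector<float>> pf, pg;
  std::vector<size_t> plen;
  std::vector<std::vector<float>> s_mean, s_invstd, s_mask;
  int logits = -1;
  bool bwd_ready = false;
  double bn_eps = 1e-5, bn_momentum = 0.1;
};

static void bilin_coeffs(int In, int On, bool align, std::vector<int>& i0,
                         std::vector<int>& i1, std::vector<double>& a) {
  i0.resize(On); i1.resize(On); a.resize(On);
  for (int o = 0; o < On; ++o) {
    double s;
    if (align) s = (On == 1) ? 0.0 : (double)o * (In - 1) / (On - 1);
    else {
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

static void im2col_ff(const float* x, int C, int H, int W, int kh, int kw,
                      int stride, int pad, int dil, int OH, int OW,
                      arma::fmat& M) {
  for (int ow = 0; ow < OW; ++ow)
    for (int oh = 0; oh < OH; ++oh) {
      int col = oh + OH * ow;
      float* colp = M.colptr(col);
      for (int j = 0; j < kw; ++j) {
        int iw = ow * stride - pad + j * dil;
        for (int i = 0; i < kh; ++i) {
          int ih = oh * stride - pad + i * dil;
          float* dst = colp + (size_t)C * (i + kh * j);
          if (ih < 0 || ih >= H || iw < 0 || iw >= W)
            std::memset(dst, 0, sizeof(float) * C);
          else
            std::memcpy(dst, x + (size_t)C * (ih + (size_t)H * iw),
                        sizeof(float) * C);
        }
      }
    }
}

static void col2im_add_ff(const arma::fmat& M, float* gx, int C, int H,
                          int W, int kh, int kw, int stride, int pad,
                          int dil, int OH, int OW) {
  for (int ow = 0; ow < OW; ++ow)
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
          float* dst = gx + (size_t)C * (ih + (size_t)H * iw);
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
}

// [[Rcpp::export]]
SEXP cpp_vm_new(List instrs, IntegerMatrix dims, IntegerVector plens,
                int logits_id) {
  VM* vm = new VM();
  int T = dims.nrow();
  vm->dims.resize(T);
  vm->tlen.resize(T);
  vm->val.resize(T);
  vm->grad.resize(T);
  for (int t = 0; t < T; ++t) {
    vm->dims[t] = {dims(t, 0), dims(t, 1), dims(t, 2), dims(t, 3)};
    vm->tlen[t] = (size_t)dims(t, 0) * dims(t, 1) * dims(t, 2) * dims(t, 3);
    vm->val[t].assign(vm->tlen[t], 0.0f);
  }
  int P = plens.size();
  vm->pf.resize(P);
  vm->pg.resize(P);
  vm->plen.resize(P);
  for (int p = 0; p < P; ++p) {
    vm->plen[p] = plens[p];
    vm->pf[p].assign(plens[p], 0.0f);
  }
  int n = instrs.size();
  vm->prog.resize(n);
  vm->s_mean.resize(n);
  vm->s_invstd.resize(n);
  vm->s_mask.resize(n);
  for (int i = 0; i < n; ++i) {
    List li = instrs[i];
    Instr& I = vm->prog[i];
    I.op = as<int>(li["op"]);
    I.out = as<int>(li["out"]);
    I.ins = as<std::vector<int>>(li["ins"]);
    IntegerVector g = li["g"];
    if (g.size() >= 6) {
      I.kh = g[0]; I.kw = g[1]; I.stride = g[2]; I.pad = g[3];
      I.dil = g[4]; I.hasb = g[5];
    }
    I.kind = as<int>(li["kind"]);
    I.from = as<int>(li["from"]);
    I.len = as<int>(li["len"]);
    I.oh = as<int>(li["oh"]);
    I.ow = as<int>(li["ow"]);
    I.align = as<int>(li["align"]);
    I.rate = as<double>(li["rate"]);
    I.pw = as<int>(li["pw"]);
    I.pb = as<int>(li["pb"]);
    I.bm = as<int>(li["bm"]);
    I.bv = as<int>(li["bv"]);
  }
  vm->logits = logits_id;
  XPtr<VM> ptr(vm, true);
  return ptr;
}

static void load_params(VM& vm, List params) {
  int P = vm.pf.size();
  for (int p = 0; p < P; ++p) {
    NumericVector v = params[p];
    float* f = vm.pf[p].data();
    const double* d = REAL(v);
    for (size_t i = 0; i < vm.plen[p]; ++i) f[i] = (float)d[i];
  }
}

static void vm_fwd(VM& vm, List buffers, bool training) {
  for (size_t ii = 0; ii < vm.prog.size(); ++ii) {
    Instr& I = vm.prog[ii];
    const auto& od = vm.dims[I.out];
    float* y = vm.val[I.out].data();
    switch (I.op) {
    case OP_CONV: {
      const auto& xd = vm.dims[I.ins[0]];
      const float* x = vm.val[I.ins[0]].data();
      int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
      int Cout = od[0], OH = od[1], OW = od[2];
      size_t K = (size_t)C * I.kh * I.kw;
      arma::fmat Wm(vm.pf[I.pw].data(), Cout, K, false);
      if (I.kh == 1 && I.kw == 1 && I.stride == 1 && I.pad == 0) {
        size_t P = (size_t)H * W * N;
        arma::fmat X(const_cast<float*>(x), C, P, false);
        arma::fmat Y(y, Cout, P, false);
        Y = Wm * X;
      } else {
        arma::fmat M(K, (size_t)OH * OW);
        for (int n = 0; n < N; ++n) {
          im2col_ff(x + (size_t)C * H * W * n, C, H, W, I.kh, I.kw,
                    I.stride, I.pad, I.dil, OH, OW, M);
          arma::fmat Y(y + (size_t)Cout * OH * OW * n, Cout,
                       (size_t)OH * OW, false);
          Y = Wm * M;
        }
      }
      if (I.hasb) {
        const float* b = vm.pf[I.pb].data();
        size_t P = vm.tlen[I.out] / Cout;
        for (size_t p = 0; p < P; ++p) {
          float* yc = y + (size_t)Cout * p;
          for (int c = 0; c < Cout; ++c) yc[c] += b[c];
        }
      }
      break;
    }
    case OP_DWCONV: {
      const auto& xd = vm.dims[I.ins[0]];
      const float* x = vm.val[I.ins[0]].data();
      const float* w = vm.pf[I.pw].data();
      int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
      int OH = od[1], OW = od[2];
      std::memset(y, 0, sizeof(float) * vm.tlen[I.out]);
      for (int n = 0; n < N; ++n) {
        const float* xn = x + (size_t)C * H * W * n;
        float* yn = y + (size_t)C * OH * OW * n;
        for (int ow = 0; ow < OW; ++ow)
          for (int oh = 0; oh < OH; ++oh) {
            float* yc = yn + (size_t)C * (oh + (size_t)OH * ow);
            for (int j = 0; j < I.kw; ++j) {
              int iw = ow * I.stride - I.pad + j * I.dil;
              if (iw < 0 || iw >= W) continue;
              for (int i = 0; i < I.kh; ++i) {
                int ih = oh * I.stride - I.pad + i * I.dil;
                if (ih < 0 || ih >= H) continue;
                const float* xc = xn + (size_t)C * (ih + (size_t)H * iw);
                const float* wc = w + (size_t)C * (i + I.kh * j);
                for (int c = 0; c < C; ++c) yc[c] += xc[c] * wc[c];
              }
            }
          }
      }
      break;
    }
    case OP_BN: {
      const auto& xd = vm.dims[I.ins[0]];
      const float* x = vm.val[I.ins[0]].data();
      int C = xd[0];
      size_t m = vm.tlen[I.ins[0]] / C;
      std::vector<float>& mean = vm.s_mean[ii];
      std::vector<float>& invstd = vm.s_invstd[ii];
      mean.assign(C, 0.0f);
      invstd.assign(C, 0.0f);
      NumericVector rm = buffers[I.bm], rv = buffers[I.bv];
      if (training) {
        std::vector<double> s1(C, 0.0), s2(C, 0.0);
        for (size_t p = 0; p < m; ++p) {
          const float* xc = x + (size_t)C * p;
          for (int c = 0; c < C; ++c) {
            s1[c] += xc[c];
            s2[c] += (double)xc[c] * xc[c];
          }
        }
        for (int c = 0; c < C; ++c) {
          double mu = s1[c] / m;
          double var = s2[c] / m - mu * mu;
          if (var < 0) var = 0;
          mean[c] = (float)mu;
          invstd[c] = (float)(1.0 / std::sqrt(var + vm.bn_eps));
          double unb = m > 1 ? var * (double)m / (m - 1) : var;
          REAL(rm)[c] = (1 - vm.bn_momentum) * REAL(rm)[c] +
                        vm.bn_momentum * mu;
          REAL(rv)[c] = (1 - vm.bn_momentum) * REAL(rv)[c] +
                        vm.bn_momentum * unb;
        }
      } else {
        for (int c = 0; c < C; ++c) {
          mean[c] = (float)REAL(rm)[c];
          invstd[c] = (float)(1.0 / std::sqrt(REAL(rv)[c] + vm.bn_eps));
        }
      }
      const float* gamma = vm.pf[I.pw].data();
      const float* beta = vm.pf[I.pb].data();
      std::vector<float> a(C), b(C);
      for (int c = 0; c < C; ++c) {
        a[c] = gamma[c] * invstd[c];
        b[c] = beta[c] - a[c] * mean[c];
      }
      for (size_t p = 0; p < m; ++p) {
        const float* xc = x + (size_t)C * p;
        float* yc = y + (size_t)C * p;
        for (int c = 0; c < C; ++c) yc[c] = a[c] * xc[c] + b[c];
      }
      break;
    }
    case OP_ACT: {
      const float* x = vm.val[I.ins[0]].data();
      size_t n = vm.tlen[I.out];
      switch (I.kind) {
      case 0: for (size_t i = 0; i < n; ++i) y[i] = x[i] > 0 ? x[i] : 0;
        break;
      case 1:
        for (size_t i = 0; i < n; ++i)
          y[i] = x[i] < 0 ? 0 : (x[i] > 6 ? 6 : x[i]);
        break;
      case 2:
        for (size_t i = 0; i < n; ++i) {
          float r = x[i] + 3;
          r = r < 0 ? 0 : (r > 6 ? 6 : r);
          y[i] = x[i] * r / 6;
        }
        break;
      case 3:
        for (size_t i = 0; i < n; ++i) y[i] = 1 / (1 + std::exp(-x[i]));
        break;
      }
      break;
    }
    case OP_ADD: {
      const float* a = vm.val[I.ins[0]].data();
      const float* b = vm.val[I.ins[1]].data();
      size_t n = vm.tlen[I.out];
      for (size_t i = 0; i < n; ++i) y[i] = a[i] + b[i];
      break;
    }
    case OP_MEANW: {
      const auto& xd = vm.dims[I.ins[0]];
      const float* x = vm.val[I.ins[0]].data();
      int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
      std::memset(y, 0, sizeof(float) * vm.tlen[I.out]);
      for (int n = 0; n < N; ++n)
        for (int w = 0; w < W; ++w) {
          const float* col = x + (size_t)C * H * (w + (size_t)W * n);
          float* zn = y + (size_t)C * H * n;
          for (size_t i = 0; i < (size_t)C * H; ++i) zn[i] += col[i];
        }
      for (size_t i = 0; i < vm.tlen[I.out]; ++i) y[i] /= W;
      break;
    }
    case OP_MEANH: {
      const auto& xd = vm.dims[I.ins[0]];
      const float* x = vm.val[I.ins[0]].data();
      int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
      std::memset(y, 0, sizeof(float) * vm.tlen[I.out]);
      for (int n = 0; n < N; ++n)
        for (int w = 0; w < W; ++w) {
          float* zc = y + (size_t)C * (w + (size_t)W * n);
          for (int h = 0; h < H; ++h) {
            const float* xc =
                x + (size_t)C * (h + (size_t)H * (w + (size_t)W * n));
            for (int c = 0; c < C; ++c) zc[c] += xc[c];
          }
        }
      for (size_t i = 0; i < vm.tlen[I.out]; ++i) y[i] /= H;
      break;
    }
    case OP_CONCAT2: {
      // strips c(C, L, 1, N) along dim 2
      const auto& ad = vm.dims[I.ins[0]];
      const auto& bd = vm.dims[I.ins[1]];
      const float* a = vm.val[I.ins[0]].data();
      const float* b = vm.val[I.ins[1]].data();
      int C = ad[0], La = ad[1], Lb = bd[1], N = ad[3];
      for (int n = 0; n < N; ++n) {
        std::memcpy(y + (size_t)C * (La + Lb) * n, a + (size_t)C * La * n,
                    sizeof(float) * C * La);
        std::memcpy(y + (size_t)C * (La + Lb) * n + (size_t)C * La,
                    b + (size_t)C * Lb * n, sizeof(float) * C * Lb);
      }
      break;
    }
    case OP_SLICE2: {
      const auto& xd = vm.dims[I.ins[0]];
      const float* x = vm.val[I.ins[0]].data();
      int C = xd[0], L = xd[1], N = xd[3];
      for (int n = 0; n < N; ++n)
        std::memcpy(y + (size_t)C * I.len * n,
                    x + (size_t)C * L * n + (size_t)C * I.from,
                    sizeof(float) * C * I.len);
      break;
    }
    case OP_SCALEHW: {
      const auto& xd = vm.dims[I.ins[0]];
      const float* x = vm.val[I.ins[0]].data();
      const float* gh = vm.val[I.ins[1]].data();
      const float* gw = vm.val[I.ins[2]].data();
      int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
      for (int n = 0; n < N; ++n)
        for (int w = 0; w < W; ++w) {
          const float* wc = gw + (size_t)C * (w + (size_t)W * n);
          for (int h = 0; h < H; ++h) {
            const float* hc = gh + (size_t)C * (h + (size_t)H * n);
            size_t off = (size_t)C * (h + (size_t)H * (w + (size_t)W * n));
            for (int c = 0; c < C; ++c)
              y[off + c] = x[off + c] * hc[c] * wc[c];
          }
        }
      break;
    }
    case OP_CONCATCH: {
      int Csum = od[0];
      size_t P = vm.tlen[I.out] / Csum;
      int at = 0;
      for (size_t k = 0; k < I.ins.size(); ++k) {
        const float* x = vm.val[I.ins[k]].data();
        int C = vm.dims[I.ins[k]][0];
        for (size_t p = 0; p < P; ++p)
          std::memcpy(y + (size_t)Csum * p + at, x + (size_t)C * p,
                      sizeof(float) * C);
        at += C;
      }
      break;
    }
    case OP_ADAPTPOOL: {
      const auto& xd = vm.dims[I.ins[0]];
      const float* x = vm.val[I.ins[0]].data();
      int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
      int OH = I.oh, OW = I.ow;
      std::memset(y, 0, sizeof(float) * vm.tlen[I.out]);
      for (int n = 0; n < N; ++n) {
        const float* xn = x + (size_t)C * H * W * n;
        float* yn = y + (size_t)C * OH * OW * n;
        for (int ow = 0; ow < OW; ++ow) {
          int ws = (ow * W) / OW, we = ((ow + 1) * W + OW - 1) / OW;
          for (int oh = 0; oh < OH; ++oh) {
            int hs = (oh * H) / OH, he = ((oh + 1) * H + OH - 1) / OH;
            float inv = 1.0f / ((we - ws) * (he - hs));
            float* yc = yn + (size_t)C * (oh + (size_t)OH * ow);
            for (int iw = ws; iw < we; ++iw)
              for (int ih = hs; ih < he; ++ih) {
                const float* xc = xn + (size_t)C * (ih + (size_t)H * iw);
                for (int c = 0; c < C; ++c) yc[c] += xc[c];
              }
            for (int c = 0; c < C; ++c) yc[c] *= inv;
          }
        }
      }
      break;
    }
    case OP_BILINEAR: {
      const auto& xd = vm.dims[I.ins[0]];
      const float* x = vm.val[I.ins[0]].data();
      int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
      int OH = I.oh, OW = I.ow;
      std::vector<int> h0, h1, w0, w1;
      std::vector<double> ah, aw;
      bilin_coeffs(H, OH, I.align, h0, h1, ah);
      bilin_coeffs(W, OW, I.align, w0, w1, aw);
      for (int n = 0; n < N; ++n) {
        const float* xn = x + (size_t)C * H * W * n;
        float* yn = y + (size_t)C * OH * OW * n;
        for (int ow = 0; ow < OW; ++ow)
          for (int oh = 0; oh < OH; ++oh) {
            const float* p00 = xn + (size_t)C * (h0[oh] + (size_t)H * w0[ow]);
            const float* p10 = xn + (size_t)C * (h1[oh] + (size_t)H * w0[ow]);
            const float* p01 = xn + (size_t)C * (h0[oh] + (size_t)H * w1[ow]);
            const float* p11 = xn + (size_t)C * (h1[oh] + (size_t)H * w1[ow]);
            float c00 = (1 - ah[oh]) * (1 - aw[ow]);
            float c10 = ah[oh] * (1 - aw[ow]);
            float c01 = (1 - ah[oh]) * aw[ow];
            float c11 = ah[oh] * aw[ow];
            float* yc = yn + (size_t)C * (oh + (size_t)OH * ow);
            for (int c = 0; c < C; ++c)
              yc[c] = c00 * p00[c] + c10 * p10[c] + c01 * p01[c] +
                      c11 * p11[c];
          }
      }
      break;
    }
    case OP_DROPOUT: {
      const float* x = vm.val[I.ins[0]].data();
      size_t n = vm.tlen[I.out];
      if (training && I.rate > 0) {
        std::vector<float>& mask = vm.s_mask[ii];
        mask.resize(n);
        float scale = 1.0f / (1.0f - (float)I.rate);
        for (size_t i = 0; i < n; ++i) {
          mask[i] = unif_rand() >= I.rate ? scale : 0.0f;
          y[i] = x[i] * mask[i];
        }
      } else {
        std::memcpy(y, x, sizeof(float) * n);
      }
      break;
    }
    default: stop("vm: unknown op %d", I.op);
    }
  }
}

static void vm_bwd(VM& vm, bool training) {
  for (size_t t = 0; t < vm.grad.size(); ++t) {
    if (vm.grad[t].size() != vm.tlen[t]) vm.grad[t].assign(vm.tlen[t], 0.0f);
    else if ((int)t != vm.logits)
      std::memset(vm.grad[t].data(), 0, sizeof(float) * vm.tlen[t]);
  }
  for (size_t p = 0; p < vm.pg.size(); ++p) {
    if (vm.pg[p].size() != vm.plen[p]) vm.pg[p].assign(vm.plen[p], 0.0f);
    else std::memset(vm.pg[p].data(), 0, sizeof(float) * vm.plen[p]);
  }
  for (int ii = (int)vm.prog.size() - 1; ii >= 0; --ii) {
    Instr& I = vm.prog[ii];
    const float* gy = vm.grad[I.out].data();
    const auto& od = vm.dims[I.out];
    switch (I.op) {
    case OP_CONV: {
      const auto& xd = vm.dims[I.ins[0]];
      const float* x = vm.val[I.ins[0]].data();
      float* gx = vm.grad[I.ins[0]].data();
      int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
      int Cout = od[0], OH = od[1], OW = od[2];
      size_t K = (size_t)C * I.kh * I.kw;
      arma::fmat Wm(vm.pf[I.pw].data(), Cout, K, false);
      arma::fmat GW(vm.pg[I.pw].data(), Cout, K, false);
      if (I.kh == 1 && I.kw == 1 && I.stride == 1 && I.pad == 0) {
        size_t P = (size_t)H * W * N;
        arma::fmat X(const_cast<float*>(x), C, P, false);
        arma::fmat GY(const_cast<float*>(gy), Cout, P, false);
        arma::fmat GX(gx, C, P, false);
        GW += GY * X.t();
        GX += Wm.t() * GY;
      } else {
        arma::fmat M(K, (size_t)OH * OW);
        for (int n = 0; n < N; ++n) {
          im2col_ff(x + (size_t)C * H * W * n, C, H, W, I.kh, I.kw,
                    I.stride, I.pad, I.dil, OH, OW, M);
          arma::fmat GY(const_cast<float*>(gy) + (size_t)Cout * OH * OW * n,
                        Cout, (size_t)OH * OW, false);
          GW += GY * M.t();
          arma::fmat Gcol = Wm.t() * GY;
          col2im_add_ff(Gcol, gx + (size_t)C * H * W * n, C, H, W, I.kh,
                        I.kw, I.stride, I.pad, I.dil, OH, OW);
        }
      }
      if (I.hasb) {
        float* gb = vm.pg[I.pb].data();
        size_t P = vm.tlen[I.out] / Cout;
        for (size_t p = 0; p < P; ++p) {
          const float* gc = gy + (size_t)Cout * p;
          for (int c = 0; c < Cout; ++c) gb[c] += gc[c];
        }
      }
      break;
    }
    case OP_DWCONV: {
      const auto& xd = vm.dims[I.ins[0]];
      const float* x = vm.val[I.ins[0]].data();
      float* gx = vm.grad[I.ins[0]].data();
      const float* w = vm.pf[I.pw].data();
      float* gw = vm.pg[I.pw].data();
      int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
      int OH = od[1], OW = od[2];
      for (int n = 0; n < N; ++n) {
        const float* xn = x + (size_t)C * H * W * n;
        const float* gn = gy + (size_t)C * OH * OW * n;
        float* gxn = gx + (size_t)C * H * W * n;
        for (int ow = 0; ow < OW; ++ow)
          for (int oh = 0; oh < OH; ++oh) {
            const float* gc = gn + (size_t)C * (oh + (size_t)OH * ow);
            for (int j = 0; j < I.kw; ++j) {
              int iw = ow * I.stride - I.pad + j * I.dil;
              if (iw < 0 || iw >= W) continue;
              for (int i = 0; i < I.kh; ++i) {
                int ih = oh * I.stride - I.pad + i * I.dil;
                if (ih < 0 || ih >= H) continue;
                const float* xc = xn + (size_t)C * (ih + (size_t)H * iw);
                float* gxc = gxn + (size_t)C * (ih + (size_t)H * iw);
                const float* wc = w + (size_t)C * (i + I.kh * j);
                float* gwc = gw + (size_t)C * (i + I.kh * j);
                for (int c = 0; c < C; ++c) {
                  gxc[c] += gc[c] * wc[c];
                  gwc[c] += gc[c] * xc[c];
                }
              }
            }
          }
      }
      break;
    }
    case OP_BN: {
      const auto& xd = vm.dims[I.ins[0]];
      const float* x = vm.val[I.ins[0]].data();
      float* gx = vm.grad[I.ins[0]].data();
      int C = xd[0];
      size_t m = vm.tlen[I.ins[0]] / C;
      const float* gamma = vm.pf[I.pw].data();
      float* dgamma = vm.pg[I.pw].data();
      float* dbeta = vm.pg[I.pb].data();
      const std::vector<float>& mean = vm.s_mean[ii];
      const std::vector<float>& invstd = vm.s_invstd[ii];
      std::vector<double> sg(C, 0.0), sgx(C, 0.0);
      for (size_t p = 0; p < m; ++p) {
        const float* xc = x + (size_t)C * p;
        const float* gc = gy + (size_t)C * p;
        for (int c = 0; c < C; ++c) {
          sg[c] += gc[c];
          sgx[c] += (double)gc[c] * (xc[c] - mean[c]) * invstd[c];
        }
      }
      for (int c = 0; c < C; ++c) {
        dbeta[c] += (float)sg[c];
        dgamma[c] += (float)sgx[c];
      }
      if (training) {
        std::vector<float> mg(C), mgx(C);
        for (int c = 0; c < C; ++c) {
          mg[c] = (float)(sg[c] / m);
          mgx[c] = (float)(sgx[c] / m);
        }
        for (size_t p = 0; p < m; ++p) {
          const float* xc = x + (size_t)C * p;
          const float* gc = gy + (size_t)C * p;
          float* oc = gx + (size_t)C * p;
          for (int c = 0; c < C; ++c) {
            float xhat = (xc[c] - mean[c]) * invstd[c];
            oc[c] += gamma[c] * invstd[c] * (gc[c] - mg[c] - xhat * mgx[c]);
          }
        }
      } else {
        for (size_t p = 0; p < m; ++p) {
          const float* gc = gy + (size_t)C * p;
          float* oc = gx + (size_t)C * p;
          for (int c = 0; c < C; ++c) oc[c] += gamma[c] * invstd[c] * gc[c];
        }
      }
      break;
    }
    case OP_ACT: {
      const float* x = vm.val[I.ins[0]].data();
      const float* yv = vm.val[I.out].data();
      float* gx = vm.grad[I.ins[0]].data();
      size_t n = vm.tlen[I.out];
      switch (I.kind) {
      case 0:
        for (size_t i = 0; i < n; ++i) if (x[i] > 0) gx[i] += gy[i];
        break;
      case 1:
        for (size_t i = 0; i < n; ++i)
          if (x[i] > 0 && x[i] < 6) gx[i] += gy[i];
        break;
      case 2:
        for (size_t i = 0; i < n; ++i) {
          if (x[i] <= -3) continue;
          gx[i] += x[i] >= 3 ? gy[i] : gy[i] * (2 * x[i] + 3) / 6;
        }
        break;
      case 3:
        for (size_t i = 0; i < n; ++i) gx[i] += gy[i] * yv[i] * (1 - yv[i]);
        break;
      }
      break;
    }
    case OP_ADD: {
      float* ga = vm.grad[I.ins[0]].data();
      float* gb = vm.grad[I.ins[1]].data();
      size_t n = vm.tlen[I.out];
      for (size_t i = 0; i < n; ++i) {
        ga[i] += gy[i];
        gb[i] += gy[i];
      }
      break;
    }
    case OP_MEANW: {
      const auto& xd = vm.dims[I.ins[0]];
      float* gx = vm.grad[I.ins[0]].data();
      int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
      for (int n = 0; n < N; ++n)
        for (int w = 0; w < W; ++w) {
          float* col = gx + (size_t)C * H * (w + (size_t)W * n);
          const float* zn = gy + (size_t)C * H * n;
          for (size_t i = 0; i < (size_t)C * H; ++i) col[i] += zn[i] / W;
        }
      break;
    }
    case OP_MEANH: {
      const auto& xd = vm.dims[I.ins[0]];
      float* gx = vm.grad[I.ins[0]].data();
      int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
      for (int n = 0; n < N; ++n)
        for (int w = 0; w < W; ++w) {
          const float* zc = gy + (size_t)C * (w + (size_t)W * n);
          for (int h = 0; h < H; ++h) {
            float* xc =
                gx + (size_t)C * (h + (size_t)H * (w + (size_t)W * n));
            for (int c = 0; c < C; ++c) xc[c] += zc[c] / H;
          }
        }
      break;
    }
    case OP_CONCAT2: {
      const auto& ad = vm.dims[I.ins[0]];
      const auto& bd = vm.dims[I.ins[1]];
      float* ga = vm.grad[I.ins[0]].data();
      float* gb = vm.grad[I.ins[1]].data();
      int C = ad[0], La = ad[1], Lb = bd[1], N = ad[3];
      for (int n = 0; n < N; ++n) {
        const float* gn = gy + (size_t)C * (La + Lb) * n;
        float* gan = ga + (size_t)C * La * n;
        float* gbn = gb + (size_t)C * Lb * n;
        for (size_t i = 0; i < (size_t)C * La; ++i) gan[i] += gn[i];
        for (size_t i = 0; i < (size_t)C * Lb; ++i)
          gbn[i] += gn[(size_t)C * La + i];
      }
      break;
    }
    case OP_SLICE2: {
      const auto& xd = vm.dims[I.ins[0]];
      float* gx = vm.grad[I.ins[0]].data();
      int C = xd[0], L = xd[1], N = xd[3];
      for (int n = 0; n < N; ++n) {
        const float* gn = gy + (size_t)C * I.len * n;
        float* gxn = gx + (size_t)C * L * n + (size_t)C * I.from;
        for (size_t i = 0; i < (size_t)C * I.len; ++i) gxn[i] += gn[i];
      }
      break;
    }
    case OP_SCALEHW: {
      const auto& xd = vm.dims[I.ins[0]];
      const float* x = vm.val[I.ins[0]].data();
      const float* gh = vm.val[I.ins[1]].data();
      const float* gw = vm.val[I.ins[2]].data();
      float* gx = vm.grad[I.ins[0]].data();
      float* ggh = vm.grad[I.ins[1]].data();
      float* ggw = vm.grad[I.ins[2]].data();
      int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
      for (int n = 0; n < N; ++n)
        for (int w = 0; w < W; ++w) {
          const float* wc = gw + (size_t)C * (w + (size_t)W * n);
          float* gwc = ggw + (size_t)C * (w + (size_t)W * n);
          for (int h = 0; h < H; ++h) {
            const float* hc = gh + (size_t)C * (h + (size_t)H * n);
            float* ghc = ggh + (size_t)C * (h + (size_t)H * n);
            size_t off = (size_t)C * (h + (size_t)H * (w + (size_t)W * n));
            for (int c = 0; c < C; ++c) {
              float g = gy[off + c], xv = x[off + c];
              gx[off + c] += g * hc[c] * wc[c];
              ghc[c] += g * xv * wc[c];
              gwc[c] += g * xv * hc[c];
            }
          }
        }
      break;
    }
    case OP_CONCATCH: {
      int Csum = od[0];
      size_t P = vm.tlen[I.out] / Csum;
      int at = 0;
      for (size_t k = 0; k < I.ins.size(); ++k) {
        float* gx = vm.grad[I.ins[k]].data();
        int C = vm.dims[I.ins[k]][0];
        for (size_t p = 0; p < P; ++p) {
          const float* gc = gy + (size_t)Csum * p + at;
          float* gxc = gx + (size_t)C * p;
          for (int c = 0; c < C; ++c) gxc[c] += gc[c];
        }
        at += C;
      }
      break;
    }
    case OP_ADAPTPOOL: {
      const auto& xd = vm.dims[I.ins[0]];
      float* gx = vm.grad[I.ins[0]].data();
      int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
      int OH = I.oh, OW = I.ow;
      for (int n = 0; n < N; ++n) {
        const float* gn = gy + (size_t)C * OH * OW * n;
        float* gxn = gx + (size_t)C * H * W * n;
        for (int ow = 0; ow < OW; ++ow) {
          int ws = (ow * W) / OW, we = ((ow + 1) * W + OW - 1) / OW;
          for (int oh = 0; oh < OH; ++oh) {
            int hs = (oh * H) / OH, he = ((oh + 1) * H + OH - 1) / OH;
            float inv = 1.0f / ((we - ws) * (he - hs));
            const float* gc = gn + (size_t)C * (oh + (size_t)OH * ow);
            for (int iw = ws; iw < we; ++iw)
              for (int ih = hs; ih < he; ++ih) {
                float* gxc = gxn + (size_t)C * (ih + (size_t)H * iw);
                for (int c = 0; c < C; ++c) gxc[c] += gc[c] * inv;
              }
          }
        }
      }
      break;
    }
    case OP_BILINEAR: {
      const auto& xd = vm.dims[I.ins[0]];
      float* gx = vm.grad[I.ins[0]].data();
      int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
      int OH = I.oh, OW = I.ow;
      std::vector<int> h0, h1, w0, w1;
      std::vector<double> ah, aw;
      bilin_coeffs(H, OH, I.align, h0, h1, ah);
      bilin_coeffs(W, OW, I.align, w0, w1, aw);
      for (int n = 0; n < N; ++n) {
        const float* gn = gy + (size_t)C * OH * OW * n;
        float* gxn = gx + (size_t)C * H * W * n;
        for (int ow = 0; ow < OW; ++ow)
          for (int oh = 0; oh < OH; ++oh) {
            float* p00 = gxn + (size_t)C * (h0[oh] + (size_t)H * w0[ow]);
            float* p10 = gxn + (size_t)C * (h1[oh] + (size_t)H * w0[ow]);
            float* p01 = gxn + (size_t)C * (h0[oh] + (size_t)H * w1[ow]);
            float* p11 = gxn + (size_t)C * (h1[oh] + (size_t)H * w1[ow]);
            float c00 = (1 - ah[oh]) * (1 - aw[ow]);
            float c10 = ah[oh] * (1 - aw[ow]);
            float c01 = (1 - ah[oh]) * aw[ow];
            float c11 = ah[oh] * aw[ow];
            const float* gc = gn + (size_t)C * (oh + (size_t)OH * ow);
            for (int c = 0; c < C; ++c) {
              p00[c] += c00 * gc[c];
              p10[c] += c10 * gc[c];
              p01[c] += c01 * gc[c];
              p11[c] += c11 * gc[c];
            }
          }
      }
      break;
    }
    case OP_DROPOUT: {
      float* gx = vm.grad[I.ins[0]].data();
      size_t n = vm.tlen[I.out];
      if (training && I.rate > 0) {
        const std::vector<float>& mask = vm.s_mask[ii];
        for (size_t i = 0; i < n; ++i) gx[i] += gy[i] * mask[i];
      } else {
        for (size_t i = 0; i < n; ++i) gx[i] += gy[i];
      }
      break;
    }
    }
  }
}

// Mixed Dice+Focal loss and its gradient with respect to the logits.
// Matches the double-precision R implementation (batch or per-image Dice;
// focal on the clamped true-class probability). Writes the gradient into
// the logits grad buffer and returns (loss, dice, focal).
static List vm_loss_grad(VM& vm, IntegerVector gt, double lambda,
                         double alpha, double gamma, double eps,
                         bool dice_image) {
  const auto& ld = vm.dims[vm.logits];
  int K = ld[0], N = ld[3];
  size_t n = vm.tlen[vm.logits] / K;
  const float* z = vm.val[vm.logits].data();
  if ((size_t)gt.size() != n) stop("vm: mask size mismatch");
  std::vector<float> P((size_t)K * n);
  std::vector<double> sgp(N, 0.0), sg(N, 0.0), sp(N, 0.0);
  size_t per_img = n / N;
  for (size_t p = 0; p < n; ++p) {
    const float* zc = z + (size_t)K * p;
    float* pc = P.data() + (size_t)K * p;
    float mx = zc[0];
    for (int k = 1; k < K; ++k) mx = std::max(mx, zc[k]);
    double s = 0;
    for (int k = 0; k < K; ++k) {
      pc[k] = std::exp((double)zc[k] - mx);
      s += pc[k];
    }
    for (int k = 0; k < K; ++k) pc[k] /= s;
    int b = dice_image ? (int)(p / per_img) : 0;
    int g = gt[p];
    if (g < 0 || g >= K) stop("vm: mask label outside 0..K-1");
    if (g == 1) {
      sg[b] += 1;
      sgp[b] += pc[1];
    }
    sp[b] += pc[1];
  }
  int nb = dice_image ? N : 1;
  double dice = 0;
  std::vector<double> num(nb), den(nb);
  for (int b = 0; b < nb; ++b) {
    num[b] = 2 * sgp[b] + eps;
    den[b] = sg[b] + sp[b] + eps;
    dice += (1 - num[b] / den[b]) / nb;
  }
  double focal = 0;
  if (vm.grad[vm.logits].size() != vm.tlen[vm.logits])
    vm.grad[vm.logits].assign(vm.tlen[vm.logits], 0.0f);
  float* gz = vm.grad[vm.logits].data();
  const double lo = 1e-7, hi = 1 - 1e-7;
  for (size_t p = 0; p < n; ++p) {
    const float* pc = P.data() + (size_t)K * p;
    float* gc = gz + (size_t)K * p;
    int g = gt[p];
    int b = dice_image ? (int)(p / per_img) : 0;
    double ptr = pc[g];
    double pt = std::min(std::max(ptr, lo), hi);
    focal += -alpha * std::pow(1 - pt, gamma) * std::log(pt);
    // dL/dP assembled sparsely: dice touches channel 1, focal channel g
    double d1 = (g == 1)
        ? -lambda * (2 * den[b] - num[b]) / (den[b] * den[b]) / nb
        : -lambda * (-num[b]) / (den[b] * den[b]) / nb;
    double dfo = 0;
    if (ptr > lo && ptr < hi) {
      double t1 = gamma == 0 ? 0
          : gamma * std::pow(1 - pt, gamma - 1) * std::log(pt);
      dfo = (1 - lambda) * alpha * (t1 - std::pow(1 - pt, gamma) / pt) / n;
    }
    // softmax backward: gz_k = P_k * (dLdP_k - sum_j P_j dLdP_j)
    double sdot = pc[1] * d1 + pc[g] * dfo;
    for (int k = 0; k < K; ++k) {
      double dk = (k == 1 ? d1 : 0.0) + (k == g ? dfo : 0.0);
      gc[k] = (float)(pc[k] * (dk - sdot));
    }
  }
  focal /= n;
  return List::create(_["loss"] = lambda * dice + (1 - lambda) * focal,
                      _["dice"] = dice, _["focal"] = focal);
}

// [[Rcpp::export]]
List cpp_vm_train_step(SEXP vmp, List params, List buffers, List vel,
                       NumericVector x, IntegerVector gt,
                       double lambda, double alpha, double gamma, double eps,
                       bool dice_image, double lr, double momentum,
                       double wd, LogicalVector wd_mask) {
  XPtr<VM> vm(vmp);
  load_params(*vm, params);
  // input tensor id 0
  if ((size_t)x.size() != vm->tlen[0]) stop("vm: input size mismatch");
  {
    float* v0 = vm->val[0].data();
    const double* xp = REAL(x);
    for (size_t i = 0; i < vm->tlen[0]; ++i) v0[i] = (float)xp[i];
  }
  vm_fwd(*vm, buffers, true);
  List loss = vm_loss_grad(*vm, gt, lambda, alpha, gamma, eps, dice_image);
  vm_bwd(*vm, true);
  // SGD with momentum; weight decay only where wd_mask is TRUE
  int P = params.size();
  for (int p = 0; p < P; ++p) {
    NumericVector pp = params[p], vv = vel[p];
    const float* g = vm->pg[p].data();
    double* pd = REAL(pp);
    double* vd = REAL(vv);
    bool use_wd = wd > 0 && wd_mask[p];
    for (size_t i = 0; i < vm->plen[p]; ++i) {
      double gi = (double)g[i] + (use_wd ? wd * pd[i] : 0.0);
      vd[i] = momentum * vd[i] + gi;
      pd[i] -= lr * vd[i];
    }
  }
  return loss;
}

// [[Rcpp::export]]
NumericVector cpp_vm_forward(SEXP vmp, List params, List buffers,
                             NumericVector x, bool training) {
  XPtr<VM> vm(vmp);
  load_params(*vm, params);
  if ((size_t)x.size() != vm->tlen[0]) stop("vm: input size mismatch");
  float* v0 = vm->val[0].data();
  const double* xp = REAL(x);
  for (size_t i = 0; i < vm->tlen[0]; ++i) v0[i] = (float)xp[i];
  vm_fwd(*vm, buffers, training);
  const auto& ld = vm->dims[vm->logits];
  NumericVector out(vm->tlen[vm->logits]);
  const float* z = vm->val[vm->logits].data();
  double* o = REAL(out);
  for (size_t i = 0; i < vm->tlen[vm->logits]; ++i) o[i] = z[i];
  out.attr("dim") = IntegerVector::create(ld[0], ld[1], ld[2], ld[3]);
  return out;
}
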