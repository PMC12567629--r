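// Compiled WideResNet engine (1-D and 2-D), single precision.
//
// Pre-activation residual topology: stem conv -> 3 groups of (depth-4)/6
// blocks at widths 16k/32k/64k (stride 2 entering groups 2 and 3, size-1
// projection shortcut where the shape changes) -> BN+ReLU -> global average
// pooling -> affine classifier. Convolutions are bias-free, normalization
// layers affine, the classifier carries a bias. 1-D networks use kernel 3
// wherever the 2-D network uses 3x3 (a 1-D conv is handled as a Kx1 kernel
// over an S1 x 1 spatial grid, so both share one code path).
//
// Convolutions run as tiled im2col + sgemm: the patch matrix is gathered
// one column tile at a time into a reused scratch buffer sized to stay in
// cache, so the full patch matrix is never materialized. BatchNorm keeps
// only per-channel statistics between forward and backward and recomputes
// normalized values from the cached layer input.
//
// All trainable scalars live in one flat float vector so that flattening,
// loading and linear interpolation of weight vectors are trivial on the R
// side. BatchNorm running statistics live in a second (non-trainable) flat
// vector. Everything is deterministic on a single thread.

#include <RcppArmadillo.h>
#include <cstring>
#include <malloc.h>
#include <limits>

using arma::fmat;
using arma::fvec;

namespace {

constexpr float BN_EPS = 1e-5f;
constexpr float BN_MOMENTUM = 0.1f;

enum Mode { MODE_EVAL = 0, MODE_TRAIN = 1, MODE_ACCUM = 2 };

struct ConvP {
  int Cin = 0, Cout = 0, KH = 1, KW = 1, SH = 1, SW = 1, PH = 0, PW = 0;
  int woff = 0;
  int nw() const { return Cout * Cin * KH * KW; }
  int krows() const { return Cin * KH * KW; }
};

struct BNP {
  int C = 0;
  int poff = 0;  // gamma at poff, beta at poff + C
  int roff = 0;  // running mean at roff, running var at roff + C
};

struct BlockP {
  BNP bn1;
  ConvP c1;
  BNP bn2;
  ConvP c2;
  bool proj = false;
  ConvP cs;
};

struct LayoutEntry {
  std::string type;
  int offset, size, fan_in, fan_out;
};

struct BNCache {
  fvec m, istd;
};

struct BlkCache {
  fmat x;      // block input (= bn1 source)
  BNCache b1;
  fmat o;      // relu(bn1(x)), consumed by conv1 and the projection
  fmat a1;     // conv1(o) (= bn2 source)
  BNCache b2;
  fmat h;      // relu(bn2(a1)), consumed by conv2
  int S1i = 0, S2i = 0, S1o = 0, S2o = 0;
};

inline bool is_identity_gather(const ConvP& cp) {
  return cp.KH == 1 && cp.KW == 1 && cp.SH == 1 && cp.SW == 1 && cp.PH == 0 &&
         cp.PW == 0;
}

// Patch-matrix column "groups": group q = o2 + O2*n covers the O1
// consecutive output columns of one (sample, o2) stripe, so tile
// boundaries never split the inner o1 runs.

// Gather groups [q0, q1) of the im2col matrix of X (C x S1*S2*N, column
// index s1 + S1*(s2 + S2*n)) into M (krows x (q1-q0)*O1). One write pass:
// in-range taps copied, padding taps zeroed.
void im2col_groups(const fmat& X, int C, int S1, int S2, int N,
                   const ConvP& cp, int O1, int O2, int q0, int q1,
                   fmat& M) {
  const size_t R = M.n_rows;
  (void)N;
  for (int q = q0; q < q1; ++q) {
    const int n = q / O2, o2 = q % O2;
    const size_t colbase = (size_t)(q - q0) * O1;
    const int s2 = o2 * cp.SW - cp.PW;
    for (int kw = 0; kw < cp.KW; ++kw) {
      const bool s2ok = (s2 + kw >= 0 && s2 + kw < S2);
      for (int kh = 0; kh < cp.KH; ++kh) {
        const int row0 = C * (kh + cp.KH * kw);
        float* dst = M.memptr() + colbase * R + row0;
        if (!s2ok) {
          for (int o1 = 0; o1 < O1; ++o1, dst += R)
            std::memset(dst, 0, sizeof(float) * C);
          continue;
        }
        int lo = 0, hi = O1 - 1;
        const int off = kh - cp.PH;
        while (lo <= hi && lo * cp.SH + off < 0) ++lo;
        if (hi * cp.SH + off > S1 - 1) hi = (S1 - 1 - off) / cp.SH;
        for (int o1 = 0; o1 < lo; ++o1, dst += R)
          std::memset(dst, 0, sizeof(float) * C);
        const float* src =
            X.memptr() + ((size_t)(lo * cp.SH + off) +
                          (size_t)S1 * (s2 + kw) + (size_t)S1 * S2 * n) * C;
        const size_t sstep = (size_t)C * cp.SH;
        for (int o1 = lo; o1 <= hi; ++o1, dst += R, src += sstep)
          std::memcpy(dst, src, sizeof(float) * C);
        for (int o1 = hi + 1; o1 < O1; ++o1, dst += R)
          std::memset(dst, 0, sizeof(float) * C);
      }
    }
  }
}

// Scatter-add transpose of im2col_groups: dM (krows x (q1-q0)*O1) into dX.
void col2im_groups(const fmat& dM, int C, int S1, int S2, int N,
                   const ConvP& cp, int O1, int O2, int q0, int q1,
                   fmat& dX) {
  const size_t R = dM.n_rows;
  (void)N;
  for (int q = q0; q < q1; ++q) {
    const int n = q / O2, o2 = q % O2;
    const size_t colbase = (size_t)(q - q0) * O1;
    const int s2 = o2 * cp.SW - cp.PW;
    for (int kw = 0; kw < cp.KW; ++kw) {
      if (s2 + kw < 0 || s2 + kw >= S2) continue;
      for (int kh = 0; kh < cp.KH; ++kh) {
        const int row0 = C * (kh + cp.KH * kw);
        const int off = kh - cp.PH;
        int lo = 0, hi = O1 - 1;
        while (lo <= hi && lo * cp.SH + off < 0) ++lo;
        if (hi * cp.SH + off > S1 - 1) hi = (S1 - 1 - off) / cp.SH;
        const float* src = dM.memptr() + (colbase + lo) * R + row0;
        float* dst =
            dX.memptr() + ((size_t)(lo * cp.SH + off) +
                           (size_t)S1 * (s2 + kw) + (size_t)S1 * S2 * n) * C;
        const size_t sstep = (size_t)C * cp.SH;
        for (int o1 = lo; o1 <= hi; ++o1, src += R, dst += sstep)
          for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
    }
  }
}

class WRN {
 public:
  int depth, width_k, dim, in_ch, n_classes;
  ConvP stem;
  std::vector<BlockP> blocks;
  BNP bn_final;
  int fc_woff = 0, fc_boff = 0, n_feat = 0;
  int n_params_ = 0, n_running_ = 0;
  std::vector<LayoutEntry> layout;

  fvec params, grads, vel, running;
  fvec accum;          // per-BN channel: sum of batch means then batch vars
  long accum_n = 0;

  // im2col tile scratch, grown on demand and reused across layers/steps
  std::vector<float> scr_m, scr_dm;

  // forward caches (valid between a train-mode forward and backward)
  fmat X0;
  int S1in = 0, S2in = 0, Nb = 0;
  std::vector<BlkCache> bc;
  fmat finsrc;  // input of the final BN
  BNCache bcF;
  fmat feat;

  WRN(int depth_, int width_k_, int dim_, int in_ch_, int n_classes_)
      : depth(depth_), width_k(width_k_), dim(dim_), in_ch(in_ch_),
        n_classes(n_classes_) {
    if (depth < 10 || (depth - 4) % 6 != 0)
      Rcpp::stop("depth must satisfy (depth - 4) %% 6 == 0 (e.g. 16, 28, 40); got %d",
                 depth);
    if (width_k < 1) Rcpp::stop("width_k must be >= 1");
    if (dim != 1 && dim != 2) Rcpp::stop("dimensionality must be 1 or 2");
    build();
  }

  int K() const { return 3; }

  ConvP make_conv(int cin, int cout, int k, int stride) {
    ConvP c;
    c.Cin = cin; c.Cout = cout;
    c.KH = k; c.KW = (dim == 2 ? k : 1);
    c.SH = stride; c.SW = (dim == 2 ? stride : 1);
    c.PH = (k - 1) / 2; c.PW = (dim == 2 ? (k - 1) / 2 : 0);
    return c;
  }

  int add_conv(ConvP& c, int off) {
    c.woff = off;
    layout.push_back({"conv", off, c.nw(), c.Cin * c.KH * c.KW,
                      c.Cout * c.KH * c.KW});
    return off + c.nw();
  }

  int add_bn(BNP& b, int C, int off, int& roff) {
    b.C = C; b.poff = off; b.roff = roff;
    layout.push_back({"bn_gamma", off, C, C, C});
    layout.push_back({"bn_beta", off + C, C, C, C});
    roff += 2 * C;
    return off + 2 * C;
  }

  void build() {
    const int n_blk = (depth - 4) / 6;
    const int widths[3] = {16 * width_k, 32 * width_k, 64 * width_k};
    int off = 0, roff = 0;

    stem = make_conv(in_ch, 16, K(), 1);
    off = add_conv(stem, off);

    int prev = 16;
    for (int g = 0; g < 3; ++g) {
      for (int b = 0; b < n_blk; ++b) {
        BlockP blk;
        const int cin = (b == 0) ? prev : widths[g];
        const int stride = (b == 0 && g > 0) ? 2 : 1;
        off = add_bn(blk.bn1, cin, off, roff);
        blk.c1 = make_conv(cin, widths[g], K(), stride);
        off = add_conv(blk.c1, off);
        off = add_bn(blk.bn2, widths[g], off, roff);
        blk.c2 = make_conv(widths[g], widths[g], K(), 1);
        off = add_conv(blk.c2, off);
        if (cin != widths[g] || stride != 1) {
          blk.proj = true;
          blk.cs = make_conv(cin, widths[g], 1, stride);
          off = add_conv(blk.cs, off);
        }
        blocks.push_back(blk);
      }
      prev = widths[g];
    }
    off = add_bn(bn_final, widths[2], off, roff);
    n_feat = widths[2];
    fc_woff = off;
    layout.push_back({"fc_w", off, n_classes * n_feat, n_feat, n_classes});
    off += n_classes * n_feat;
    fc_boff = off;
    layout.push_back({"fc_b", off, n_classes, n_feat, n_classes});
    off += n_classes;

    n_params_ = off;
    n_running_ = roff;
    params.zeros(n_params_);
    grads.zeros(n_params_);
    vel.zeros(n_params_);
    running.zeros(n_running_);
    reset_running();
    accum.zeros(n_running_);
  }

  void reset_running() {
    running.zeros();
    auto set_var1 = [&](const BNP& b) {
      for (int c = 0; c < b.C; ++c) running[b.roff + b.C + c] = 1.0f;
    };
    for (auto& blk : blocks) { set_var1(blk.bn1); set_var1(blk.bn2); }
    set_var1(bn_final);
  }

  fmat wmat(const ConvP& c) {
    return fmat(params.memptr() + c.woff, c.Cout, c.krows(), false, true);
  }
  fmat gwmat(const ConvP& c) {
    return fmat(grads.memptr() + c.woff, c.Cout, c.krows(), false, true);
  }

  // groups per tile: keep the patch tile around ~768 KB so it stays cached
  static int tile_q(int krows, int O1) {
    const size_t budget = 192 * 1024;  // floats
    int q = (int)(budget / std::max<size_t>(1, (size_t)krows * O1));
    return std::max(1, q);
  }

  fmat scratch(std::vector<float>& buf, size_t r, size_t c) {
    if (buf.size() < r * c) buf.resize(r * c);
    return fmat(buf.data(), r, c, false, true);
  }

  fmat conv_fw(const fmat& X, int C, int S1, int S2, int N, const ConvP& cp,
               int& O1, int& O2) {
    O1 = (S1 + 2 * cp.PH - cp.KH) / cp.SH + 1;
    O2 = (S2 + 2 * cp.PW - cp.KW) / cp.SW + 1;
    if (is_identity_gather(cp)) return wmat(cp) * X;
    const int R = cp.krows(), Q = O2 * N, qt = tile_q(R, O1);
    fmat Y(cp.Cout, (size_t)O1 * O2 * N);
    fmat W = wmat(cp);
    for (int q0 = 0; q0 < Q; q0 += qt) {
      const int q1 = std::min(Q, q0 + qt);
      fmat M = scratch(scr_m, R, (size_t)(q1 - q0) * O1);
      im2col_groups(X, C, S1, S2, N, cp, O1, O2, q0, q1, M);
      fmat Yv(Y.memptr() + (size_t)cp.Cout * q0 * O1, cp.Cout,
              (size_t)(q1 - q0) * O1, false, true);
      Yv = W * M;
    }
    return Y;
  }

  // accumulates dW; returns dX when need_dx
  fmat conv_bw(const fmat& dY, const fmat& Xin, int C, int S1, int S2, int N,
               const ConvP& cp, int O1, int O2, bool need_dx) {
    if (is_identity_gather(cp)) {
      gwmat(cp) += dY * Xin.t();
      if (!need_dx) return fmat();
      return wmat(cp).t() * dY;
    }
    const int R = cp.krows(), Q = O2 * N, qt = tile_q(R, O1);
    fmat dX;
    if (need_dx) dX.zeros(C, (size_t)S1 * S2 * N);
    fmat W = wmat(cp);
    fmat gW = gwmat(cp);
    for (int q0 = 0; q0 < Q; q0 += qt) {
      const int q1 = std::min(Q, q0 + qt);
      const size_t cols = (size_t)(q1 - q0) * O1;
      fmat M = scratch(scr_m, R, cols);
      im2col_groups(Xin, C, S1, S2, N, cp, O1, O2, q0, q1, M);
      const fmat dYv(const_cast<float*>(dY.memptr()) +
                         (size_t)cp.Cout * q0 * O1,
                     cp.Cout, cols, false, true);
      gW += dYv * M.t();
      if (need_dx) {
        fmat dM = scratch(scr_dm, R, cols);
        dM = W.t() * dYv;
        col2im_groups(dM, C, S1, S2, N, cp, O1, O2, q0, q1, dX);
      }
    }
    return dX;
  }

  // fused BN + ReLU, out of place: returns relu(gamma * xhat + beta)
  // while leaving the source (the backward pass re-normalizes from it)
  // untouched. One stats pass (train/accumulate modes) + one transform
  // pass.
  fmat bn_relu_fw(const fmat& src, const BNP& bn, int mode, BNCache* cache) {
    const int C = bn.C;
    const size_t Mc = src.n_cols;
    fvec g(params.memptr() + bn.poff, C, false, true);
    fvec b(params.memptr() + bn.poff + C, C, false, true);
    fvec m(C), v(C);
    if (mode == MODE_EVAL) {
      for (int c = 0; c < C; ++c) {
        m[c] = running[bn.roff + c];
        v[c] = running[bn.roff + C + c];
      }
    } else {
      fvec s(C, arma::fill::zeros), s2(C, arma::fill::zeros);
      for (size_t j = 0; j < Mc; ++j) {
        const float* sp = src.colptr(j);
        for (int c = 0; c < C; ++c) {
          s[c] += sp[c];
          s2[c] += sp[c] * sp[c];
        }
      }
      const float invM = 1.0f / (float)Mc;
      m = s * invM;
      v = s2 * invM - arma::square(m);
      v.clamp(0.0f, std::numeric_limits<float>::max());
      if (mode == MODE_TRAIN) {
        for (int c = 0; c < C; ++c) {
          running[bn.roff + c] =
              (1.0f - BN_MOMENTUM) * running[bn.roff + c] + BN_MOMENTUM * m[c];
          running[bn.roff + C + c] = (1.0f - BN_MOMENTUM) *
                                         running[bn.roff + C + c] +
                                     BN_MOMENTUM * v[c];
        }
      } else {  // MODE_ACCUM: equal-weight average of batch statistics
        for (int c = 0; c < C; ++c) {
          accum[bn.roff + c] += m[c];
          accum[bn.roff + C + c] += v[c];
        }
      }
    }
    fvec istd = 1.0f / arma::sqrt(v + BN_EPS);
    fvec scale = g % istd;
    fvec shift = b - m % scale;
    fmat out(C, Mc);
    for (size_t j = 0; j < Mc; ++j) {
      const float* sp = src.colptr(j);
      float* op = out.colptr(j);
      for (int c = 0; c < C; ++c) {
        const float y = scale[c] * sp[c] + shift[c];
        op[c] = y > 0.0f ? y : 0.0f;
      }
    }
    if (cache != nullptr) {
      cache->m = std::move(m);
      cache->istd = std::move(istd);
    }
    return out;
  }

  // Backward through (ReLU after BN): transforms dY in place into the
  // gradient w.r.t. src. The ReLU mask is recomputed from src and the
  // cached statistics (the forward output sign equals the sign of
  // scale*src + shift) and applied during the first pass, so no activation
  // copy is stored for it.
  void bn_bw(fmat& dY, const BNP& bn, const BNCache& cc, const fmat& src) {
    const int C = bn.C;
    const size_t Mc = dY.n_cols;
    fvec g(params.memptr() + bn.poff, C, false, true);
    fvec b(params.memptr() + bn.poff + C, C, false, true);
    fvec dg(grads.memptr() + bn.poff, C, false, true);
    fvec db(grads.memptr() + bn.poff + C, C, false, true);
    fvec scale = g % cc.istd;
    fvec shift = b - cc.m % scale;
    fvec s1(C, arma::fill::zeros), s2(C, arma::fill::zeros);
    for (size_t j = 0; j < Mc; ++j) {
      const float* sp = src.colptr(j);
      float* dp = dY.colptr(j);
      for (int c = 0; c < C; ++c) {
        float d = dp[c];
        if (scale[c] * sp[c] + shift[c] <= 0.0f) { d = 0.0f; dp[c] = 0.0f; }
        s1[c] += d;
        s2[c] += d * (sp[c] - cc.m[c]) * cc.istd[c];
      }
    }
    dg += s2;
    db += s1;
    const float invM = 1.0f / (float)Mc;
    fvec k1 = g % cc.istd;
    fvec k3 = -(k1 % cc.istd) % s2 * invM;
    fvec k2 = -(k1 % s1) * invM - k3 % cc.m;
    for (size_t j = 0; j < Mc; ++j) {
      const float* sp = src.colptr(j);
      float* dp = dY.colptr(j);
      for (int c = 0; c < C; ++c)
        dp[c] = k1[c] * dp[c] + k3[c] * sp[c] + k2[c];
    }
  }

  // x laid out (C x S1*S2*N); returns logits (n_classes x N)
  fmat forward(const fvec& x, int S1, int S2, int N, int mode,
               bool keep_cache) {
    S1in = S1; S2in = S2; Nb = N;
    const bool tr = keep_cache;
    X0 = fmat(const_cast<float*>(x.memptr()), in_ch, (size_t)S1 * S2 * N,
              true, true);
    int o1, o2;
    fmat A = conv_fw(X0, in_ch, S1, S2, N, stem, o1, o2);
    int s1 = o1, s2 = o2;
    bc.assign(blocks.size(), BlkCache());
    for (size_t i = 0; i < blocks.size(); ++i) {
      BlockP& blk = blocks[i];
      BlkCache& cc = bc[i];
      cc.S1i = s1; cc.S2i = s2;
      fmat O = bn_relu_fw(A, blk.bn1, mode, tr ? &cc.b1 : nullptr);
      cc.x = std::move(A);  // kept for the residual add (and bn1 backward)
      fmat A1 = conv_fw(O, blk.c1.Cin, s1, s2, N, blk.c1, o1, o2);
      cc.S1o = o1; cc.S2o = o2;
      fmat H = bn_relu_fw(A1, blk.bn2, mode, tr ? &cc.b2 : nullptr);
      if (tr) cc.a1 = std::move(A1);
      int q1, q2;
      fmat A2 = conv_fw(H, blk.c2.Cin, o1, o2, N, blk.c2, q1, q2);
      if (blk.proj) {
        int p1, p2;
        A2 += conv_fw(O, blk.cs.Cin, s1, s2, N, blk.cs, p1, p2);
      } else {
        A2 += cc.x;
      }
      if (tr) { cc.o = std::move(O); cc.h = std::move(H); }
      else cc.x.reset();
      A = std::move(A2);
      s1 = o1; s2 = o2;
    }
    finsrc = std::move(A);
    A = bn_relu_fw(finsrc, bn_final, mode, tr ? &bcF : nullptr);
    if (!tr) finsrc.reset();
    // global average pooling: (C x S*N) -> (C x N)
    const size_t S = (size_t)s1 * s2;
    feat.set_size(n_feat, N);
    for (int n = 0; n < N; ++n)
      feat.col(n) =
          arma::mean(A.cols((size_t)n * S, (size_t)(n + 1) * S - 1), 1);
    if (!tr) { X0.reset(); bc.clear(); }
    fmat W(params.memptr() + fc_woff, n_classes, n_feat, false, true);
    fvec b(params.memptr() + fc_boff, n_classes, false, true);
    fmat logits = W * feat;
    logits.each_col() += b;
    last_s1 = s1; last_s2 = s2;
    return logits;
  }

  int last_s1 = 0, last_s2 = 0;

  void backward(const fmat& dlogits) {
    if (bc.empty() || bc[0].x.is_empty())
      Rcpp::stop("backward() requires a preceding training-mode forward pass");
    fmat W(params.memptr() + fc_woff, n_classes, n_feat, false, true);
    fmat dW(grads.memptr() + fc_woff, n_classes, n_feat, false, true);
    fvec db(grads.memptr() + fc_boff, n_classes, false, true);
    dW += dlogits * feat.t();
    db += arma::sum(dlogits, 1);
    fmat dfeat = W.t() * dlogits;  // C x N
    const size_t S = (size_t)last_s1 * last_s2;
    fmat dA(n_feat, S * Nb);
    const float invS = 1.0f / (float)S;
    for (int n = 0; n < Nb; ++n)
      dA.cols((size_t)n * S, (size_t)(n + 1) * S - 1)
          .each_col() = fvec(dfeat.col(n) * invS);
    bn_bw(dA, bn_final, bcF, finsrc);
    finsrc.reset();
    for (int i = (int)blocks.size() - 1; i >= 0; --i) {
      BlockP& blk = blocks[i];
      BlkCache& cc = bc[i];
      fmat dH = conv_bw(dA, cc.h, blk.c2.Cin, cc.S1o, cc.S2o, Nb, blk.c2,
                        cc.S1o, cc.S2o, true);
      cc.h.reset();
      bn_bw(dH, blk.bn2, cc.b2, cc.a1);
      cc.a1.reset();
      fmat dO2 = conv_bw(dH, cc.o, blk.c1.Cin, cc.S1i, cc.S2i, Nb, blk.c1,
                         cc.S1o, cc.S2o, true);
      dH.reset();
      if (blk.proj)
        dO2 += conv_bw(dA, cc.o, blk.cs.Cin, cc.S1i, cc.S2i, Nb, blk.cs,
                       cc.S1o, cc.S2o, true);
      cc.o.reset();
      bn_bw(dO2, blk.bn1, cc.b1, cc.x);
      cc.x.reset();
      if (!blk.proj) dO2 += dA;
      dA = std::move(dO2);
    }
    // stem: weight gradient only (input gradient unused)
    int o1 = (S1in + 2 * stem.PH - stem.KH) / stem.SH + 1;
    int o2 = (S2in + 2 * stem.PW - stem.KW) / stem.SW + 1;
    conv_bw(dA, X0, in_ch, S1in, S2in, Nb, stem, o1, o2, false);
    // release caches
    X0.reset(); bc.clear();
  }

  void sgd_step(float lr, float momentum, float wd) {
    grads += wd * params;
    vel = momentum * vel + grads;
    params -= lr * vel;
    grads.zeros();
  }
};

}  // namespace

// [[Rcpp::export(name = ".wrn_create")]]
SEXP wrn_create(int depth, int width_k, int dim, int in_ch, int n_classes) {
  mallopt(M_MMAP_THRESHOLD, 1024 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 1024 * 1024 * 1024);
  Rcpp::XPtr<WRN> p(new WRN(depth, width_k, dim, in_ch, n_classes), true);
  return p;
}

// [[Rcpp::export(name = ".wrn_n_params")]]
int wrn_n_params(SEXP ptr) { return Rcpp::XPtr<WRN>(ptr)->n_params_; }

// [[Rcpp::export(name = ".wrn_layout")]]
Rcpp::DataFrame wrn_layout(SEXP ptr) {
  Rcpp::XPtr<WRN> p(ptr);
  const size_t n = p->layout.size();
  Rcpp::CharacterVector type(n);
  Rcpp::IntegerVector offset(n), size(n), fan_in(n), fan_out(n);
  for (size_t i = 0; i < n; ++i) {
    type[i] = p->layout[i].type;
    offset[i] = p->layout[i].offset + 1;  // 1-based for R
    size[i] = p->layout[i].size;
    fan_in[i] = p->layout[i].fan_in;
    fan_out[i] = p->layout[i].fan_out;
  }
  return Rcpp::DataFrame::create(
      Rcpp::Named("type") = type, Rcpp::Named("offset") = offset,
      Rcpp::Named("size") = size, Rcpp::Named("fan_in") = fan_in,
      Rcpp::Named("fan_out") = fan_out);
}

// [[Rcpp::export(name = ".wrn_get_params")]]
Rcpp::NumericVector wrn_get_params(SEXP ptr) {
  Rcpp::XPtr<WRN> p(ptr);
  return Rcpp::NumericVector(p->params.begin(), p->params.end());
}

// [[Rcpp::export(name = ".wrn_set_params")]]
void wrn_set_params(SEXP ptr, Rcpp::NumericVector v) {
  Rcpp::XPtr<WRN> p(ptr);
  if ((int)v.size() != p->n_params_)
    Rcpp::stop("parameter vector has length %d; network expects %d",
               (int)v.size(), p->n_params_);
  for (int i = 0; i < p->n_params_; ++i) p->params[i] = (float)v[i];
}

// [[Rcpp::export(name = ".wrn_get_running")]]
Rcpp::NumericVector wrn_get_running(SEXP ptr) {
  Rcpp::XPtr<WRN> p(ptr);
  return Rcpp::NumericVector(p->running.begin(), p->running.end());
}

// [[Rcpp::export(name = ".wrn_set_running")]]
void wrn_set_running(SEXP ptr, Rcpp::NumericVector v) {
  Rcpp::XPtr<WRN> p(ptr);
  if ((int)v.size() != p->n_running_)
    Rcpp::stop("running-statistics vector has length %d; expected %d",
               (int)v.size(), p->n_running_);
  for (int i = 0; i < p->n_running_; ++i) p->running[i] = (float)v[i];
}

// [[Rcpp::export(name = ".wrn_reset_state")]]
void wrn_reset_state(SEXP ptr) {
  Rcpp::XPtr<WRN> p(ptr);
  p->vel.zeros();
  p->grads.zeros();
  p->reset_running();
}

static fvec as_fvec(const Rcpp::NumericVector& x) {
  fvec out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = (float)x[i];
  return out;
}

// dims = c(C, S1, S2, N)
// [[Rcpp::export(name = ".wrn_forward")]]
Rcpp::NumericMatrix wrn_forward(SEXP ptr, Rcpp::NumericVector x,
                                Rcpp::IntegerVector dims, int mode,
                                bool keep_cache) {
  Rcpp::XPtr<WRN> p(ptr);
  const int C = dims[0], S1 = dims[1], S2 = dims[2], N = dims[3];
  if (C != p->in_ch)
    Rcpp::stop("input has %d channels; network expects %d", C, p->in_ch);
  if ((R_xlen_t)C * S1 * S2 * N != x.size())
    Rcpp::stop("input length does not match dims");
  fvec xf = as_fvec(x);
  fmat logits = p->forward(xf, S1, S2, N, mode, keep_cache);
  Rcpp::NumericMatrix out(N, p->n_classes);
  for (int n = 0; n < N; ++n)
    for (int k = 0; k < p->n_classes; ++k) out(n, k) = logits(k, n);
  return out;
}

// [[Rcpp::export(name = ".wrn_features")]]
Rcpp::NumericMatrix wrn_features(SEXP ptr, Rcpp::NumericVector x,
                                 Rcpp::IntegerVector dims) {
  Rcpp::XPtr<WRN> p(ptr);
  const int S1 = dims[1], S2 = dims[2], N = dims[3];
  fvec xf = as_fvec(x);
  p->forward(xf, S1, S2, N, MODE_EVAL, false);
  Rcpp::NumericMatrix out(N, p->n_feat);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < p->n_feat; ++c) out(n, c) = p->feat(c, n);
  return out;
}

// dlogits: N x K (matches wrn_forward output orientation)
// [[Rcpp::export(name = ".wrn_backward")]]
void wrn_backward(SEXP ptr, Rcpp::NumericMatrix dlogits) {
  Rcpp::XPtr<WRN> p(ptr);
  const int N = dlogits.nrow(), K = dlogits.ncol();
  if (K != p->n_classes || N != p->Nb)
    Rcpp::stop("gradient shape does not match the cached forward pass");
  fmat dl(K, N);
  for (int n = 0; n < N; ++n)
    for (int k = 0; k < K; ++k) dl(k, n) = (float)dlogits(n, k);
  p->backward(dl);
}

// [[Rcpp::export(name = ".wrn_sgd_step")]]
void wrn_sgd_step(SEXP ptr, double lr, double momentum, double wd) {
  Rcpp::XPtr<WRN>(ptr)->sgd_step((float)lr, (float)momentum, (float)wd);
}

// [[Rcpp::export(name = ".wrn_bn_accum_reset")]]
void wrn_bn_accum_reset(SEXP ptr) {
  Rcpp::XPtr<WRN> p(ptr);
  p->accum.zeros();
  p->accum_n = 0;
}

// [[Rcpp::export(name = ".wrn_bn_accum_add")]]
void wrn_bn_accum_add(SEXP ptr) { Rcpp::XPtr<WRN>(ptr)->accum_n += 1; }

// [[Rcpp::export(name = ".wrn_bn_accum_finalize")]]
void wrn_bn_accum_finalize(SEXP ptr) {
  Rcpp::XPtr<WRN> p(ptr);
  if (p->accum_n < 1)
    Rcpp::stop("no accumulation passes recorded; run forward in accumulate mode first");
  p->running = p->accum / (float)p->accum_n;
}
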