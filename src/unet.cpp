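// Four-level U-Net for 5-class outer-retina B-scan segmentation.
//
// No deep-learning framework is available to the package, so the network is
// implemented directly on Armadillo (float32): im2col/GEMM convolutions,
// batch normalization, leaky-ReLU, 2x2 max pooling, 2x2-stride-2 transposed
// convolutions, skip concatenations, a softmax head, the combined
// Dice + weighted cross-entropy loss, full backpropagation and Adam.
//
// Topology (base filters F, doubling per level, 5x5 kernels, "same" padding):
//   enc1(1->F->F) -> pool -> enc2(->2F) -> pool -> enc3(->4F) -> pool
//   -> bottleneck(->8F) -> up3 -> [cat enc3] -> dec3(->4F) -> up2
//   -> [cat enc2] -> dec2(->2F) -> up1 -> [cat enc1] -> dec1(->F)
//   -> 1x1 conv -> n_classes logits.
// Input H and W must be divisible by 8 (three pooling stages).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace arma;
using Rcpp::List;
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;
using Rcpp::IntegerMatrix;
using Rcpp::XPtr;
using Rcpp::stop;

static const float BN_EPS   = 1e-5f;
static const float BN_MOM   = 0.9f;   // running-stat momentum
static const float LRELU    = 0.1f;   // leaky-ReLU negative slope
static const double ADAM_B1 = 0.9;
static const double ADAM_B2 = 0.999;
static const double ADAM_EPS = 1e-8;

// ---------------------------------------------------------------- blocks --

struct ConvBlock {
  int cin = 0, cout = 0, k = 5;
  bool bn_act = true;           // conv -> BN -> leaky-ReLU (final 1x1: false)
  fmat W;  fvec b;              // W: cout x (cin*k*k)
  fvec g, bb, rm, rv;           // BN gamma, beta, running mean/var
  // gradients
  fmat dW; fvec db, dg, dbb;
  // Adam first/second moments
  fmat mW, vW; fvec mb, vb, mg, vg, mbb, vbb;
};

struct UpBlock {                // transposed conv, 2x2 kernel, stride 2
  int cin = 0, cout = 0;
  fmat W; fvec b;               // W: cout x (cin*4), offset o = di*2+dj
  fmat dW; fvec db;
  fmat mW, vW; fvec mb, vb;
};

struct UNet {
  int F = 16, nclass = 5;
  ConvBlock cb[15];
  UpBlock up[3];
  long step = 0;                // Adam time step
};

typedef std::vector<fcube> Batch;

struct BlockCache { Batch X, xhat; fvec invstd; };
struct NetCache {
  BlockCache c[15];
  Batch poolX[3];
  Batch upX[3];
  Batch cat_skip[3];            // skip halves feeding the concatenations
};

// --------------------------------------------------------------- helpers --

static fmat im2col(const fcube& X, int k) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices, pad = k / 2;
  fmat col(C * k * k, H * W);
  fmat P(H + 2 * pad, W + 2 * pad);
  for (int c = 0; c < C; ++c) {
    P.zeros();
    P.submat(pad, pad, pad + H - 1, pad + W - 1) = X.slice(c);
    for (int dx = 0; dx < k; ++dx)
      for (int dy = 0; dy < k; ++dy)
        col.row(c * k * k + dx * k + dy) =
          vectorise(P.submat(dy, dx, dy + H - 1, dx + W - 1)).t();
  }
  return col;
}

static fcube col2im(const fmat& col, int H, int W, int C, int k) {
  const int pad = k / 2;
  fcube dX(H, W, C);
  fmat P(H + 2 * pad, W + 2 * pad);
  for (int c = 0; c < C; ++c) {
    P.zeros();
    for (int dx = 0; dx < k; ++dx)
      for (int dy = 0; dy < k; ++dy)
        P.submat(dy, dx, dy + H - 1, dx + W - 1) +=
          reshape(col.row(c * k * k + dx * k + dy), H, W);
    dX.slice(c) = P.submat(pad, pad, pad + H - 1, pad + W - 1);
  }
  return dX;
}

static fcube conv_fw_one(const ConvBlock& L, const fcube& X) {
  const int H = X.n_rows, W = X.n_cols;
  fmat Ym = L.W * im2col(X, L.k);
  Ym.each_col() += L.b;
  fcube Y(H, W, L.cout);
  for (int c = 0; c < L.cout; ++c)
    Y.slice(c) = reshape(Ym.row(c), H, W);
  return Y;
}

// conv -> (BN -> leaky-ReLU) over a batch; caches what backward needs
static Batch block_fw(ConvBlock& L, const Batch& Xs, BlockCache& C,
                      bool train, bool update_running) {
  const int N = (int)Xs.size();
  C.X = Xs;
  Batch Y(N);
  for (int s = 0; s < N; ++s) Y[s] = conv_fw_one(L, Xs[s]);
  if (!L.bn_act) return Y;

  const int H = Y[0].n_rows, W = Y[0].n_cols, Cc = L.cout;
  const float M = (float)N * H * W;
  fvec mean(Cc), var(Cc);
  if (train) {
    for (int c = 0; c < Cc; ++c) {
      float s1 = 0, s2 = 0;
      for (int s = 0; s < N; ++s) {
        s1 += accu(Y[s].slice(c));
        s2 += accu(square(Y[s].slice(c)));
      }
      mean(c) = s1 / M;
      var(c)  = std::max(s2 / M - mean(c) * mean(c), 0.0f);
    }
    if (update_running) {
      L.rm = BN_MOM * L.rm + (1 - BN_MOM) * mean;
      L.rv = BN_MOM * L.rv + (1 - BN_MOM) * var;
    }
  } else {
    mean = L.rm; var = L.rv;
  }
  C.invstd = 1.0f / sqrt(var + BN_EPS);
  C.xhat.assign(N, fcube(H, W, Cc));
  for (int s = 0; s < N; ++s)
    for (int c = 0; c < Cc; ++c) {
      fmat xh = (Y[s].slice(c) - mean(c)) * C.invstd(c);
      C.xhat[s].slice(c) = xh;
      fmat z = L.g(c) * xh + L.bb(c);
      fmat pos = conv_to<fmat>::from(z >= 0);
      Y[s].slice(c) = z % (pos + LRELU * (1.0f - pos));
    }
  return Y;
}

static Batch block_bw(ConvBlock& L, const Batch& dOut, const BlockCache& C) {
  const int N = (int)dOut.size();
  Batch dY(N);
  if (L.bn_act) {
    const int H = dOut[0].n_rows, W = dOut[0].n_cols, Cc = L.cout;
    const float M = (float)N * H * W;
    for (int s = 0; s < N; ++s) dY[s].set_size(H, W, Cc);
    for (int c = 0; c < Cc; ++c) {
      float s1 = 0, s2 = 0;
      std::vector<fmat> dz(N);
      for (int s = 0; s < N; ++s) {
        const fmat& xh = C.xhat[s].slice(c);
        fmat z = L.g(c) * xh + L.bb(c);
        fmat pos = conv_to<fmat>::from(z >= 0);
        dz[s] = dOut[s].slice(c) % (pos + LRELU * (1.0f - pos));
        s1 += accu(dz[s]);
        s2 += accu(dz[s] % xh);
      }
      L.dbb(c) += s1;
      L.dg(c)  += s2;
      const float gi = L.g(c), is = C.invstd(c);
      for (int s = 0; s < N; ++s)
        dY[s].slice(c) = (is / M) *
          (M * gi * dz[s] - gi * s1 - C.xhat[s].slice(c) * (gi * s2));
    }
  } else {
    dY = dOut;
  }
  // conv backward
  const int H = C.X[0].n_rows, W = C.X[0].n_cols;
  Batch dX(N);
  for (int s = 0; s < N; ++s) {
    fmat col = im2col(C.X[s], L.k);
    fmat dYm(L.cout, H * W);
    for (int c = 0; c < L.cout; ++c)
      dYm.row(c) = vectorise(dY[s].slice(c)).t();
    L.dW += dYm * col.t();
    L.db += sum(dYm, 1);
    dX[s] = col2im(L.W.t() * dYm, H, W, L.cin, L.k);
  }
  return dX;
}

static fcube pool_fw_one(const fcube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  fcube Y(H / 2, W / 2, C);
  for (int c = 0; c < C; ++c) {
    const fmat& S = X.slice(c);
    fmat& O = Y.slice(c);
    for (int j = 0; j < W / 2; ++j)
      for (int i = 0; i < H / 2; ++i) {
        float m = S(2 * i, 2 * j);
        m = std::max(m, S(2 * i + 1, 2 * j));
        m = std::max(m, S(2 * i, 2 * j + 1));
        m = std::max(m, S(2 * i + 1, 2 * j + 1));
        O(i, j) = m;
      }
  }
  return Y;
}

static fcube pool_bw_one(const fcube& X, const fcube& dY) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  fcube dX(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const fmat& S = X.slice(c);
    const fmat& G = dY.slice(c);
    fmat& D = dX.slice(c);
    for (int j = 0; j < W / 2; ++j)
      for (int i = 0; i < H / 2; ++i) {
        int bi = 2 * i, bj = 2 * j;          // first maximum in fixed order
        float m = S(bi, bj);
        if (S(2*i+1, 2*j)     > m) { m = S(2*i+1, 2*j);     bi = 2*i+1; bj = 2*j;   }
        if (S(2*i,   2*j+1)   > m) { m = S(2*i,   2*j+1);   bi = 2*i;   bj = 2*j+1; }
        if (S(2*i+1, 2*j+1)   > m) {                        bi = 2*i+1; bj = 2*j+1; }
        D(bi, bj) += G(i, j);
      }
  }
  return dX;
}

static fcube up_fw_one(const UpBlock& U, const fcube& X) {
  const int H = X.n_rows, W = X.n_cols;
  fmat Xm(U.cin, H * W);
  for (int c = 0; c < U.cin; ++c) Xm.row(c) = vectorise(X.slice(c)).t();
  fcube Y(2 * H, 2 * W, U.cout);
  for (int di = 0; di < 2; ++di)
    for (int dj = 0; dj < 2; ++dj) {
      const int o = di * 2 + dj;
      fmat Wo(U.cout, U.cin);
      for (int c = 0; c < U.cin; ++c) Wo.col(c) = U.W.col(c * 4 + o);
      fmat Yo = Wo * Xm;
      uvec ri = regspace<uvec>(di, 2, 2 * H - 1);
      uvec cj = regspace<uvec>(dj, 2, 2 * W - 1);
      for (int c = 0; c < U.cout; ++c)
        Y.slice(c).submat(ri, cj) = reshape(Yo.row(c), H, W) + U.b(c);
    }
  return Y;
}

static fcube up_bw_one(UpBlock& U, const fcube& X, const fcube& dY) {
  const int H = X.n_rows, W = X.n_cols;
  fmat Xm(U.cin, H * W);
  for (int c = 0; c < U.cin; ++c) Xm.row(c) = vectorise(X.slice(c)).t();
  fmat dXm(U.cin, H * W, fill::zeros);
  for (int c = 0; c < U.cout; ++c) U.db(c) += accu(dY.slice(c));
  for (int di = 0; di < 2; ++di)
    for (int dj = 0; dj < 2; ++dj) {
      const int o = di * 2 + dj;
      uvec ri = regspace<uvec>(di, 2, 2 * H - 1);
      uvec cj = regspace<uvec>(dj, 2, 2 * W - 1);
      fmat dYo(U.cout, H * W);
      for (int c = 0; c < U.cout; ++c) {
        fmat M = dY.slice(c).submat(ri, cj);
        dYo.row(c) = vectorise(M).t();
      }
      fmat dWo = dYo * Xm.t();               // cout x cin
      for (int c = 0; c < U.cin; ++c) U.dW.col(c * 4 + o) += dWo.col(c);
      fmat Wo(U.cout, U.cin);
      for (int c = 0; c < U.cin; ++c) Wo.col(c) = U.W.col(c * 4 + o);
      dXm += Wo.t() * dYo;
    }
  fcube dX(H, W, U.cin);
  for (int c = 0; c < U.cin; ++c) dX.slice(c) = reshape(dXm.row(c), H, W);
  return dX;
}

static Batch cat_batch(const Batch& A, const Batch& B) {
  Batch Y(A.size());
  for (size_t s = 0; s < A.size(); ++s) Y[s] = join_slices(A[s], B[s]);
  return Y;
}

// ---------------------------------------------------------- construction --

static fmat he_init(int rows, int cols, int fan_in, std::mt19937& gen) {
  std::normal_distribution<float> dist(0.0f, std::sqrt(2.0f / fan_in));
  fmat W(rows, cols);
  for (uword i = 0; i < W.n_elem; ++i) W(i) = dist(gen);
  return W;
}

static void init_conv(ConvBlock& L, int cin, int cout, int k, bool bn_act,
                      std::mt19937& gen) {
  L.cin = cin; L.cout = cout; L.k = k; L.bn_act = bn_act;
  const int fan_in = cin * k * k;
  L.W = he_init(cout, fan_in, fan_in, gen);
  L.b = fvec(cout, fill::zeros);
  L.g  = fvec(cout, fill::ones);  L.bb = fvec(cout, fill::zeros);
  L.rm = fvec(cout, fill::zeros); L.rv = fvec(cout, fill::ones);
  L.dW = fmat(size(L.W), fill::zeros); L.db = fvec(cout, fill::zeros);
  L.dg = fvec(cout, fill::zeros); L.dbb = fvec(cout, fill::zeros);
  L.mW = L.vW = L.dW; L.mb = L.vb = L.db;
  L.mg = L.vg = L.mbb = L.vbb = L.dg;
}

static void init_up(UpBlock& U, int cin, int cout, std::mt19937& gen) {
  U.cin = cin; U.cout = cout;
  const int fan_in = cin * 4;
  U.W = he_init(cout, fan_in, fan_in, gen);
  U.b = fvec(cout, fill::zeros);
  U.dW = fmat(size(U.W), fill::zeros); U.db = fvec(cout, fill::zeros);
  U.mW = U.vW = U.dW; U.mb = U.vb = U.db;
}

static UNet* make_unet(int F, int nclass, int seed) {
  std::mt19937 gen((unsigned)seed);
  UNet* n = new UNet();
  n->F = F; n->nclass = nclass;
  init_conv(n->cb[0],  1,     F,     5, true, gen);   // enc1
  init_conv(n->cb[1],  F,     F,     5, true, gen);
  init_conv(n->cb[2],  F,     2 * F, 5, true, gen);   // enc2
  init_conv(n->cb[3],  2 * F, 2 * F, 5, true, gen);
  init_conv(n->cb[4],  2 * F, 4 * F, 5, true, gen);   // enc3
  init_conv(n->cb[5],  4 * F, 4 * F, 5, true, gen);
  init_conv(n->cb[6],  4 * F, 8 * F, 5, true, gen);   // bottleneck
  init_conv(n->cb[7],  8 * F, 8 * F, 5, true, gen);
  init_conv(n->cb[8],  8 * F, 4 * F, 5, true, gen);   // dec3 (after concat)
  init_conv(n->cb[9],  4 * F, 4 * F, 5, true, gen);
  init_conv(n->cb[10], 4 * F, 2 * F, 5, true, gen);   // dec2
  init_conv(n->cb[11], 2 * F, 2 * F, 5, true, gen);
  init_conv(n->cb[12], 2 * F, F,     5, true, gen);   // dec1
  init_conv(n->cb[13], F,     F,     5, true, gen);
  init_conv(n->cb[14], F, nclass,    1, false, gen);  // 1x1 head
  init_up(n->up[0], 8 * F, 4 * F, gen);
  init_up(n->up[1], 4 * F, 2 * F, gen);
  init_up(n->up[2], 2 * F, F, gen);
  return n;
}

// ----------------------------------------------------- forward / backward --

static Batch net_forward(UNet& n, const Batch& Xs, NetCache& C,
                         bool train, bool update_running) {
  Batch e1a = block_fw(n.cb[0], Xs,  C.c[0], train, update_running);
  Batch e1  = block_fw(n.cb[1], e1a, C.c[1], train, update_running);
  C.poolX[0] = e1;
  Batch p1(e1.size()); for (size_t s = 0; s < e1.size(); ++s) p1[s] = pool_fw_one(e1[s]);
  Batch e2a = block_fw(n.cb[2], p1,  C.c[2], train, update_running);
  Batch e2  = block_fw(n.cb[3], e2a, C.c[3], train, update_running);
  C.poolX[1] = e2;
  Batch p2(e2.size()); for (size_t s = 0; s < e2.size(); ++s) p2[s] = pool_fw_one(e2[s]);
  Batch e3a = block_fw(n.cb[4], p2,  C.c[4], train, update_running);
  Batch e3  = block_fw(n.cb[5], e3a, C.c[5], train, update_running);
  C.poolX[2] = e3;
  Batch p3(e3.size()); for (size_t s = 0; s < e3.size(); ++s) p3[s] = pool_fw_one(e3[s]);
  Batch ba  = block_fw(n.cb[6], p3,  C.c[6], train, update_running);
  Batch bb  = block_fw(n.cb[7], ba,  C.c[7], train, update_running);

  C.upX[0] = bb;
  Batch u3(bb.size()); for (size_t s = 0; s < bb.size(); ++s) u3[s] = up_fw_one(n.up[0], bb[s]);
  C.cat_skip[0] = e3;
  Batch d3a = block_fw(n.cb[8], cat_batch(u3, e3), C.c[8], train, update_running);
  Batch d3  = block_fw(n.cb[9], d3a, C.c[9], train, update_running);

  C.upX[1] = d3;
  Batch u2(d3.size()); for (size_t s = 0; s < d3.size(); ++s) u2[s] = up_fw_one(n.up[1], d3[s]);
  C.cat_skip[1] = e2;
  Batch d2a = block_fw(n.cb[10], cat_batch(u2, e2), C.c[10], train, update_running);
  Batch d2  = block_fw(n.cb[11], d2a, C.c[11], train, update_running);

  C.upX[2] = d2;
  Batch u1(d2.size()); for (size_t s = 0; s < d2.size(); ++s) u1[s] = up_fw_one(n.up[2], d2[s]);
  C.cat_skip[2] = e1;
  Batch d1a = block_fw(n.cb[12], cat_batch(u1, e1), C.c[12], train, update_running);
  Batch d1  = block_fw(n.cb[13], d1a, C.c[13], train, update_running);
  return block_fw(n.cb[14], d1, C.c[14], train, update_running);  // logits
}

// splits concat gradient into (up part, skip part)
static void split_grad(const Batch& dcat, int c_up, Batch& d_up, Batch& d_skip) {
  d_up.resize(dcat.size()); d_skip.resize(dcat.size());
  for (size_t s = 0; s < dcat.size(); ++s) {
    d_up[s]   = dcat[s].slices(0, c_up - 1);
    d_skip[s] = dcat[s].slices(c_up, dcat[s].n_slices - 1);
  }
}

static void net_backward(UNet& n, const Batch& dlogits, NetCache& C) {
  Batch g = block_bw(n.cb[14], dlogits, C.c[14]);
  g = block_bw(n.cb[13], g, C.c[13]);
  g = block_bw(n.cb[12], g, C.c[12]);
  Batch du, dskip1;
  split_grad(g, n.F, du, dskip1);
  Batch g2(du.size());
  for (size_t s = 0; s < du.size(); ++s) g2[s] = up_bw_one(n.up[2], C.upX[2][s], du[s]);

  g2 = block_bw(n.cb[11], g2, C.c[11]);
  g2 = block_bw(n.cb[10], g2, C.c[10]);
  Batch du2, dskip2;
  split_grad(g2, 2 * n.F, du2, dskip2);
  Batch g3(du2.size());
  for (size_t s = 0; s < du2.size(); ++s) g3[s] = up_bw_one(n.up[1], C.upX[1][s], du2[s]);

  g3 = block_bw(n.cb[9], g3, C.c[9]);
  g3 = block_bw(n.cb[8], g3, C.c[8]);
  Batch du3, dskip3;
  split_grad(g3, 4 * n.F, du3, dskip3);
  Batch g4(du3.size());
  for (size_t s = 0; s < du3.size(); ++s) g4[s] = up_bw_one(n.up[0], C.upX[0][s], du3[s]);

  g4 = block_bw(n.cb[7], g4, C.c[7]);
  g4 = block_bw(n.cb[6], g4, C.c[6]);
  for (size_t s = 0; s < g4.size(); ++s)
    g4[s] = pool_bw_one(C.poolX[2][s], g4[s]);
  for (size_t s = 0; s < g4.size(); ++s) g4[s] += dskip3[s];
  g4 = block_bw(n.cb[5], g4, C.c[5]);
  g4 = block_bw(n.cb[4], g4, C.c[4]);
  for (size_t s = 0; s < g4.size(); ++s)
    g4[s] = pool_bw_one(C.poolX[1][s], g4[s]);
  for (size_t s = 0; s < g4.size(); ++s) g4[s] += dskip2[s];
  g4 = block_bw(n.cb[3], g4, C.c[3]);
  g4 = block_bw(n.cb[2], g4, C.c[2]);
  for (size_t s = 0; s < g4.size(); ++s)
    g4[s] = pool_bw_one(C.poolX[0][s], g4[s]);
  for (size_t s = 0; s < g4.size(); ++s) g4[s] += dskip1[s];
  g4 = block_bw(n.cb[1], g4, C.c[1]);
  block_bw(n.cb[0], g4, C.c[0]);
}

// ------------------------------------------------------------------ loss --

static Batch softmax_batch(const Batch& logits) {
  Batch P(logits.size());
  for (size_t s = 0; s < logits.size(); ++s) {
    const fcube& L = logits[s];
    const int H = L.n_rows, W = L.n_cols, Cc = L.n_slices;
    fmat mx = L.slice(0);
    for (int c = 1; c < Cc; ++c) mx = arma::max(mx, L.slice(c));
    fcube Pc(H, W, Cc);
    fmat sm(H, W, fill::zeros);
    for (int c = 0; c < Cc; ++c) { Pc.slice(c) = exp(L.slice(c) - mx); sm += Pc.slice(c); }
    for (int c = 0; c < Cc; ++c) Pc.slice(c) /= sm;
    P[s] = Pc;
  }
  return P;
}

// combined loss: lambda * weighted-CE + (1-lambda) * (1 - mean smoothed Dice)
static double loss_and_grad(const Batch& logits,
                            const std::vector<imat>& Ys,
                            double lambda, const vec& wts, int nclass,
                            Batch* dlogits) {
  Batch P = softmax_batch(logits);
  const int N = (int)P.size();
  vec I(nclass, fill::zeros), Psum(nclass, fill::zeros), Tsum(nclass, fill::zeros);
  double ce = 0, wsum = 0;
  for (int s = 0; s < N; ++s) {
    const int H = P[s].n_rows, W = P[s].n_cols;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const int y = Ys[s](i, j);
        const double py = std::max((double)P[s](i, j, y), 1e-12);
        ce += wts(y) * (-std::log(py));
        wsum += wts(y);
        I(y) += py;
        Tsum(y) += 1.0;
      }
    for (int c = 0; c < nclass; ++c) Psum(c) += accu(P[s].slice(c));
  }
  if (wsum <= 0) stop("all class weights are zero over this batch");
  const double ce_loss = ce / wsum;
  double dice = 0;
  vec A(nclass), B(nclass);
  for (int c = 0; c < nclass; ++c) {
    A(c) = 2.0 * I(c) + 1.0;
    B(c) = Psum(c) + Tsum(c) + 1.0;
    dice += A(c) / B(c);
  }
  dice /= nclass;
  const double loss = lambda * ce_loss + (1.0 - lambda) * (1.0 - dice);
  if (!dlogits) return loss;

  dlogits->resize(N);
  for (int s = 0; s < N; ++s) {
    const int H = P[s].n_rows, W = P[s].n_cols;
    fcube g(H, W, nclass, fill::zeros);
    for (int c = 0; c < nclass; ++c) {
      const double base = -(1.0 - lambda) / nclass;
      // dDice_c/dp_c at pixel = (2*y_c*B - A)/B^2
      const float gc0 = (float)(base * (-A(c) / (B(c) * B(c))));
      const float gc1 = (float)(base * ((2.0 * B(c) - A(c)) / (B(c) * B(c))));
      fmat gm(H, W); gm.fill(gc0);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i)
          if (Ys[s](i, j) == c) gm(i, j) = gc1;
      g.slice(c) = gm;
    }
    // CE part: d/dp_y = -lambda * w_y / (p_y * wsum)
    for (int j = 0; j < P[s].n_cols; ++j)
      for (int i = 0; i < (int)P[s].n_rows; ++i) {
        const int y = Ys[s](i, j);
        const double py = std::max((double)P[s](i, j, y), 1e-12);
        g(i, j, y) += (float)(-lambda * wts(y) / (py * wsum));
      }
    // chain through softmax: dz_c = p_c * (g_c - sum_k g_k p_k)
    fmat dot(P[s].n_rows, P[s].n_cols, fill::zeros);
    for (int c = 0; c < nclass; ++c) dot += g.slice(c) % P[s].slice(c);
    fcube dz(P[s].n_rows, P[s].n_cols, nclass);
    for (int c = 0; c < nclass; ++c)
      dz.slice(c) = P[s].slice(c) % (g.slice(c) - dot);
    (*dlogits)[s] = dz;
  }
  return loss;
}

// ------------------------------------------------------------------ Adam --

static void adam_mat(fmat& W, fmat& g, fmat& m, fmat& v,
                     double lr, long t) {
  m = (float)ADAM_B1 * m + (float)(1 - ADAM_B1) * g;
  v = (float)ADAM_B2 * v + (float)(1 - ADAM_B2) * square(g);
  const double a = lr * std::sqrt(1 - std::pow(ADAM_B2, (double)t)) /
                   (1 - std::pow(ADAM_B1, (double)t));
  W -= (float)a * (m / (sqrt(v) + (float)ADAM_EPS));
  g.zeros();
}
static void adam_vec(fvec& W, fvec& g, fvec& m, fvec& v,
                     double lr, long t) {
  m = (float)ADAM_B1 * m + (float)(1 - ADAM_B1) * g;
  v = (float)ADAM_B2 * v + (float)(1 - ADAM_B2) * square(g);
  const double a = lr * std::sqrt(1 - std::pow(ADAM_B2, (double)t)) /
                   (1 - std::pow(ADAM_B1, (double)t));
  W -= (float)a * (m / (sqrt(v) + (float)ADAM_EPS));
  g.zeros();
}

static void zero_grads(UNet& n) {
  for (int l = 0; l < 15; ++l) {
    n.cb[l].dW.zeros(); n.cb[l].db.zeros();
    n.cb[l].dg.zeros(); n.cb[l].dbb.zeros();
  }
  for (int u = 0; u < 3; ++u) { n.up[u].dW.zeros(); n.up[u].db.zeros(); }
}

static void adam_step(UNet& n, double lr) {
  n.step += 1;
  for (int l = 0; l < 15; ++l) {
    ConvBlock& L = n.cb[l];
    adam_mat(L.W, L.dW, L.mW, L.vW, lr, n.step);
    adam_vec(L.b, L.db, L.mb, L.vb, lr, n.step);
    if (L.bn_act) {
      adam_vec(L.g,  L.dg,  L.mg,  L.vg,  lr, n.step);
      adam_vec(L.bb, L.dbb, L.mbb, L.vbb, lr, n.step);
    }
  }
  for (int u = 0; u < 3; ++u) {
    adam_mat(n.up[u].W, n.up[u].dW, n.up[u].mW, n.up[u].vW, lr, n.step);
    adam_vec(n.up[u].b, n.up[u].db, n.up[u].mb, n.up[u].vb, lr, n.step);
  }
}

// ------------------------------------------------------------- R glue ----

static Batch batch_from_list(const List& images) {
  Batch Xs(images.size());
  for (int s = 0; s < images.size(); ++s) {
    NumericMatrix M(images[s]);
    if (M.nrow() % 8 != 0 || M.ncol() % 8 != 0)
      stop("image dimensions must be divisible by 8, got %d x %d",
           M.nrow(), M.ncol());
    fcube X(M.nrow(), M.ncol(), 1);
    for (int j = 0; j < M.ncol(); ++j)
      for (int i = 0; i < M.nrow(); ++i)
        X(i, j, 0) = (float)M(i, j);
    Xs[s] = X;
  }
  return Xs;
}

static std::vector<imat> masks_from_list(const List& masks, int nclass) {
  std::vector<imat> Ys(masks.size());
  for (int s = 0; s < masks.size(); ++s) {
    IntegerMatrix M(masks[s]);
    imat Y(M.nrow(), M.ncol());
    for (int j = 0; j < M.ncol(); ++j)
      for (int i = 0; i < M.nrow(); ++i) {
        const int y = M(i, j);
        if (y < 0 || y >= nclass) stop("mask label %d outside 0..%d", y, nclass - 1);
        Y(i, j) = y;
      }
    Ys[s] = Y;
  }
  return Ys;
}

// [[Rcpp::export]]
SEXP cpp_unet_create(int base_filters, int n_classes, int seed) {
  if (base_filters < 1) stop("base_filters must be >= 1");
  if (n_classes < 2) stop("n_classes must be >= 2");
  XPtr<UNet> p(make_unet(base_filters, n_classes, seed), true);
  return p;
}

// [[Rcpp::export]]
double cpp_unet_nparams(SEXP ptr) {
  XPtr<UNet> n(ptr);
  double tot = 0;
  for (int l = 0; l < 15; ++l) {
    tot += n->cb[l].W.n_elem + n->cb[l].b.n_elem;
    if (n->cb[l].bn_act) tot += n->cb[l].g.n_elem + n->cb[l].bb.n_elem;
  }
  for (int u = 0; u < 3; ++u) tot += n->up[u].W.n_elem + n->up[u].b.n_elem;
  return tot;
}

// [[Rcpp::export]]
List cpp_unet_forward(SEXP ptr, List images, bool train = false) {
  XPtr<UNet> n(ptr);
  Batch Xs = batch_from_list(images);
  NetCache C;
  Batch P = softmax_batch(net_forward(*n, Xs, C, train, false));
  List out(P.size());
  for (size_t s = 0; s < P.size(); ++s) {
    Rcpp::NumericVector a(P[s].n_elem);
    std::copy(P[s].begin(), P[s].end(), a.begin());
    a.attr("dim") = Rcpp::IntegerVector::create(P[s].n_rows, P[s].n_cols,
                                                P[s].n_slices);
    out[s] = a;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_unet_loss(SEXP ptr, List images, List masks, double lambda,
                     NumericVector class_weights) {
  XPtr<UNet> n(ptr);
  Batch Xs = batch_from_list(images);
  std::vector<imat> Ys = masks_from_list(masks, n->nclass);
  NetCache C;
  Batch logits = net_forward(*n, Xs, C, true, false);
  return loss_and_grad(logits, Ys, lambda,
                       Rcpp::as<vec>(class_weights), n->nclass, nullptr);
}

// analytic gradients without updating parameters (finite-difference checks)
// [[Rcpp::export]]
List cpp_unet_backward(SEXP ptr, List images, List masks, double lambda,
                       NumericVector class_weights) {
  XPtr<UNet> n(ptr);
  Batch Xs = batch_from_list(images);
  std::vector<imat> Ys = masks_from_list(masks, n->nclass);
  NetCache C;
  Batch logits = net_forward(*n, Xs, C, true, false);
  Batch dlogits;
  zero_grads(*n);
  double loss = loss_and_grad(logits, Ys, lambda,
                              Rcpp::as<vec>(class_weights), n->nclass,
                              &dlogits);
  net_backward(*n, dlogits, C);
  List convs(15), ups(3);
  for (int l = 0; l < 15; ++l)
    convs[l] = List::create(
      Rcpp::Named("dW") = Rcpp::wrap(conv_to<mat>::from(n->cb[l].dW)),
      Rcpp::Named("db") = Rcpp::wrap(conv_to<vec>::from(n->cb[l].db)),
      Rcpp::Named("dgamma") = Rcpp::wrap(conv_to<vec>::from(n->cb[l].dg)),
      Rcpp::Named("dbeta") = Rcpp::wrap(conv_to<vec>::from(n->cb[l].dbb)));
  for (int u = 0; u < 3; ++u)
    ups[u] = List::create(
      Rcpp::Named("dW") = Rcpp::wrap(conv_to<mat>::from(n->up[u].dW)),
      Rcpp::Named("db") = Rcpp::wrap(conv_to<vec>::from(n->up[u].db)));
  return List::create(Rcpp::Named("loss") = loss,
                      Rcpp::Named("conv") = convs,
                      Rcpp::Named("up") = ups);
}

// [[Rcpp::export]]
double cpp_unet_train_batch(SEXP ptr, List images, List masks, double lambda,
                            NumericVector class_weights, double lr) {
  XPtr<UNet> n(ptr);
  Batch Xs = batch_from_list(images);
  std::vector<imat> Ys = masks_from_list(masks, n->nclass);
  NetCache C;
  Batch logits = net_forward(*n, Xs, C, true, true);
  Batch dlogits;
  zero_grads(*n);
  double loss = loss_and_grad(logits, Ys, lambda,
                              Rcpp::as<vec>(class_weights), n->nclass, &dlogits);
  if (!std::isfinite(loss)) stop("non-finite training loss");
  net_backward(*n, dlogits, C);
  adam_step(*n, lr);
  return loss;
}

// [[Rcpp::export]]
List cpp_unet_get_weights(SEXP ptr) {
  XPtr<UNet> n(ptr);
  List convs(15), ups(3);
  for (int l = 0; l < 15; ++l) {
    ConvBlock& L = n->cb[l];
    convs[l] = List::create(
      Rcpp::Named("W") = Rcpp::wrap(conv_to<mat>::from(L.W)),
      Rcpp::Named("b") = Rcpp::wrap(conv_to<vec>::from(L.b)),
      Rcpp::Named("gamma") = Rcpp::wrap(conv_to<vec>::from(L.g)),
      Rcpp::Named("beta") = Rcpp::wrap(conv_to<vec>::from(L.bb)),
      Rcpp::Named("running_mean") = Rcpp::wrap(conv_to<vec>::from(L.rm)),
      Rcpp::Named("running_var") = Rcpp::wrap(conv_to<vec>::from(L.rv)));
  }
  for (int u = 0; u < 3; ++u)
    ups[u] = List::create(
      Rcpp::Named("W") = Rcpp::wrap(conv_to<mat>::from(n->up[u].W)),
      Rcpp::Named("b") = Rcpp::wrap(conv_to<vec>::from(n->up[u].b)));
  return List::create(Rcpp::Named("base_filters") = n->F,
                      Rcpp::Named("n_classes") = n->nclass,
                      Rcpp::Named("conv") = convs,
                      Rcpp::Named("up") = ups);
}

// [[Rcpp::export]]
void cpp_unet_set_weights(SEXP ptr, List w) {
  XPtr<UNet> n(ptr);
  List convs = w["conv"], ups = w["up"];
  if (convs.size() != 15 || ups.size() != 3)
    stop("weight list does not match the network topology");
  for (int l = 0; l < 15; ++l) {
    List Lw = convs[l];
    ConvBlock& L = n->cb[l];
    fmat W = conv_to<fmat>::from(Rcpp::as<mat>(Lw["W"]));
    if (W.n_rows != L.W.n_rows || W.n_cols != L.W.n_cols)
      stop("conv weight %d has wrong shape", l + 1);
    L.W = W;
    L.b = conv_to<fvec>::from(Rcpp::as<vec>(Lw["b"]));
    L.g = conv_to<fvec>::from(Rcpp::as<vec>(Lw["gamma"]));
    L.bb = conv_to<fvec>::from(Rcpp::as<vec>(Lw["beta"]));
    L.rm = conv_to<fvec>::from(Rcpp::as<vec>(Lw["running_mean"]));
    L.rv = conv_to<fvec>::from(Rcpp::as<vec>(Lw["running_var"]));
  }
  for (int u = 0; u < 3; ++u) {
    List Uw = ups[u];
    fmat W = conv_to<fmat>::from(Rcpp::as<mat>(Uw["W"]));
    if (W.n_rows != n->up[u].W.n_rows || W.n_cols != n->up[u].W.n_cols)
      stop("transposed-conv weight %d has wrong shape", u + 1);
    n->up[u].W = W;
    n->up[u].b = conv_to<fvec>::from(Rcpp::as<vec>(Uw["b"]));
  }
}
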