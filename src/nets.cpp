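// Small CPU-scale reference backbones behind the trainer contract:
//  - residual CNN for binary L3-slice detection (stem + 2 residual blocks,
//    identity shortcuts, global average pooling, softmax head);
//  - 3-level U-Net (3x3 convolutions, max-pooling, nearest-neighbour
//    upsampling, skip connections) for 5-class tissue segmentation.
// Training is plain SGD with momentum, L2 weight decay, global
// gradient-norm clipping and per-class weighted cross-entropy, so that
// every hyperparameter design variable is consumed. All randomness
// (weight init, minibatch shuffling) comes from one std::mt19937 seeded
// per fit, making training bit-reproducible for a fixed seed.
//
// Activation layout: single-precision matrix with n_rows = channels and
// n_cols = batch * H * W; pixel (i, j) of image b sits in column
// b*H*W + j*H + i (column-major, matching R matrices). Convolutions use
// im2col + GEMM; single precision keeps the loops memory-lean on one CPU.

#include <RcppArmadillo.h>
#include <random>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

typedef arma::fmat FM;
typedef arma::fvec FV;

static const float WCE_EPS = 1e-12f;

// ---------- im2col / col2im for 3x3 same-padding convolution ----------

static void im2col3(const FM& X, int H, int W, int B, FM& col) {
  const int C = X.n_rows, HW = H * W;
  col.zeros(9 * C, (arma::uword)B * HW);
  const float* xp = X.memptr();
  float* cp = col.memptr();
  const size_t xld = C, cld = 9 * (size_t)C;
  int k = 0;
  for (int dj = -1; dj <= 1; ++dj)
    for (int di = -1; di <= 1; ++di, ++k)
      for (int b = 0; b < B; ++b)
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          const float* src = xp + ((size_t)b * HW + (size_t)js * H + i0 + di) * xld;
          float* dst = cp + ((size_t)b * HW + (size_t)j * H + i0) * cld + (size_t)k * C;
          for (int i = i0; i < i1; ++i) {
            std::memcpy(dst, src, C * sizeof(float));
            src += xld; dst += cld;
          }
        }
}

static void col2im3(const FM& col, int H, int W, int B, int C, FM& X) {
  const int HW = H * W;
  X.zeros(C, (arma::uword)B * HW);
  float* xp = X.memptr();
  const float* cp = col.memptr();
  const size_t xld = C, cld = 9 * (size_t)C;
  int k = 0;
  for (int dj = -1; dj <= 1; ++dj)
    for (int di = -1; di <= 1; ++di, ++k)
      for (int b = 0; b < B; ++b)
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          float* dst = xp + ((size_t)b * HW + (size_t)js * H + i0 + di) * xld;
          const float* src = cp + ((size_t)b * HW + (size_t)j * H + i0) * cld + (size_t)k * C;
          for (int i = i0; i < i1; ++i) {
            for (int c = 0; c < C; ++c) dst[c] += src[c];
            src += cld; dst += xld;
          }
        }
}

// ---------- layers ----------

struct Conv {  // 3x3 same-padding (ksq = 9) or 1x1 (ksq = 1)
  FM W, vW, gW, col;
  FV b, vb, gb;
  int Cin = 0, Cout = 0, ksq = 9;

  void init(int cin, int cout, int ks, std::mt19937& rng) {
    Cin = cin; Cout = cout; ksq = ks;
    std::normal_distribution<double> nd(0.0, std::sqrt(2.0 / (cin * ks)));
    W.set_size(cout, cin * ks);
    for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = (float)nd(rng);
    b.set_size(cout); b.fill(0.01f);  // small positive bias avoids dead ReLU
    vW.zeros(arma::size(W)); vb.zeros(cout);
  }
  FM fwd(const FM& X, int H, int Wd, int B) {
    if (ksq == 9) im2col3(X, H, Wd, B, col); else col = X;
    FM Y = W * col;
    Y.each_col() += b;
    return Y;
  }
  FM bwd(const FM& dY, int H, int Wd, int B, bool need_dx = true) {
    gW = dY * col.t();
    gb = arma::sum(dY, 1);
    if (!need_dx) return FM();
    FM dcol = W.t() * dY;
    if (ksq == 1) return dcol;
    FM dX;
    col2im3(dcol, H, Wd, B, Cin, dX);
    return dX;
  }
};

struct Dense {
  FM W, vW, gW, in;
  FV b, vb, gb;
  void init(int cin, int cout, std::mt19937& rng) {
    std::normal_distribution<double> nd(0.0, std::sqrt(2.0 / cin));
    W.set_size(cout, cin);
    for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = (float)nd(rng);
    b.zeros(cout);  // softmax head stays unbiased
    vW.zeros(arma::size(W)); vb.zeros(cout);
  }
  FM fwd(const FM& X) { in = X; FM Y = W * X; Y.each_col() += b; return Y; }
  FM bwd(const FM& dY) {
    gW = dY * in.t(); gb = arma::sum(dY, 1);
    return W.t() * dY;
  }
};

static void maxpool2(const FM& X, int H, int W, int B,
                     FM& Y, arma::umat& idx) {
  const int C = X.n_rows, Ho = H / 2, Wo = W / 2;
  Y.set_size(C, (arma::uword)B * Ho * Wo);
  idx.set_size(C, Y.n_cols);
  const float* xp = X.memptr();
  float* yp = Y.memptr();
  arma::uword* ip = idx.memptr();
  for (int b = 0; b < B; ++b)
    for (int jo = 0; jo < Wo; ++jo)
      for (int io = 0; io < Ho; ++io) {
        const size_t oc = (size_t)b * Ho * Wo + (size_t)jo * Ho + io;
        const size_t c00 = (size_t)b * H * W + (size_t)(2 * jo) * H + 2 * io;
        const size_t cand[4] = {c00, c00 + 1, c00 + H, c00 + H + 1};
        for (int c = 0; c < C; ++c) {
          float best = xp[cand[0] * C + c]; size_t bi = cand[0];
          for (int t = 1; t < 4; ++t) {
            const float v = xp[cand[t] * C + c];
            if (v > best) { best = v; bi = cand[t]; }
          }
          yp[oc * C + c] = best;
          ip[oc * C + c] = bi;
        }
      }
}

static FM maxpool2_back(const FM& dY, const arma::umat& idx,
                        int H, int W, int B) {
  FM dX(dY.n_rows, (arma::uword)B * H * W, arma::fill::zeros);
  const int C = dY.n_rows;
  const float* dp = dY.memptr();
  const arma::uword* ip = idx.memptr();
  float* xp = dX.memptr();
  for (arma::uword oc = 0; oc < dY.n_cols; ++oc)
    for (int c = 0; c < C; ++c)
      xp[ip[oc * C + c] * C + c] += dp[oc * C + c];
  return dX;
}

static FM up2(const FM& X, int H, int W, int B) {
  const int C = X.n_rows, Ho = 2 * H, Wo = 2 * W;
  FM Y(C, (arma::uword)B * Ho * Wo);
  const float* xp = X.memptr();
  float* yp = Y.memptr();
  for (int b = 0; b < B; ++b)
    for (int jo = 0; jo < Wo; ++jo)
      for (int io = 0; io < Ho; ++io)
        std::memcpy(yp + ((size_t)b * Ho * Wo + (size_t)jo * Ho + io) * C,
                    xp + ((size_t)b * H * W + (size_t)(jo / 2) * H + io / 2) * C,
                    C * sizeof(float));
  return Y;
}

static FM up2_back(const FM& dY, int H, int W, int B) {
  // H, W are the (small) input dims; dY lives at 2H x 2W
  const int C = dY.n_rows, Ho = 2 * H, Wo = 2 * W;
  FM dX(C, (arma::uword)B * H * W, arma::fill::zeros);
  const float* dp = dY.memptr();
  float* xp = dX.memptr();
  for (int b = 0; b < B; ++b)
    for (int jo = 0; jo < Wo; ++jo)
      for (int io = 0; io < Ho; ++io) {
        float* dst = xp + ((size_t)b * H * W + (size_t)(jo / 2) * H + io / 2) * C;
        const float* src = dp + ((size_t)b * Ho * Wo + (size_t)jo * Ho + io) * C;
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
  return dX;
}

// leaky ReLU (slope 0.1): keeps gradient flow alive in the very narrow
// networks used at CPU scale, where hard ReLUs can die at initialisation
static const float LRELU = 0.1f;
static inline void relu_(FM& X) {
  float* p = X.memptr();
  for (arma::uword i = 0; i < X.n_elem; ++i) if (p[i] < 0) p[i] *= LRELU;
}
static inline void relu_back_(FM& dX, const FM& A) {
  float* d = dX.memptr();
  const float* a = A.memptr();
  for (arma::uword i = 0; i < dX.n_elem; ++i) if (a[i] <= 0) d[i] *= LRELU;
}

// softmax over columns + weighted cross-entropy; fills P and dlogits
static double softmax_wce(const FM& logits, const arma::ivec& y,
                          const FV& w, FM& P, FM& dL) {
  P = logits;
  P.each_row() -= arma::max(logits, 0);
  P = arma::exp(P);
  arma::frowvec s = arma::sum(P, 0);
  P.each_row() /= s;
  const arma::uword M = logits.n_cols;
  double loss = 0.0;
  dL = P;
  for (arma::uword m = 0; m < M; ++m) {
    const int k = y(m);
    const float wk = w(k);
    loss += -(double)wk * std::log(std::max(P(k, m), WCE_EPS));
    dL.col(m) *= wk;
    dL(k, m) -= wk;
  }
  loss /= M;
  dL /= (float)M;
  return loss;
}

// ---------- SGD with momentum, weight decay, global-norm clipping ----------

struct Hyper {
  double lr, l2, clip, momentum;
  int batch, epochs;
};

static Hyper read_hyper(const List& design) {
  Hyper h;
  h.lr = as<double>(design["initial_learning_rate"]);
  h.l2 = as<double>(design["l2_regularization"]);
  h.batch = as<int>(design["batch_size"]);
  h.clip = as<double>(design["gradient_threshold"]);
  h.epochs = as<int>(design["epochs"]);
  h.momentum = as<double>(design["momentum"]);
  if (h.lr <= 0 || h.batch < 1 || h.epochs < 1 || h.clip <= 0)
    stop("invalid hyperparameter design");
  return h;
}

struct ParamRef { FM* W; FM* g; FM* v; bool decay; };

static double sgd_step(std::vector<ParamRef>& ps,
                       std::vector<FV*>& bs, std::vector<FV*>& gbs,
                       std::vector<FV*>& vbs, const Hyper& h) {
  double g2 = 0.0;
  for (auto& p : ps) g2 += arma::accu(arma::square(arma::conv_to<arma::mat>::from(*p.g)));
  for (auto* g : gbs) g2 += arma::accu(arma::square(arma::conv_to<arma::vec>::from(*g)));
  const double gn = std::sqrt(g2);
  const float scale = (gn > h.clip && gn > 0) ? (float)(h.clip / gn) : 1.0f;
  const float lr = (float)h.lr, l2 = (float)h.l2, mom = (float)h.momentum;
  for (auto& p : ps) {
    FM g = (*p.g) * scale;
    if (p.decay) g += l2 * (*p.W);
    *p.v = mom * (*p.v) - lr * g;
    *p.W += *p.v;
  }
  for (size_t t = 0; t < bs.size(); ++t) {
    FV g = (*gbs[t]) * scale;
    *vbs[t] = mom * (*vbs[t]) - lr * g;
    *bs[t] += *vbs[t];
  }
  return std::min(gn, h.clip);  // post-clip global norm
}

// copy selected image slices (double cube) into the batched float layout
static FM gather_images(const arma::cube& imgs, const std::vector<int>& idx) {
  const int HW = imgs.n_rows * imgs.n_cols, B = (int)idx.size();
  FM X(1, (arma::uword)B * HW);
  float* xp = X.memptr();
  for (int b = 0; b < B; ++b) {
    const double* sp = imgs.slice(idx[b]).memptr();
    for (int p = 0; p < HW; ++p) xp[(size_t)b * HW + p] = (float)sp[p];
  }
  return X;
}

// ---------- detection network ----------

struct DetNet {
  Conv c1, c2, c3, c4, c5;
  Dense d;
  int C, S;
  FM A1, A2, A3, P, B1, B2, G;
  arma::umat pidx;

  void init(int channels, int size, std::mt19937& rng) {
    C = channels; S = size;
    c1.init(1, C, 9, rng);
    c2.init(C, C, 9, rng); c3.init(C, C, 9, rng);
    c4.init(C, C, 9, rng); c5.init(C, C, 9, rng);
    d.init(C, 2, rng);
  }

  FM forward(const FM& X, int B) {
    const int S2 = S / 2, HW2 = S2 * S2;
    A1 = c1.fwd(X, S, S, B); relu_(A1);
    A2 = c2.fwd(A1, S, S, B); relu_(A2);
    A3 = c3.fwd(A2, S, S, B); A3 += A1; relu_(A3);
    maxpool2(A3, S, S, B, P, pidx);
    B1 = c4.fwd(P, S2, S2, B); relu_(B1);
    B2 = c5.fwd(B1, S2, S2, B); B2 += P; relu_(B2);
    G.set_size(C, B);
    for (int b = 0; b < B; ++b)
      G.col(b) = arma::mean(B2.cols((arma::uword)b * HW2,
                                    (arma::uword)(b + 1) * HW2 - 1), 1);
    return d.fwd(G);
  }

  void backward(const FM& dlogits, int B) {
    const int S2 = S / 2, HW2 = S2 * S2;
    FM dG = d.bwd(dlogits);
    FM dB2(C, (arma::uword)B * HW2);
    for (int b = 0; b < B; ++b)
      dB2.cols((arma::uword)b * HW2, (arma::uword)(b + 1) * HW2 - 1) =
        arma::repmat(dG.col(b) / (float)HW2, 1, HW2);
    relu_back_(dB2, B2);
    FM dB1 = c5.bwd(dB2, S2, S2, B);
    relu_back_(dB1, B1);
    FM dP = c4.bwd(dB1, S2, S2, B) + dB2;  // skip connection
    FM dA3 = maxpool2_back(dP, pidx, S, S, B);
    relu_back_(dA3, A3);
    FM dA2 = c3.bwd(dA3, S, S, B);
    relu_back_(dA2, A2);
    FM dA1 = c2.bwd(dA2, S, S, B) + dA3;   // skip connection
    relu_back_(dA1, A1);
    c1.bwd(dA1, S, S, B, false);
  }

  void collect(std::vector<ParamRef>& ps, std::vector<FV*>& bs,
               std::vector<FV*>& gbs, std::vector<FV*>& vbs) {
    Conv* cs[5] = {&c1, &c2, &c3, &c4, &c5};
    for (auto* c : cs) {
      ps.push_back({&c->W, &c->gW, &c->vW, true});
      bs.push_back(&c->b); gbs.push_back(&c->gb); vbs.push_back(&c->vb);
    }
    ps.push_back({&d.W, &d.gW, &d.vW, true});
    bs.push_back(&d.b); gbs.push_back(&d.gb); vbs.push_back(&d.vb);
  }
};

static arma::mat f2d(const FM& X) { return arma::conv_to<arma::mat>::from(X); }
static arma::vec f2d(const FV& x) { return arma::conv_to<arma::vec>::from(x); }
static FM d2f(const arma::mat& X) { return arma::conv_to<FM>::from(X); }
static FV d2f(const arma::vec& x) { return arma::conv_to<FV>::from(x); }

static List det_to_list(const DetNet& net) {
  return List::create(
    _["arch"] = "res_detect", _["channels"] = net.C, _["input_size"] = net.S,
    _["c1W"] = f2d(net.c1.W), _["c1b"] = f2d(net.c1.b),
    _["c2W"] = f2d(net.c2.W), _["c2b"] = f2d(net.c2.b),
    _["c3W"] = f2d(net.c3.W), _["c3b"] = f2d(net.c3.b),
    _["c4W"] = f2d(net.c4.W), _["c4b"] = f2d(net.c4.b),
    _["c5W"] = f2d(net.c5.W), _["c5b"] = f2d(net.c5.b),
    _["dW"] = f2d(net.d.W), _["db"] = f2d(net.d.b));
}

static void det_from_list(const List& m, DetNet& net) {
  net.C = as<int>(m["channels"]); net.S = as<int>(m["input_size"]);
  Conv* cs[5] = {&net.c1, &net.c2, &net.c3, &net.c4, &net.c5};
  const char* wn[5] = {"c1W", "c2W", "c3W", "c4W", "c5W"};
  const char* bn[5] = {"c1b", "c2b", "c3b", "c4b", "c5b"};
  const int cins[5] = {1, net.C, net.C, net.C, net.C};
  for (int t = 0; t < 5; ++t) {
    cs[t]->W = d2f(as<arma::mat>(m[wn[t]]));
    cs[t]->b = d2f(as<arma::vec>(m[bn[t]]));
    cs[t]->Cin = cins[t]; cs[t]->ksq = 9;
  }
  net.d.W = d2f(as<arma::mat>(m["dW"]));
  net.d.b = d2f(as<arma::vec>(m["db"]));
}

// [[Rcpp::export(rng = false)]]
List cpp_det_fit(const arma::cube& images, const arma::ivec& labels,
                 const List& design, const arma::vec& class_weights,
                 int channels, int seed) {
  const int N = images.n_slices, S = images.n_rows;
  if ((int)images.n_cols != S) stop("images must be square");
  if (S % 2 != 0) stop("input size must be even");
  if ((int)labels.n_elem != N) stop("labels/images length mismatch");
  const Hyper h = read_hyper(design);
  std::mt19937 rng((unsigned)seed);
  DetNet net;
  net.init(channels, S, rng);

  std::vector<ParamRef> ps; std::vector<FV*> bs, gbs, vbs;
  net.collect(ps, bs, gbs, vbs);
  const FV w = d2f(class_weights);

  const int bsz = std::min(h.batch, N);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  std::vector<double> grad_norms, losses;
  FM Pm, dL;

  for (int e = 0; e < h.epochs; ++e) {
    std::shuffle(order.begin(), order.end(), rng);
    for (int s0 = 0; s0 < N; s0 += bsz) {
      const int s1 = std::min(N, s0 + bsz);
      std::vector<int> idx(order.begin() + s0, order.begin() + s1);
      FM X = gather_images(images, idx);
      FM logits = net.forward(X, (int)idx.size());
      arma::ivec y((int)idx.size());
      for (size_t b = 0; b < idx.size(); ++b) y(b) = labels(idx[b]);
      losses.push_back(softmax_wce(logits, y, w, Pm, dL));
      net.backward(dL, (int)idx.size());
      grad_norms.push_back(sgd_step(ps, bs, gbs, vbs, h));
    }
  }

  List model = det_to_list(net);
  model["grad_norms"] = grad_norms;
  model["losses"] = losses;
  model["n_steps"] = (int)grad_norms.size();
  model["seed"] = seed;
  return model;
}

// [[Rcpp::export(rng = false)]]
arma::mat cpp_det_predict(const List& model, const arma::cube& images) {
  DetNet net;
  det_from_list(model, net);
  const int N = images.n_slices;
  arma::mat out(N, 2);
  const int chunk = 256;
  for (int s0 = 0; s0 < N; s0 += chunk) {
    const int s1 = std::min(N, s0 + chunk);
    std::vector<int> idx;
    for (int i = s0; i < s1; ++i) idx.push_back(i);
    FM logits = net.forward(gather_images(images, idx), (int)idx.size());
    logits.each_row() -= arma::max(logits, 0);
    FM P = arma::exp(logits);
    arma::frowvec s = arma::sum(P, 0);
    P.each_row() /= s;
    out.rows(s0, s1 - 1) = f2d(P).t();
  }
  return out;
}

// ---------- U-Net ----------

struct UNet {
  Conv c1, c2, c3, c4, c5, c6;
  int C, S, K;
  FM E1, E2, M, D2, D1, P1, P2;
  arma::umat idx1, idx2;

  void init(int channels, int size, int n_classes, std::mt19937& rng) {
    C = channels; S = size; K = n_classes;
    c1.init(1, C, 9, rng);
    c2.init(C, 2 * C, 9, rng);
    c3.init(2 * C, 4 * C, 9, rng);
    c4.init(6 * C, 2 * C, 9, rng);
    c5.init(3 * C, C, 9, rng);
    c6.init(C, K, 1, rng);
  }

  FM forward(const FM& X, int B) {
    const int S2 = S / 2, S4 = S / 4;
    E1 = c1.fwd(X, S, S, B); relu_(E1);
    maxpool2(E1, S, S, B, P1, idx1);
    E2 = c2.fwd(P1, S2, S2, B); relu_(E2);
    maxpool2(E2, S2, S2, B, P2, idx2);
    M = c3.fwd(P2, S4, S4, B); relu_(M);
    FM K2 = arma::join_cols(up2(M, S4, S4, B), E2);
    D2 = c4.fwd(K2, S2, S2, B); relu_(D2);
    FM K1 = arma::join_cols(up2(D2, S2, S2, B), E1);
    D1 = c5.fwd(K1, S, S, B); relu_(D1);
    return c6.fwd(D1, S, S, B);
  }

  void backward(const FM& dlogits, int B) {
    const int S2 = S / 2, S4 = S / 4;
    FM dD1 = c6.bwd(dlogits, S, S, B);
    relu_back_(dD1, D1);
    FM dK1 = c5.bwd(dD1, S, S, B);
    FM dU1 = dK1.rows(0, 2 * C - 1);
    FM dE1 = dK1.rows(2 * C, 3 * C - 1);
    FM dD2 = up2_back(dU1, S2, S2, B);
    relu_back_(dD2, D2);
    FM dK2 = c4.bwd(dD2, S2, S2, B);
    FM dU2 = dK2.rows(0, 4 * C - 1);
    FM dE2 = dK2.rows(4 * C, 6 * C - 1);
    FM dM = up2_back(dU2, S4, S4, B);
    relu_back_(dM, M);
    dE2 += maxpool2_back(c3.bwd(dM, S4, S4, B), idx2, S2, S2, B);
    relu_back_(dE2, E2);
    dE1 += maxpool2_back(c2.bwd(dE2, S2, S2, B), idx1, S, S, B);
    relu_back_(dE1, E1);
    c1.bwd(dE1, S, S, B, false);
  }

  void collect(std::vector<ParamRef>& ps, std::vector<FV*>& bs,
               std::vector<FV*>& gbs, std::vector<FV*>& vbs) {
    Conv* cs[6] = {&c1, &c2, &c3, &c4, &c5, &c6};
    for (auto* c : cs) {
      ps.push_back({&c->W, &c->gW, &c->vW, true});
      bs.push_back(&c->b); gbs.push_back(&c->gb); vbs.push_back(&c->vb);
    }
  }
};

static List unet_to_list(const UNet& net) {
  return List::create(
    _["arch"] = "unet", _["channels"] = net.C, _["input_size"] = net.S,
    _["n_classes"] = net.K,
    _["c1W"] = f2d(net.c1.W), _["c1b"] = f2d(net.c1.b),
    _["c2W"] = f2d(net.c2.W), _["c2b"] = f2d(net.c2.b),
    _["c3W"] = f2d(net.c3.W), _["c3b"] = f2d(net.c3.b),
    _["c4W"] = f2d(net.c4.W), _["c4b"] = f2d(net.c4.b),
    _["c5W"] = f2d(net.c5.W), _["c5b"] = f2d(net.c5.b),
    _["c6W"] = f2d(net.c6.W), _["c6b"] = f2d(net.c6.b));
}

static void unet_from_list(const List& m, UNet& net) {
  net.C = as<int>(m["channels"]); net.S = as<int>(m["input_size"]);
  net.K = as<int>(m["n_classes"]);
  Conv* cs[6] = {&net.c1, &net.c2, &net.c3, &net.c4, &net.c5, &net.c6};
  const char* wn[6] = {"c1W", "c2W", "c3W", "c4W", "c5W", "c6W"};
  const char* bn[6] = {"c1b", "c2b", "c3b", "c4b", "c5b", "c6b"};
  const int cins[6] = {1, net.C, 2 * net.C, 6 * net.C, 3 * net.C, net.C};
  for (int t = 0; t < 6; ++t) {
    cs[t]->W = d2f(as<arma::mat>(m[wn[t]]));
    cs[t]->b = d2f(as<arma::vec>(m[bn[t]]));
    cs[t]->Cin = cins[t];
    cs[t]->ksq = (t == 5) ? 1 : 9;
  }
}

// [[Rcpp::export(rng = false)]]
List cpp_unet_fit(const arma::cube& images, const arma::cube& masks,
                  const List& design, const arma::vec& class_weights,
                  int channels, int n_classes, int seed) {
  const int N = images.n_slices, S = images.n_rows, HW = S * S;
  if ((int)images.n_cols != S) stop("images must be square");
  if (S % 4 != 0) stop("input size must be divisible by 4");
  if (masks.n_slices != images.n_slices || (int)masks.n_rows != S)
    stop("masks/images shape mismatch");
  const Hyper h = read_hyper(design);
  std::mt19937 rng((unsigned)seed);
  UNet net;
  net.init(channels, S, n_classes, rng);

  std::vector<ParamRef> ps; std::vector<FV*> bs, gbs, vbs;
  net.collect(ps, bs, gbs, vbs);
  const FV w = d2f(class_weights);

  const int bsz = std::min(h.batch, N);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  std::vector<double> grad_norms, losses;
  FM Pm, dL;

  for (int e = 0; e < h.epochs; ++e) {
    std::shuffle(order.begin(), order.end(), rng);
    for (int s0 = 0; s0 < N; s0 += bsz) {
      const int s1 = std::min(N, s0 + bsz);
      std::vector<int> idx(order.begin() + s0, order.begin() + s1);
      const int B = (int)idx.size();
      FM X = gather_images(images, idx);
      FM logits = net.forward(X, B);
      arma::ivec y((arma::uword)B * HW);
      for (int b = 0; b < B; ++b) {
        const double* mk = masks.slice(idx[b]).memptr();
        for (int p = 0; p < HW; ++p) y((arma::uword)b * HW + p) = (int)mk[p];
      }
      losses.push_back(softmax_wce(logits, y, w, Pm, dL));
      net.backward(dL, B);
      grad_norms.push_back(sgd_step(ps, bs, gbs, vbs, h));
    }
  }

  List model = unet_to_list(net);
  model["grad_norms"] = grad_norms;
  model["losses"] = losses;
  model["n_steps"] = (int)grad_norms.size();
  model["seed"] = seed;
  return model;
}

// [[Rcpp::export(rng = false)]]
arma::cube cpp_unet_predict(const List& model, const arma::cube& images) {
  UNet net;
  unet_from_list(model, net);
  const int N = images.n_slices, S = images.n_rows, HW = S * S;
  arma::cube out(S, S, (arma::uword)net.K * N);  // slice K*(n-1)+k per image
  const int chunk = 32;
  for (int s0 = 0; s0 < N; s0 += chunk) {
    const int s1 = std::min(N, s0 + chunk);
    std::vector<int> idx;
    for (int i = s0; i < s1; ++i) idx.push_back(i);
    FM logits = net.forward(gather_images(images, idx), (int)idx.size());
    logits.each_row() -= arma::max(logits, 0);
    FM P = arma::exp(logits);
    arma::frowvec s = arma::sum(P, 0);
    P.each_row() /= s;
    for (size_t b = 0; b < idx.size(); ++b)
      for (int k = 0; k < net.K; ++k) {
        double* op = out.slice((arma::uword)net.K * idx[b] + k).memptr();
        const float* pp = P.memptr();
        for (int p = 0; p < HW; ++p)
          op[p] = (double)pp[((size_t)b * HW + p) * net.K + k];
      }
  }
  return out;
}
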