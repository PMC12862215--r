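// Compiled engine for the per-nucleotide TIS/TTS labeler.
//
// The network is a 1D dilated-residual convolutional stack operating on
// integer-encoded transcripts (0 = padding/N, 1..4 = A,C,G,T):
//   embedding -> local conv (k=3) + BN + ReLU
//     -> stage 1 (4 pre-activation residual blocks, k=26, dilation 1)
//     -> 1x1 expansion -> stage 2 (k=26, dilation 2)
//     -> 1x1 expansion -> stage 3 (k=36, dilation 5)
//   -> BN + ReLU -> 1x1 conv -> ReLU -> 1x1 conv -> 3-class logits.
//
// Forward, backward and the Adam update are implemented here in single
// precision; convolutions are evaluated as one GEMM per kernel tap so the
// heavy lifting stays inside BLAS.  All randomness (initial weights, batch
// order) is supplied from the R side; this file is deterministic.
//
// Activations are laid out channel-major as C x (B*L) matrices, sequence b
// occupying the contiguous column block [b*L, (b+1)*L).  "same" padding with
// even kernels splits the total pad d*(K-1) as floor half left, ceil half
// right, so output length always equals input length.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::fmat;
using arma::frowvec;
using arma::fvec;
using Rcpp::List;
using Rcpp::Named;

static const float BN_EPS = 1e-5f;
static const float BN_MOMENTUM = 0.1f;

// single-precision GEMM straight from BLAS; Armadillo's fmat products go
// through the same routine, but calling it directly lets the convolutions
// accumulate into column slices without temporaries
extern "C" void sgemm_(const char* transa, const char* transb, const int* m,
                       const int* n, const int* k, const float* alpha,
                       const float* a, const int* lda, const float* b,
                       const int* ldb, const float* beta, float* c,
                       const int* ldc);

static inline void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                         const float* A, int lda, const float* B, int ldb,
                         float beta, float* C, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

// zero the entries of d where the forward activation was clamped
static inline void relu_backward_(fmat& d, const fmat& a) {
  float* dp = d.memptr();
  const float* ap = a.memptr();
  const size_t n = d.n_elem;
  for (size_t i = 0; i < n; ++i)
    if (ap[i] <= 0.0f) dp[i] = 0.0f;
}

// ---------------------------------------------------------------------------
// parameter with Adam state
struct Param {
  fmat w, g, m, v;
  void init(int r, int c) {
    w.zeros(r, c); g.zeros(r, c); m.zeros(r, c); v.zeros(r, c);
  }
};

struct AdamState {
  long t = 0;
  float beta1 = 0.9f, beta2 = 0.999f, eps = 1e-8f;
};

static void adam_step(Param& p, const AdamState& st, float lr) {
  const float bc1 = 1.0f - std::pow(st.beta1, (float)st.t);
  const float bc2 = 1.0f - std::pow(st.beta2, (float)st.t);
  p.m = st.beta1 * p.m + (1.0f - st.beta1) * p.g;
  p.v = st.beta2 * p.v + (1.0f - st.beta2) * arma::square(p.g);
  p.w -= lr * (p.m / bc1) / (arma::sqrt(p.v / bc2) + st.eps);
}

// ---------------------------------------------------------------------------
// dilated 1D convolution, "same" length, optional bias
struct Conv1d {
  int c_in = 0, c_out = 0, K = 1, dil = 1, pad_left = 0;
  bool bias = false;
  Param W;  // c_out x (c_in * K), tap k in columns [k*c_in, (k+1)*c_in)
  Param b;  // c_out x 1

  void configure(int ci, int co, int k, int d, bool has_bias) {
    c_in = ci; c_out = co; K = k; dil = d; bias = has_bias;
    pad_left = (d * (k - 1)) / 2;
    W.init(co, ci * k);
    if (bias) b.init(co, 1);
  }

  void forward(const fmat& X, fmat& Y, int L, int B) const {
    Y.zeros(c_out, (size_t)L * B);
    for (int s = 0; s < B; ++s) {
      const int base = s * L;
      for (int k = 0; k < K; ++k) {
        const int o = k * dil - pad_left;
        const int t0 = std::max(0, -o);
        const int t1 = (L - 1) - std::max(0, o);
        if (t0 > t1) continue;
        // Y[, t0..t1] += W_k (c_out x c_in) * X[, t0+o..t1+o]
        sgemm('N', 'N', c_out, t1 - t0 + 1, c_in, 1.0f,
              W.w.memptr() + (size_t)k * c_in * c_out, c_out,
              X.memptr() + (size_t)(base + t0 + o) * c_in, c_in,
              1.0f, Y.memptr() + (size_t)(base + t0) * c_out, c_out);
      }
    }
    if (bias) Y.each_col() += b.w.col(0);
  }

  // accumulates into W.g / b.g; writes dX (overwrites)
  void backward(const fmat& X, const fmat& dY, fmat& dX, int L, int B) {
    dX.zeros(c_in, (size_t)L * B);
    for (int s = 0; s < B; ++s) {
      const int base = s * L;
      for (int k = 0; k < K; ++k) {
        const int o = k * dil - pad_left;
        const int t0 = std::max(0, -o);
        const int t1 = (L - 1) - std::max(0, o);
        if (t0 > t1) continue;
        const int width = t1 - t0 + 1;
        // dX[, t0+o..t1+o] += W_k' * dY[, t0..t1]
        sgemm('T', 'N', c_in, width, c_out, 1.0f,
              W.w.memptr() + (size_t)k * c_in * c_out, c_out,
              dY.memptr() + (size_t)(base + t0) * c_out, c_out,
              1.0f, dX.memptr() + (size_t)(base + t0 + o) * c_in, c_in);
        // dW_k += dY[, t0..t1] * X[, t0+o..t1+o]'
        sgemm('N', 'T', c_out, c_in, width, 1.0f,
              dY.memptr() + (size_t)(base + t0) * c_out, c_out,
              X.memptr() + (size_t)(base + t0 + o) * c_in, c_in,
              1.0f, W.g.memptr() + (size_t)k * c_in * c_out, c_out);
      }
    }
    if (bias) b.g += arma::sum(dY, 1);
  }
};

// ---------------------------------------------------------------------------
// batch normalization over all positions (padding included by design)
struct BatchNorm {
  int C = 0;
  Param gamma, beta;
  fvec run_mean, run_var;
  // caches for backward
  fmat xhat;
  fvec istd;
  // accumulators for post-training statistics re-estimation
  fvec acc_mean, acc_var;
  long acc_n = 0;
  bool calibrating = false;

  void configure(int c) {
    C = c;
    gamma.init(c, 1); gamma.w.ones();
    beta.init(c, 1);
    run_mean.zeros(c);
    run_var.ones(c);
  }

  void calib_begin() {
    acc_mean.zeros(C);
    acc_var.zeros(C);
    acc_n = 0;
    calibrating = true;
  }

  void calib_end() {
    if (acc_n > 0) {
      run_mean = acc_mean / acc_n;
      run_var = acc_var / acc_n;
    }
    calibrating = false;
  }

  void forward(const fmat& X, fmat& Y, bool train) {
    const size_t N = X.n_cols;
    if (train) {
      fvec mu = arma::mean(X, 1);
      fmat centered = X.each_col() - mu;
      fvec var = arma::mean(arma::square(centered), 1);  // biased
      istd = 1.0f / arma::sqrt(var + BN_EPS);
      xhat = centered.each_col() % istd;
      Y = xhat.each_col() % gamma.w.col(0);
      Y.each_col() += beta.w.col(0);
      const float unb = N > 1 ? (float)N / (float)(N - 1) : 1.0f;
      if (calibrating) {
        // plain average of per-batch statistics with the weights frozen
        acc_mean += mu;
        acc_var += var * unb;
        acc_n += 1;
      } else {
        run_mean = (1.0f - BN_MOMENTUM) * run_mean + BN_MOMENTUM * mu;
        run_var = (1.0f - BN_MOMENTUM) * run_var + BN_MOMENTUM * (var * unb);
      }
    } else {
      fvec is = 1.0f / arma::sqrt(run_var + BN_EPS);
      Y = (X.each_col() - run_mean).each_col() % (is % gamma.w.col(0));
      Y.each_col() += beta.w.col(0);
    }
  }

  // train-mode backward; uses caches from the last train forward
  void backward(const fmat& dY, fmat& dX) {
    const float N = (float)dY.n_cols;
    fvec dgamma = arma::sum(dY % xhat, 1);
    fvec dbeta = arma::sum(dY, 1);
    gamma.g += dgamma;
    beta.g += dbeta;
    dX = dY * N;
    dX -= xhat.each_col() % dgamma;
    dX.each_col() -= dbeta;
    dX.each_col() %= (gamma.w.col(0) % istd) / N;
  }
};

static inline void relu_(fmat& X) { X.transform([](float x) { return x > 0.0f ? x : 0.0f; }); }

// ---------------------------------------------------------------------------
// pre-activation residual block: BN-ReLU-conv-BN-ReLU-conv + identity
struct ResBlock {
  BatchNorm bn1, bn2;
  Conv1d conv1, conv2;
  // caches
  fmat x_in, a1, a2;

  void configure(int c, int k, int d) {
    bn1.configure(c); bn2.configure(c);
    conv1.configure(c, c, k, d, false);
    conv2.configure(c, c, k, d, false);
  }

  void forward(const fmat& X, fmat& Y, int L, int B, bool train) {
    fmat t;
    bn1.forward(X, t, train);
    relu_(t);
    if (train) { x_in = X; a1 = t; }
    fmat c1;
    conv1.forward(t, c1, L, B);
    bn2.forward(c1, t, train);
    relu_(t);
    if (train) a2 = t;
    conv2.forward(t, Y, L, B);
    Y += X;
  }

  void backward(const fmat& dY, fmat& dX, int L, int B) {
    fmat d2;
    conv2.backward(a2, dY, d2, L, B);
    relu_backward_(d2, a2);
    fmat d1;
    bn2.backward(d2, d1);
    fmat d0;
    conv1.backward(a1, d1, d0, L, B);
    relu_backward_(d0, a1);
    bn1.backward(d0, dX);
    dX += dY;  // identity skip
  }
};

// ---------------------------------------------------------------------------
struct NetConfig {
  int vocab = 5, emb_dim = 128;
  int local_channels = 32, local_kernel = 3;
  std::vector<int> stage_channels{32, 64, 128};
  std::vector<int> blocks{4, 4, 4};
  std::vector<int> kernels{26, 26, 36};
  std::vector<int> dilations{1, 2, 5};
  int head_channels = 32, n_classes = 3;
};

struct Net {
  NetConfig cfg;
  Param emb;  // emb_dim x vocab, column 0 pinned to zero
  Conv1d local;
  BatchNorm local_bn;
  std::vector<Conv1d> trans;           // one per stage, K=1 (unused if channels match)
  std::vector<bool> has_trans;
  std::vector<std::vector<ResBlock>> stages;
  BatchNorm final_bn;
  Conv1d head1, head2;
  AdamState adam;

  // caches for backward
  arma::imat tok_cache;
  fmat x_emb, a_local, a_head1, a_final;
  std::vector<fmat> stage_in;  // input to each stage's transition

  void configure(const NetConfig& c) {
    cfg = c;
    emb.init(c.emb_dim, c.vocab);
    local.configure(c.emb_dim, c.local_channels, c.local_kernel, 1, false);
    local_bn.configure(c.local_channels);
    int prev = c.local_channels;
    const int S = (int)c.stage_channels.size();
    trans.resize(S); has_trans.resize(S); stages.resize(S); stage_in.resize(S);
    for (int s = 0; s < S; ++s) {
      const int ch = c.stage_channels[s];
      has_trans[s] = (ch != prev);
      if (has_trans[s]) trans[s].configure(prev, ch, 1, 1, false);
      stages[s].resize(c.blocks[s]);
      for (int b = 0; b < c.blocks[s]; ++b)
        stages[s][b].configure(ch, c.kernels[s], c.dilations[s]);
      prev = ch;
    }
    final_bn.configure(prev);
    head1.configure(prev, c.head_channels, 1, 1, true);
    head2.configure(c.head_channels, c.n_classes, 1, 1, true);
  }

  template <typename F>
  void each_param(F f) {
    f("emb", emb);
    f("local.W", local.W);
    f("local_bn.gamma", local_bn.gamma);
    f("local_bn.beta", local_bn.beta);
    for (size_t s = 0; s < stages.size(); ++s) {
      const std::string p = "s" + std::to_string(s + 1);
      if (has_trans[s]) f((p + ".trans.W").c_str(), trans[s].W);
      for (size_t b = 0; b < stages[s].size(); ++b) {
        const std::string q = p + ".b" + std::to_string(b + 1);
        ResBlock& rb = stages[s][b];
        f((q + ".bn1.gamma").c_str(), rb.bn1.gamma);
        f((q + ".bn1.beta").c_str(), rb.bn1.beta);
        f((q + ".conv1.W").c_str(), rb.conv1.W);
        f((q + ".bn2.gamma").c_str(), rb.bn2.gamma);
        f((q + ".bn2.beta").c_str(), rb.bn2.beta);
        f((q + ".conv2.W").c_str(), rb.conv2.W);
      }
    }
    f("final_bn.gamma", final_bn.gamma);
    f("final_bn.beta", final_bn.beta);
    f("head1.W", head1.W);
    f("head1.b", head1.b);
    f("head2.W", head2.W);
    f("head2.b", head2.b);
  }

  template <typename F>
  void each_bn(F f) {
    f("local_bn", local_bn);
    for (size_t s = 0; s < stages.size(); ++s)
      for (size_t b = 0; b < stages[s].size(); ++b) {
        const std::string q = "s" + std::to_string(s + 1) + ".b" + std::to_string(b + 1);
        f((q + ".bn1").c_str(), stages[s][b].bn1);
        f((q + ".bn2").c_str(), stages[s][b].bn2);
      }
    f("final_bn", final_bn);
  }

  // tokens: L x B integer matrix in {0..vocab-1}
  void forward(const arma::imat& tokens, fmat& logits, bool train) {
    const int L = tokens.n_rows, B = tokens.n_cols;
    const size_t N = (size_t)L * B;
    fmat x(cfg.emb_dim, N);
    for (int s = 0; s < B; ++s)
      for (int t = 0; t < L; ++t) {
        const int tk = tokens(t, s);
        if (tk < 0 || tk >= cfg.vocab) Rcpp::stop("token out of range: %d", tk);
        x.col((size_t)s * L + t) = emb.w.col(tk);
      }
    if (train) { tok_cache = tokens; }
    fmat y;
    local.forward(x, y, L, B);
    if (train) x_emb = x;
    local_bn.forward(y, x, train);
    relu_(x);
    if (train) a_local = x;
    for (size_t s = 0; s < stages.size(); ++s) {
      if (has_trans[s]) {
        if (train) stage_in[s] = x;
        trans[s].forward(x, y, L, B);
        x = y;
      }
      for (auto& rb : stages[s]) {
        rb.forward(x, y, L, B, train);
        x = y;
      }
    }
    final_bn.forward(x, y, train);
    relu_(y);
    if (train) a_final = y;
    head1.forward(y, x, L, B);
    relu_(x);
    if (train) a_head1 = x;
    head2.forward(x, logits, L, B);
  }

  // dlogits -> parameter gradients (accumulated; call zero_grad first)
  void backward(const fmat& dlogits) {
    const int L = tok_cache.n_rows, B = tok_cache.n_cols;
    fmat dx, dy;
    head2.backward(a_head1, dlogits, dx, L, B);
    relu_backward_(dx, a_head1);
    head1.backward(a_final, dx, dy, L, B);
    relu_backward_(dy, a_final);
    final_bn.backward(dy, dx);
    for (int s = (int)stages.size() - 1; s >= 0; --s) {
      for (int b = (int)stages[s].size() - 1; b >= 0; --b) {
        stages[s][b].backward(dx, dy, L, B);
        dx = dy;
      }
      if (has_trans[s]) {
        trans[s].backward(stage_in[s], dx, dy, L, B);
        dx = dy;
      }
    }
    relu_backward_(dx, a_local);
    local_bn.backward(dx, dy);
    local.backward(x_emb, dy, dx, L, B);
    // scatter into the embedding gradient; padding row stays frozen
    for (int s = 0; s < B; ++s)
      for (int t = 0; t < L; ++t)
        emb.g.col(tok_cache(t, s)) += dx.col((size_t)s * L + t);
    emb.g.col(0).zeros();
  }

  void zero_grad() {
    each_param([](const char*, Param& p) { p.g.zeros(); });
  }

  void step(float lr) {
    adam.t += 1;
    each_param([&](const char*, Param& p) { adam_step(p, adam, lr); });
    emb.w.col(0).zeros();  // keep the padding embedding pinned at zero
  }
};

// ---------------------------------------------------------------------------
// masked softmax cross-entropy; labels in {0,1,2}, -1 = ignore
static double ce_loss_grad(const fmat& logits, const arma::imat& labels,
                           fmat* dlogits) {
  const int L = labels.n_rows, B = labels.n_cols;
  double loss = 0.0;
  long count = 0;
  if (dlogits) dlogits->zeros(logits.n_rows, logits.n_cols);
  fmat probs = logits;
  probs.each_row() -= arma::max(logits, 0);
  probs = arma::exp(probs);
  probs.each_row() /= arma::sum(probs, 0);
  for (int s = 0; s < B; ++s)
    for (int t = 0; t < L; ++t) {
      const int y = labels(t, s);
      if (y < 0) continue;
      const size_t j = (size_t)s * L + t;
      loss -= std::log(std::max(probs(y, j), 1e-12f));
      ++count;
      if (dlogits) {
        dlogits->col(j) = probs.col(j);
        (*dlogits)(y, j) -= 1.0f;
      }
    }
  if (count == 0) return 0.0;
  if (dlogits) *dlogits /= (float)count;
  return loss / count;
}

// ---------------------------------------------------------------------------
// R interface

static NetConfig config_from_list(const List& cl) {
  NetConfig c;
  c.vocab = cl["vocab_size"];
  c.emb_dim = cl["embedding_dim"];
  c.local_channels = cl["local_channels"];
  c.local_kernel = cl["local_kernel"];
  c.stage_channels = Rcpp::as<std::vector<int>>(cl["stage_channels"]);
  c.blocks = Rcpp::as<std::vector<int>>(cl["blocks_per_stage"]);
  c.kernels = Rcpp::as<std::vector<int>>(cl["stage_kernels"]);
  c.dilations = Rcpp::as<std::vector<int>>(cl["stage_dilations"]);
  c.head_channels = cl["head_channels"];
  c.n_classes = cl["n_classes"];
  if (c.stage_channels.size() != c.kernels.size() ||
      c.kernels.size() != c.dilations.size() ||
      c.blocks.size() != c.kernels.size())
    Rcpp::stop("stage_channels, blocks_per_stage, stage_kernels and stage_dilations must have equal length");
  return c;
}

// [[Rcpp::export(name = ".nn_param_shapes")]]
List nn_param_shapes(List config) {
  Net net;
  net.configure(config_from_list(config));
  std::vector<std::string> names;
  std::vector<Rcpp::IntegerVector> dims;
  net.each_param([&](const char* nm, Param& p) {
    names.push_back(nm);
    dims.push_back(Rcpp::IntegerVector::create((int)p.w.n_rows, (int)p.w.n_cols));
  });
  net.each_bn([&](const char* nm, BatchNorm& bn) {
    names.push_back(std::string(nm) + ".run_mean");
    dims.push_back(Rcpp::IntegerVector::create(bn.C, 1));
    names.push_back(std::string(nm) + ".run_var");
    dims.push_back(Rcpp::IntegerVector::create(bn.C, 1));
  });
  List out(dims.size());
  for (size_t i = 0; i < dims.size(); ++i) out[i] = dims[i];
  out.names() = names;
  return out;
}

static void set_params(Net& net, const List& params) {
  net.each_param([&](const char* nm, Param& p) {
    if (!params.containsElementNamed(nm)) Rcpp::stop("missing parameter '%s'", nm);
    Rcpp::NumericMatrix m = params[nm];
    if ((int)p.w.n_rows != m.nrow() || (int)p.w.n_cols != m.ncol())
      Rcpp::stop("parameter '%s' has wrong shape", nm);
    for (size_t j = 0; j < p.w.n_cols; ++j)
      for (size_t i = 0; i < p.w.n_rows; ++i)
        p.w(i, j) = (float)m(i, j);
  });
  net.each_bn([&](const char* nm, BatchNorm& bn) {
    const std::string rm = std::string(nm) + ".run_mean";
    const std::string rv = std::string(nm) + ".run_var";
    if (params.containsElementNamed(rm.c_str())) {
      Rcpp::NumericMatrix m = params[rm];
      for (int i = 0; i < bn.C; ++i) bn.run_mean(i) = (float)m(i, 0);
    }
    if (params.containsElementNamed(rv.c_str())) {
      Rcpp::NumericMatrix m = params[rv];
      for (int i = 0; i < bn.C; ++i) bn.run_var(i) = (float)m(i, 0);
    }
  });
  net.emb.w.col(0).zeros();
}

// [[Rcpp::export(name = ".nn_create")]]
SEXP nn_create(List config, List params) {
  Rcpp::XPtr<Net> ptr(new Net(), true);
  ptr->configure(config_from_list(config));
  set_params(*ptr, params);
  return ptr;
}

// [[Rcpp::export(name = ".nn_get_params")]]
List nn_get_params(SEXP handle) {
  Rcpp::XPtr<Net> net(handle);
  std::vector<std::string> names;
  std::vector<Rcpp::NumericMatrix> mats;
  net->each_param([&](const char* nm, Param& p) {
    Rcpp::NumericMatrix m(p.w.n_rows, p.w.n_cols);
    for (size_t j = 0; j < p.w.n_cols; ++j)
      for (size_t i = 0; i < p.w.n_rows; ++i) m(i, j) = p.w(i, j);
    names.push_back(nm);
    mats.push_back(m);
  });
  net->each_bn([&](const char* nm, BatchNorm& bn) {
    Rcpp::NumericMatrix rm(bn.C, 1), rv(bn.C, 1);
    for (int i = 0; i < bn.C; ++i) { rm(i, 0) = bn.run_mean(i); rv(i, 0) = bn.run_var(i); }
    names.push_back(std::string(nm) + ".run_mean"); mats.push_back(rm);
    names.push_back(std::string(nm) + ".run_var"); mats.push_back(rv);
  });
  List out(mats.size());
  for (size_t i = 0; i < mats.size(); ++i) out[i] = mats[i];
  out.names() = names;
  return out;
}

// [[Rcpp::export(name = ".nn_set_params")]]
void nn_set_params(SEXP handle, List params) {
  Rcpp::XPtr<Net> net(handle);
  set_params(*net, params);
}

static arma::imat tokens_from_R(const Rcpp::IntegerMatrix& m) {
  arma::imat t(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i) t(i, j) = m(i, j);
  return t;
}

// [[Rcpp::export(name = ".nn_forward")]]
Rcpp::NumericVector nn_forward(SEXP handle, Rcpp::IntegerMatrix tokens, bool train = false) {
  Rcpp::XPtr<Net> net(handle);
  arma::imat tok = tokens_from_R(tokens);
  fmat logits;
  net->forward(tok, logits, train);
  const int L = tokens.nrow(), B = tokens.ncol(), C = net->cfg.n_classes;
  Rcpp::NumericVector out(Rcpp::Dimension(C, L, B));
  for (int s = 0; s < B; ++s)
    for (int t = 0; t < L; ++t)
      for (int c = 0; c < C; ++c)
        out[(size_t)s * L * C + (size_t)t * C + c] = logits(c, (size_t)s * L + t);
  return out;
}

// one optimization pass over `order` (1-based sample indices, consumed in
// consecutive chunks of batch_size); returns position-weighted mean loss
// [[Rcpp::export(name = ".nn_train_epoch")]]
double nn_train_epoch(SEXP handle, Rcpp::IntegerMatrix tokens, Rcpp::IntegerMatrix labels,
                      Rcpp::IntegerVector order, int batch_size, double lr) {
  Rcpp::XPtr<Net> net(handle);
  const int L = tokens.nrow(), n = order.size();
  double total_loss = 0.0;
  long total_pos = 0;
  for (int start = 0; start < n; start += batch_size) {
    const int B = std::min(batch_size, n - start);
    arma::imat tok(L, B), lab(L, B);
    for (int s = 0; s < B; ++s) {
      const int idx = order[start + s] - 1;
      for (int t = 0; t < L; ++t) {
        tok(t, s) = tokens(t, idx);
        lab(t, s) = labels(t, idx);
      }
    }
    fmat logits;
    net->forward(tok, logits, true);
    fmat dlogits;
    const double loss = ce_loss_grad(logits, lab, &dlogits);
    if (!std::isfinite(loss)) Rcpp::stop("training loss diverged (non-finite) at sample %d", start + 1);
    long nvalid = 0;
    for (int s = 0; s < B; ++s)
      for (int t = 0; t < L; ++t) if (lab(t, s) >= 0) ++nvalid;
    total_loss += loss * nvalid;
    total_pos += nvalid;
    net->zero_grad();
    net->backward(dlogits);
    net->step((float)lr);
    if ((start / batch_size) % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return total_pos > 0 ? total_loss / total_pos : 0.0;
}

// [[Rcpp::export(name = ".nn_eval_loss")]]
double nn_eval_loss(SEXP handle, Rcpp::IntegerMatrix tokens, Rcpp::IntegerMatrix labels,
                    int batch_size = 16) {
  Rcpp::XPtr<Net> net(handle);
  const int L = tokens.nrow(), n = tokens.ncol();
  double total_loss = 0.0;
  long total_pos = 0;
  for (int start = 0; start < n; start += batch_size) {
    const int B = std::min(batch_size, n - start);
    arma::imat tok(L, B), lab(L, B);
    for (int s = 0; s < B; ++s)
      for (int t = 0; t < L; ++t) {
        tok(t, s) = tokens(t, start + s);
        lab(t, s) = labels(t, start + s);
      }
    fmat logits;
    net->forward(tok, logits, false);
    const double loss = ce_loss_grad(logits, lab, nullptr);
    long nvalid = 0;
    for (int s = 0; s < B; ++s)
      for (int t = 0; t < L; ++t) if (lab(t, s) >= 0) ++nvalid;
    total_loss += loss * nvalid;
    total_pos += nvalid;
  }
  return total_pos > 0 ? total_loss / total_pos : 0.0;
}

// loss and full parameter gradient for one (train-mode) batch; used by the
// finite-difference gradient tests
// [[Rcpp::export(name = ".nn_loss_grad")]]
List nn_loss_grad(SEXP handle, Rcpp::IntegerMatrix tokens, Rcpp::IntegerMatrix labels) {
  Rcpp::XPtr<Net> net(handle);
  arma::imat tok = tokens_from_R(tokens);
  arma::imat lab = tokens_from_R(labels);
  fmat logits;
  net->forward(tok, logits, true);
  fmat dlogits;
  const double loss = ce_loss_grad(logits, lab, &dlogits);
  net->zero_grad();
  net->backward(dlogits);
  std::vector<std::string> names;
  std::vector<Rcpp::NumericMatrix> mats;
  net->each_param([&](const char* nm, Param& p) {
    Rcpp::NumericMatrix m(p.g.n_rows, p.g.n_cols);
    for (size_t j = 0; j < p.g.n_cols; ++j)
      for (size_t i = 0; i < p.g.n_rows; ++i) m(i, j) = p.g(i, j);
    names.push_back(nm);
    mats.push_back(m);
  });
  List grads(mats.size());
  for (size_t i = 0; i < mats.size(); ++i) grads[i] = mats[i];
  grads.names() = names;
  return List::create(Named("loss") = loss, Named("grads") = grads);
}

// re-estimate batch-norm population statistics with frozen weights: forward
// passes in train mode whose per-batch statistics are averaged into the
// running buffers used at evaluation time
// [[Rcpp::export(name = ".nn_recalibrate_bn")]]
void nn_recalibrate_bn(SEXP handle, Rcpp::IntegerMatrix tokens, int batch_size = 16) {
  Rcpp::XPtr<Net> net(handle);
  const int L = tokens.nrow(), n = tokens.ncol();
  net->each_bn([](const char*, BatchNorm& bn) { bn.calib_begin(); });
  for (int start = 0; start < n; start += batch_size) {
    const int B = std::min(batch_size, n - start);
    arma::imat tok(L, B);
    for (int s = 0; s < B; ++s)
      for (int t = 0; t < L; ++t) tok(t, s) = tokens(t, start + s);
    fmat logits;
    net->forward(tok, logits, true);
  }
  net->each_bn([](const char*, BatchNorm& bn) { bn.calib_end(); });
}

// train-mode loss only (no gradient); finite-difference helper
// [[Rcpp::export(name = ".nn_loss_only")]]
double nn_loss_only(SEXP handle, Rcpp::IntegerMatrix tokens, Rcpp::IntegerMatrix labels) {
  Rcpp::XPtr<Net> net(handle);
  arma::imat tok = tokens_from_R(tokens);
  arma::imat lab = tokens_from_R(labels);
  fmat logits;
  net->forward(tok, logits, true);
  return ce_loss_grad(logits, lab, nullptr);
}
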