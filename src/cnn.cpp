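// Compact EEGNet-style CNN for PGES-end detection, trained with Adam on
// binary cross-entropy. Layer order: shared temporal convolution per montage
// -> spatial convolution across montages -> BN/ReLU/avg-pool/dropout ->
// depthwise temporal convolution -> pointwise convolution ->
// BN/ReLU/avg-pool/dropout -> fully connected -> sigmoid.
// Implemented here because training must run CPU-only and deterministically.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace arma;

struct Shapes {
  int C, T, F1, k1, F2, D, k2, F3, p1, p2;
  int T1, T2, T3, T4, nflat;
};

static Shapes get_shapes(const Rcpp::List& cfg) {
  Shapes s;
  s.C  = cfg["n_channels"];
  s.T  = cfg["n_samples"];
  s.F1 = cfg["temporal_filters"];
  s.k1 = cfg["temporal_kernel_len"];
  s.F2 = cfg["spatial_filters"];
  s.D  = cfg["depthwise_multiplier"];
  s.k2 = cfg["depthwise_kernel_len"];
  s.F3 = cfg["pointwise_filters"];
  s.p1 = cfg["pool1"];
  s.p2 = cfg["pool2"];
  s.T1 = s.T - s.k1 + 1;
  s.T2 = s.T1 / s.p1;
  s.T3 = s.T2 - s.k2 + 1;
  s.T4 = s.T3 / s.p2;
  s.nflat = s.F3 * s.T4;
  if (s.T1 < 1) Rcpp::stop("temporal kernel longer than the input window");
  if (s.T3 < 1) Rcpp::stop("depthwise kernel longer than the pooled map");
  if (s.T4 < 1) Rcpp::stop("second pooling leaves no samples");
  return s;
}

struct Params {
  mat w1;  vec b1;           // F1 x k1
  mat W2;  vec b2;           // F2 x (F1*C)
  vec g1, be1, rm1, rv1;     // BN over F2 maps
  mat w3;  vec b3;           // (F2*D) x k2
  mat W4;  vec b4;           // F3 x (F2*D)
  vec g2, be2, rm2, rv2;     // BN over F3 maps
  vec w5;  double b5;        // nflat -> 1
};

static Params init_params(const Shapes& s, std::mt19937& rng) {
  Params p;
  auto glorot = [&](mat& m, int fan_in, int fan_out) {
    double lim = std::sqrt(6.0 / (fan_in + fan_out));
    std::uniform_real_distribution<double> u(-lim, lim);
    m.for_each([&](double& v) { v = u(rng); });
  };
  p.w1.set_size(s.F1, s.k1);  glorot(p.w1, s.k1, s.k1);
  p.b1.zeros(s.F1);
  p.W2.set_size(s.F2, s.F1 * s.C);  glorot(p.W2, s.F1 * s.C, s.F2);
  p.b2.zeros(s.F2);
  p.g1.ones(s.F2); p.be1.zeros(s.F2); p.rm1.zeros(s.F2); p.rv1.ones(s.F2);
  p.w3.set_size(s.F2 * s.D, s.k2);  glorot(p.w3, s.k2, s.k2);
  p.b3.zeros(s.F2 * s.D);
  p.W4.set_size(s.F3, s.F2 * s.D);  glorot(p.W4, s.F2 * s.D, s.F3);
  p.b4.zeros(s.F3);
  p.g2.ones(s.F3); p.be2.zeros(s.F3); p.rm2.zeros(s.F3); p.rv2.ones(s.F3);
  p.w5.set_size(s.nflat);
  {
    double lim = std::sqrt(6.0 / (s.nflat + 1));
    std::uniform_real_distribution<double> u(-lim, lim);
    p.w5.for_each([&](double& v) { v = u(rng); });
  }
  p.b5 = 0.0;
  return p;
}

// valid 1-d correlation of each row of x with kernel k: out cols = T-k+1
static mat conv_rows_valid(const mat& x, const rowvec& k) {
  int T = x.n_cols, kk = k.n_elem, To = T - kk + 1;
  mat out(x.n_rows, To, fill::zeros);
  for (int j = 0; j < kk; ++j)
    out += k(j) * x.cols(j, j + To - 1);
  return out;
}

static mat avg_pool(const mat& x, int p) {
  int To = x.n_cols / p;
  mat out(x.n_rows, To);
  for (int t = 0; t < To; ++t)
    out.col(t) = mean(x.cols(t * p, t * p + p - 1), 1);
  return out;
}

static mat unpool_grad(const mat& g, int p, int T_orig) {
  mat out(g.n_rows, T_orig, fill::zeros);
  for (unsigned t = 0; t < g.n_cols; ++t)
    for (int j = 0; j < p; ++j)
      out.col(t * p + j) = g.col(t) / p;
  return out;
}

struct Cache {                 // per-sample forward intermediates
  mat A1;                      // (F1*C) x T1
  mat Z2, Z2h, U2;             // F2 x T1
  mat P2, M1, D2;              // F2 x T2
  mat Z3;                      // (F2*D) x T3
  mat Z4, Z4h, U4;             // F3 x T3
  mat P4, M2, D4;              // F3 x T4
  double score, prob;
};

// forward one sample up to (and excluding) batch norm 1
static void forward_pre_bn1(const Params& p, const Shapes& s, const mat& x,
                            Cache& c) {
  c.A1.set_size(s.F1 * s.C, s.T1);
  for (int f = 0; f < s.F1; ++f) {
    mat a = conv_rows_valid(x, p.w1.row(f));
    a += p.b1(f);
    c.A1.rows(f * s.C, f * s.C + s.C - 1) = a;
  }
  c.Z2 = p.W2 * c.A1;
  c.Z2.each_col() += p.b2;
}

// remainder of the forward pass given normalized Z2h; training flag decides
// dropout masks (already filled in M1/M2) vs identity
static void forward_post_bn1(const Params& p, const Shapes& s, Cache& c,
                             const vec& mu2, const vec& sd2, bool training,
                             double keep) {
  c.U2 = c.Z2h;
  c.U2.each_col() %= p.g1;
  c.U2.each_col() += p.be1;
  mat R2 = clamp(c.U2, 0.0, datum::inf);
  c.P2 = avg_pool(R2, s.p1);
  c.D2 = training ? (c.P2 % c.M1) / keep : c.P2;

  c.Z3.set_size(s.F2 * s.D, s.T3);
  for (int f = 0; f < s.F2; ++f)
    for (int d = 0; d < s.D; ++d) {
      int m = f * s.D + d;
      c.Z3.row(m) =
          conv_rows_valid(c.D2.row(f), p.w3.row(m)) + p.b3(m);
    }
  c.Z4 = p.W4 * c.Z3;
  c.Z4.each_col() += p.b4;

  c.Z4h = c.Z4;
  c.Z4h.each_col() -= mu2;
  c.Z4h.each_col() /= sd2;
  c.U4 = c.Z4h;
  c.U4.each_col() %= p.g2;
  c.U4.each_col() += p.be2;
  mat R4 = clamp(c.U4, 0.0, datum::inf);
  c.P4 = avg_pool(R4, s.p2);
  c.D4 = training ? (c.P4 % c.M2) / keep : c.P4;

  c.score = dot(p.w5, vectorise(c.D4)) + p.b5;
  c.prob = 1.0 / (1.0 + std::exp(-c.score));
}

static vec predict_probs(const Params& p, const Shapes& s, const cube& X) {
  int N = X.n_slices;
  vec out(N);
  vec sd1 = sqrt(p.rv1 + 1e-5), sd2 = sqrt(p.rv2 + 1e-5);
  for (int i = 0; i < N; ++i) {
    Cache c;
    forward_pre_bn1(p, s, X.slice(i), c);
    c.Z2h = c.Z2;
    c.Z2h.each_col() -= p.rm1;
    c.Z2h.each_col() /= sd1;
    forward_post_bn1(p, s, c, p.rm2, sd2, false, 1.0);
    out(i) = c.prob;
  }
  return out;
}

// Mann-Whitney AUC with average-rank tie handling
static double auc_rank(const vec& scores, const vec& y) {
  int n = scores.n_elem;
  uvec ord = sort_index(scores);
  vec ranks(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && scores(ord(j + 1)) == scores(ord(i))) ++j;
    double r = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k) ranks(ord(k)) = r;
    i = j + 1;
  }
  double n1 = accu(y), n0 = n - n1;
  if (n1 == 0 || n0 == 0) return datum::nan;
  double sum_pos = dot(ranks, y);
  return (sum_pos - n1 * (n1 + 1) / 2.0) / (n1 * n0);
}

struct Grads {
  mat w1; vec b1; mat W2; vec b2; vec g1, be1;
  mat w3; vec b3; mat W4; vec b4; vec g2, be2;
  vec w5; double b5;
  void zeros_like(const Params& p) {
    w1.zeros(size(p.w1)); b1.zeros(size(p.b1));
    W2.zeros(size(p.W2)); b2.zeros(size(p.b2));
    g1.zeros(size(p.g1)); be1.zeros(size(p.be1));
    w3.zeros(size(p.w3)); b3.zeros(size(p.b3));
    W4.zeros(size(p.W4)); b4.zeros(size(p.b4));
    g2.zeros(size(p.g2)); be2.zeros(size(p.be2));
    w5.zeros(size(p.w5)); b5 = 0.0;
  }
};

struct Adam {
  Grads m, v; long step = 0;
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
  void init(const Params& p, double lr_) {
    lr = lr_; m.zeros_like(p); v.zeros_like(p);
  }
  template <class A>
  void upd(A& w, A& mw, A& vw, const A& g, double a) {
    mw = b1 * mw + (1 - b1) * g;
    vw = b2 * vw + (1 - b2) * (g % g);
    w -= a * mw / (sqrt(vw) + eps);
  }
  void apply(Params& p, const Grads& g) {
    ++step;
    double a = lr * std::sqrt(1 - std::pow(b2, step)) /
               (1 - std::pow(b1, step));
    upd(p.w1, m.w1, v.w1, g.w1, a);  upd(p.b1, m.b1, v.b1, g.b1, a);
    upd(p.W2, m.W2, v.W2, g.W2, a);  upd(p.b2, m.b2, v.b2, g.b2, a);
    upd(p.g1, m.g1, v.g1, g.g1, a);  upd(p.be1, m.be1, v.be1, g.be1, a);
    upd(p.w3, m.w3, v.w3, g.w3, a);  upd(p.b3, m.b3, v.b3, g.b3, a);
    upd(p.W4, m.W4, v.W4, g.W4, a);  upd(p.b4, m.b4, v.b4, g.b4, a);
    upd(p.g2, m.g2, v.g2, g.g2, a);  upd(p.be2, m.be2, v.be2, g.be2, a);
    upd(p.w5, m.w5, v.w5, g.w5, a);
    { // scalar bias
      m.b5 = b1 * m.b5 + (1 - b1) * g.b5;
      v.b5 = b2 * v.b5 + (1 - b2) * g.b5 * g.b5;
      p.b5 -= a * m.b5 / (std::sqrt(v.b5) + eps);
    }
  }
};

// one weighted-BCE training step on a batch; returns mean weighted loss
static double batch_step(Params& p, const Shapes& s, const cube& X,
                         const vec& y, const uvec& idx, const vec& cls_w,
                         double dropout, std::mt19937& rng, Adam& opt,
                         bool update_running) {
  int B = idx.n_elem;
  double keep = 1.0 - dropout;
  std::bernoulli_distribution bern(keep);
  std::vector<Cache> cs(B);

  // pass 1: conv1 + conv2 for the whole batch, then batch statistics
  for (int b = 0; b < B; ++b)
    forward_pre_bn1(p, s, X.slice(idx(b)), cs[b]);
  vec mu1(s.F2), var1(s.F2);
  long n1 = (long)B * s.T1;
  for (int f = 0; f < s.F2; ++f) {
    double acc = 0, acc2 = 0;
    for (int b = 0; b < B; ++b) {
      acc += accu(cs[b].Z2.row(f));
      acc2 += accu(square(cs[b].Z2.row(f)));
    }
    mu1(f) = acc / n1;
    var1(f) = acc2 / n1 - mu1(f) * mu1(f);
    if (var1(f) < 0) var1(f) = 0;
  }
  vec sd1 = sqrt(var1 + 1e-5);

  // pass 2: finish forward with batch BN1 stats; BN2 needs its own stats,
  // so run up to Z4 first
  for (int b = 0; b < B; ++b) {
    Cache& c = cs[b];
    c.Z2h = c.Z2;
    c.Z2h.each_col() -= mu1;
    c.Z2h.each_col() /= sd1;
    c.M1.set_size(s.F2, s.T2);
    c.M1.for_each([&](double& v) { v = bern(rng) ? 1.0 : 0.0; });
    c.M2.set_size(s.F3, s.T4);
    c.M2.for_each([&](double& v) { v = bern(rng) ? 1.0 : 0.0; });
    // partial: compute up to Z4 with dummy BN2, overwritten below
    c.U2 = c.Z2h;
    c.U2.each_col() %= p.g1;
    c.U2.each_col() += p.be1;
    mat R2 = clamp(c.U2, 0.0, datum::inf);
    c.P2 = avg_pool(R2, s.p1);
    c.D2 = (c.P2 % c.M1) / keep;
    c.Z3.set_size(s.F2 * s.D, s.T3);
    for (int f = 0; f < s.F2; ++f)
      for (int d = 0; d < s.D; ++d) {
        int m = f * s.D + d;
        c.Z3.row(m) = conv_rows_valid(c.D2.row(f), p.w3.row(m)) + p.b3(m);
      }
    c.Z4 = p.W4 * c.Z3;
    c.Z4.each_col() += p.b4;
  }
  vec mu2(s.F3), var2(s.F3);
  long n2 = (long)B * s.T3;
  for (int f = 0; f < s.F3; ++f) {
    double acc = 0, acc2 = 0;
    for (int b = 0; b < B; ++b) {
      acc += accu(cs[b].Z4.row(f));
      acc2 += accu(square(cs[b].Z4.row(f)));
    }
    mu2(f) = acc / n2;
    var2(f) = acc2 / n2 - mu2(f) * mu2(f);
    if (var2(f) < 0) var2(f) = 0;
  }
  vec sd2 = sqrt(var2 + 1e-5);

  double loss = 0;
  vec dscore(B);
  for (int b = 0; b < B; ++b) {
    Cache& c = cs[b];
    c.Z4h = c.Z4;
    c.Z4h.each_col() -= mu2;
    c.Z4h.each_col() /= sd2;
    c.U4 = c.Z4h;
    c.U4.each_col() %= p.g2;
    c.U4.each_col() += p.be2;
    mat R4 = clamp(c.U4, 0.0, datum::inf);
    c.P4 = avg_pool(R4, s.p2);
    c.D4 = (c.P4 % c.M2) / keep;
    c.score = dot(p.w5, vectorise(c.D4)) + p.b5;
    c.prob = 1.0 / (1.0 + std::exp(-c.score));
    double yi = y(idx(b));
    double w = cls_w(yi > 0.5 ? 1 : 0);
    double pr = std::min(std::max(c.prob, 1e-12), 1.0 - 1e-12);
    loss += -w * (yi * std::log(pr) + (1 - yi) * std::log(1 - pr));
    dscore(b) = w * (c.prob - yi) / B;
  }
  loss /= B;

  if (update_running) {
    const double mom = 0.1;
    p.rm1 = (1 - mom) * p.rm1 + mom * mu1;
    p.rv1 = (1 - mom) * p.rv1 + mom * var1;
    p.rm2 = (1 - mom) * p.rm2 + mom * mu2;
    p.rv2 = (1 - mom) * p.rv2 + mom * var2;
  }

  // backward
  Grads g; g.zeros_like(p);
  // accumulators for BN backward (need batch-wide sums first)
  mat dU4_sum(s.F3, 1, fill::zeros);
  std::vector<mat> dU4(B), dU2(B);
  vec sum_dU4(s.F3, fill::zeros), sum_dU4_z(s.F3, fill::zeros);
  for (int b = 0; b < B; ++b) {
    Cache& c = cs[b];
    mat dD4 = reshape(p.w5 * dscore(b), s.F3, s.T4);
    g.w5 += vectorise(c.D4) * dscore(b);
    g.b5 += dscore(b);
    mat dP4 = (dD4 % c.M2) / keep;
    mat dR4 = unpool_grad(dP4, s.p2, s.T3);
    dU4[b] = dR4 % conv_to<mat>::from(c.U4 > 0);
    g.g2 += sum(dU4[b] % c.Z4h, 1);
    g.be2 += sum(dU4[b], 1);
    sum_dU4 += sum(dU4[b] % (repmat(p.g2, 1, s.T3)), 1) / 1.0; // dZ4h sums
    sum_dU4_z += sum((dU4[b].each_col() % p.g2) % c.Z4h, 1);
  }
  // BN2 backward: dZ4 = g2/sd * (dU4 - mean(dU4) - Z4h * mean(dU4 % Z4h))
  for (int b = 0; b < B; ++b) {
    Cache& c = cs[b];
    mat dZ4h = dU4[b];
    dZ4h.each_col() %= p.g2;
    mat dZ4 = dZ4h;
    dZ4.each_col() -= sum_dU4 / n2;
    dZ4 -= c.Z4h.each_col() % (sum_dU4_z / n2);
    dZ4.each_col() /= sd2;

    g.W4 += dZ4 * c.Z3.t();
    g.b4 += sum(dZ4, 1);
    mat dZ3 = p.W4.t() * dZ4;
    mat dD2(s.F2, s.T2, fill::zeros);
    for (int f = 0; f < s.F2; ++f)
      for (int d = 0; d < s.D; ++d) {
        int m = f * s.D + d;
        const rowvec dz = dZ3.row(m);
        for (int j = 0; j < s.k2; ++j) {
          g.w3(m, j) += dot(dz, c.D2.row(f).cols(j, j + s.T3 - 1));
          dD2.row(f).cols(j, j + s.T3 - 1) += p.w3(m, j) * dz;
        }
        g.b3(m) += accu(dz);
      }
    mat dP2 = (dD2 % cs[b].M1) / keep;
    mat dR2 = unpool_grad(dP2, s.p1, s.T1);
    dU2[b] = dR2 % conv_to<mat>::from(c.U2 > 0);
    g.g1 += sum(dU2[b] % c.Z2h, 1);
    g.be1 += sum(dU2[b], 1);
  }
  vec sum_dU2(s.F2, fill::zeros), sum_dU2_z(s.F2, fill::zeros);
  for (int b = 0; b < B; ++b) {
    sum_dU2 += sum(dU2[b].each_col() % p.g1, 1);
    sum_dU2_z += sum((dU2[b].each_col() % p.g1) % cs[b].Z2h, 1);
  }
  for (int b = 0; b < B; ++b) {
    Cache& c = cs[b];
    mat dZ2h = dU2[b];
    dZ2h.each_col() %= p.g1;
    mat dZ2 = dZ2h;
    dZ2.each_col() -= sum_dU2 / n1;
    dZ2 -= c.Z2h.each_col() % (sum_dU2_z / n1);
    dZ2.each_col() /= sd1;

    g.W2 += dZ2 * c.A1.t();
    g.b2 += sum(dZ2, 1);
    mat dA1 = p.W2.t() * dZ2;
    const mat& x = X.slice(idx(b));
    for (int f = 0; f < s.F1; ++f) {
      const mat dA = dA1.rows(f * s.C, f * s.C + s.C - 1);
      for (int j = 0; j < s.k1; ++j)
        g.w1(f, j) += accu(dA % x.cols(j, j + s.T1 - 1));
      g.b1(f) += accu(dA);
    }
  }
  opt.apply(p, g);
  return loss;
}

static Rcpp::List params_to_list(const Params& p) {
  return Rcpp::List::create(
      Rcpp::Named("w1") = p.w1, Rcpp::Named("b1") = p.b1,
      Rcpp::Named("W2") = p.W2, Rcpp::Named("b2") = p.b2,
      Rcpp::Named("g1") = p.g1, Rcpp::Named("be1") = p.be1,
      Rcpp::Named("rm1") = p.rm1, Rcpp::Named("rv1") = p.rv1,
      Rcpp::Named("w3") = p.w3, Rcpp::Named("b3") = p.b3,
      Rcpp::Named("W4") = p.W4, Rcpp::Named("b4") = p.b4,
      Rcpp::Named("g2") = p.g2, Rcpp::Named("be2") = p.be2,
      Rcpp::Named("rm2") = p.rm2, Rcpp::Named("rv2") = p.rv2,
      Rcpp::Named("w5") = p.w5, Rcpp::Named("b5") = p.b5);
}

static Params params_from_list(const Rcpp::List& l) {
  Params p;
  p.w1 = Rcpp::as<mat>(l["w1"]);  p.b1 = Rcpp::as<vec>(l["b1"]);
  p.W2 = Rcpp::as<mat>(l["W2"]);  p.b2 = Rcpp::as<vec>(l["b2"]);
  p.g1 = Rcpp::as<vec>(l["g1"]);  p.be1 = Rcpp::as<vec>(l["be1"]);
  p.rm1 = Rcpp::as<vec>(l["rm1"]); p.rv1 = Rcpp::as<vec>(l["rv1"]);
  p.w3 = Rcpp::as<mat>(l["w3"]);  p.b3 = Rcpp::as<vec>(l["b3"]);
  p.W4 = Rcpp::as<mat>(l["W4"]);  p.b4 = Rcpp::as<vec>(l["b4"]);
  p.g2 = Rcpp::as<vec>(l["g2"]);  p.be2 = Rcpp::as<vec>(l["be2"]);
  p.rm2 = Rcpp::as<vec>(l["rm2"]); p.rv2 = Rcpp::as<vec>(l["rv2"]);
  p.w5 = Rcpp::as<vec>(l["w5"]);  p.b5 = Rcpp::as<double>(l["b5"]);
  return p;
}

// [[Rcpp::export(name = ".cnn_init")]]
Rcpp::List cnn_init_cpp(Rcpp::List cfg, int seed) {
  Shapes s = get_shapes(cfg);
  std::mt19937 rng(static_cast<unsigned>(seed));
  Params p = init_params(s, rng);
  return params_to_list(p);
}

// [[Rcpp::export(name = ".cnn_fit")]]
Rcpp::List cnn_fit_cpp(arma::cube X, arma::vec y, arma::cube Xval,
                       arma::vec yval, Rcpp::List cfg, Rcpp::List tc) {
  Shapes s = get_shapes(cfg);
  int epochs = tc["epochs"];
  int batch = tc["batch_size"];
  double lr = tc["learning_rate"];
  double dropout = cfg["dropout_rate"];
  int seed = tc["seed"];
  vec cls_w = Rcpp::as<vec>(tc["class_weights"]);
  int N = X.n_slices;
  if ((int)y.n_elem != N) Rcpp::stop("label/crop count mismatch");
  if ((int)X.n_rows != s.C || (int)X.n_cols != s.T)
    Rcpp::stop("crop shape does not match the architecture input shape");

  std::mt19937 rng(static_cast<unsigned>(seed));
  Params p = init_params(s, rng);
  Adam opt; opt.init(p, lr);

  std::vector<double> ep_loss(epochs), ep_auc(epochs);
  Rcpp::List best = params_to_list(p);
  double best_auc = -1; int best_epoch = 0;
  uvec order = regspace<uvec>(0, N - 1);
  bool has_val = Xval.n_slices > 0;

  for (int e = 0; e < epochs; ++e) {
    for (int i = N - 1; i > 0; --i) {  // Fisher-Yates with own RNG
      std::uniform_int_distribution<int> u(0, i);
      std::swap(order(i), order(u(rng)));
    }
    double tot = 0; int nb = 0;
    for (int at = 0; at < N; at += batch) {
      int hi = std::min(at + batch - 1, N - 1);
      if (hi - at + 1 < 2) continue;   // BN needs more than one sample
      uvec idx = order.subvec(at, hi);
      tot += batch_step(p, s, X, y, idx, cls_w, dropout, rng, opt, true);
      ++nb;
    }
    ep_loss[e] = tot / std::max(nb, 1);
    double a = datum::nan;
    if (has_val) a = auc_rank(predict_probs(p, s, Xval), yval);
    ep_auc[e] = a;
    double score = std::isnan(a) ? -ep_loss[e] : a;
    if (score > best_auc) {
      best_auc = score; best_epoch = e + 1;
      best = params_to_list(p);
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("params") = best,
      Rcpp::Named("final_params") = params_to_list(p),
      Rcpp::Named("train_loss") = ep_loss,
      Rcpp::Named("val_auc") = ep_auc,
      Rcpp::Named("best_epoch") = best_epoch);
}

// [[Rcpp::export(name = ".cnn_predict")]]
arma::vec cnn_predict_cpp(Rcpp::List params, arma::cube X, Rcpp::List cfg) {
  Shapes s = get_shapes(cfg);
  if ((int)X.n_rows != s.C || (int)X.n_cols != s.T)
    Rcpp::stop("crop shape does not match the architecture input shape");
  Params p = params_from_list(params);
  return predict_probs(p, s, X);
}

// [[Rcpp::export(name = ".cnn_step_loss")]]
Rcpp::NumericVector cnn_step_loss_cpp(arma::cube X, arma::vec y,
                                      Rcpp::List cfg, Rcpp::List tc) {
  // loss on one batch before and after a single optimizer step (sanity hook)
  Shapes s = get_shapes(cfg);
  double lr = tc["learning_rate"];
  int seed = tc["seed"];
  vec cls_w = Rcpp::as<vec>(tc["class_weights"]);
  std::mt19937 rng(static_cast<unsigned>(seed));
  Params p = init_params(s, rng);
  Adam opt; opt.init(p, lr);
  uvec idx = regspace<uvec>(0, X.n_slices - 1);
  double l0 = batch_step(p, s, X, y, idx, cls_w, 0.0, rng, opt, true);
  // recompute loss on the same batch with updated weights (no update)
  Params q = p;
  Adam noop; noop.init(q, 0.0);
  std::mt19937 rng2(static_cast<unsigned>(seed) + 1u);
  double l1 = batch_step(q, s, X, y, idx, cls_w, 0.0, rng2, noop, false);
  return Rcpp::NumericVector::create(l0, l1);
}
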