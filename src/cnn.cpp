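// Compact convolutional network for 2-s EEG epochs (channels x samples),
// trained per subject: temporal convolution (12 filters, 1x4, linear),
// spatio-temporal convolution (12 filters, n_ch x 4 over the 12 maps, ELU),
// 1x4 max-pool, dropout, dense-32 (ELU), dense-1 (sigmoid). Convolutions
// are GEMM-formulated (shift-stacked inputs) so OpenBLAS carries the load.
// All randomness (init, shuffling, dropout) flows from one xorshift stream
// so a seed fully determines training.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed * 2862933555777941757ULL + 3037000493ULL) {
    if (s == 0) s = 0x9E3779B97F4A7C15ULL;
    for (int i = 0; i < 8; ++i) next();
  }
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 2685821657736338717ULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double unif(double lo, double hi) { return lo + (hi - lo) * unif(); }
  void shuffle(uvec& v) {
    for (uword i = v.n_elem - 1; i > 0; --i) {
      uword j = static_cast<uword>(unif() * (i + 1));
      if (j > i) j = i;
      std::swap(v[i], v[j]);
    }
  }
};

struct Net {
  mat W1;  vec b1;   // 12 x 4           temporal filters
  mat W2;  vec b2;   // 12 x (4*12*nch)  spatio-temporal filters
  mat W3;  vec b3;   // 32 x flat
  rowvec W4; double b4;
  uword nch, nsamp, nmap = 12, klen = 4, pool = 4, dense = 32;
  uword L1() const { return nsamp - klen + 1; }           // after conv1
  uword L2() const { return L1() - klen + 1; }            // after conv2
  uword npool() const { return L2() / pool; }             // floor
  uword nflat() const { return nmap * npool(); }
};

void init_net(Net& n, uword nch, uword nsamp, Rng& rng) {
  n.nch = nch; n.nsamp = nsamp;
  auto glorot = [&](mat& W, double fan_in, double fan_out) {
    double lim = std::sqrt(6.0 / (fan_in + fan_out));
    for (uword i = 0; i < W.n_elem; ++i) W[i] = rng.unif(-lim, lim);
  };
  n.W1.set_size(n.nmap, n.klen);
  glorot(n.W1, n.klen, n.klen * n.nmap);
  n.b1.zeros(n.nmap);
  n.W2.set_size(n.nmap, n.klen * n.nmap * nch);
  glorot(n.W2, (double)n.klen * n.nmap * nch, (double)n.klen * n.nmap * nch);
  n.b2.zeros(n.nmap);
  n.W3.set_size(n.dense, n.nflat());
  glorot(n.W3, n.nflat(), n.dense);
  n.b3.zeros(n.dense);
  mat w4(1, n.dense);
  glorot(w4, n.dense, 1.0);
  n.W4 = w4.row(0);
  n.b4 = 0.0;
}

inline void elu_inplace(mat& z) {
  for (uword i = 0; i < z.n_elem; ++i)
    if (z[i] < 0) z[i] = std::expm1(z[i]);
}
inline void elu_inplace(vec& z) {
  for (uword i = 0; i < z.n_elem; ++i)
    if (z[i] < 0) z[i] = std::expm1(z[i]);
}

// Scratch for one sample's forward/backward pass.
struct Pass {
  mat A1;        // (nmap*nch) x L1   conv1 output (linear)
  mat Z2, A2;    // nmap x L2 (pre/post ELU)
  umat AM;       // argmax column of each pooled cell
  vec h0, h, z3, a3;
  double z4, p;
  vec mask;      // inverted-dropout mask
};

void forward(const Net& n, const mat& x, Pass& ps, bool train,
             double keep, Rng* rng) {
  const uword L1 = n.L1(), L2 = n.L2(), np = n.npool();
  ps.A1.set_size(n.nmap * n.nch, L1);
  for (uword m = 0; m < n.nmap; ++m) {
    mat block = n.W1(m, 0) * x.cols(0, L1 - 1);
    for (uword k = 1; k < n.klen; ++k)
      block += n.W1(m, k) * x.cols(k, k + L1 - 1);
    block += n.b1(m);
    ps.A1.rows(m * n.nch, (m + 1) * n.nch - 1) = block;
  }
  // conv2 as klen GEMMs on contiguous column blocks: no im2col copy
  const uword rows = n.nmap * n.nch;
  ps.Z2.set_size(n.nmap, L2);
  ps.Z2.each_col() = n.b2;
  for (uword k = 0; k < n.klen; ++k)
    ps.Z2 += n.W2.cols(k * rows, (k + 1) * rows - 1) *
             ps.A1.cols(k, k + L2 - 1);
  ps.A2 = ps.Z2;
  elu_inplace(ps.A2);
  ps.AM.set_size(n.nmap, np);
  mat P(n.nmap, np);
  for (uword t = 0; t < np; ++t) {
    for (uword f = 0; f < n.nmap; ++f) {
      uword best = t * n.pool;
      double bv = ps.A2(f, best);
      for (uword j = 1; j < n.pool; ++j) {
        double v = ps.A2(f, t * n.pool + j);
        if (v > bv) { bv = v; best = t * n.pool + j; }
      }
      P(f, t) = bv;
      ps.AM(f, t) = best;
    }
  }
  ps.h0 = vectorise(P);
  if (train) {
    ps.mask.set_size(ps.h0.n_elem);
    for (uword i = 0; i < ps.mask.n_elem; ++i)
      ps.mask[i] = (rng->unif() < keep) ? 1.0 / keep : 0.0;
    ps.h = ps.h0 % ps.mask;
  } else {
    ps.h = ps.h0;
  }
  ps.z3 = n.W3 * ps.h + n.b3;
  ps.a3 = ps.z3;
  elu_inplace(ps.a3);
  ps.z4 = dot(n.W4, ps.a3) + n.b4;
  ps.p = 1.0 / (1.0 + std::exp(-ps.z4));
}

struct Grads {
  mat W1; vec b1; mat W2; vec b2; mat W3; vec b3; rowvec W4; double b4;
  void zeros_like(const Net& n) {
    W1.zeros(size(n.W1)); b1.zeros(size(n.b1));
    W2.zeros(size(n.W2)); b2.zeros(size(n.b2));
    W3.zeros(size(n.W3)); b3.zeros(size(n.b3));
    W4.zeros(1, n.W4.n_elem); b4 = 0.0;
  }
};

void backward(const Net& n, const mat& x, const Pass& ps, double dz4,
              Grads& g) {
  const uword L1 = n.L1(), L2 = n.L2();
  g.W4 += dz4 * ps.a3.t();
  g.b4 += dz4;
  vec da3 = n.W4.t() * dz4;
  vec dz3 = da3;
  for (uword i = 0; i < dz3.n_elem; ++i)
    if (ps.z3[i] < 0) dz3[i] *= (ps.a3[i] + 1.0);
  g.W3 += dz3 * ps.h.t();
  g.b3 += dz3;
  vec dh = n.W3.t() * dz3;
  vec dh0 = dh % ps.mask;
  mat dA2(n.nmap, L2, fill::zeros);
  const uword np = n.npool();
  for (uword t = 0; t < np; ++t)
    for (uword f = 0; f < n.nmap; ++f)
      dA2(f, ps.AM(f, t)) += dh0[f + n.nmap * t];
  // ELU gradient through conv2
  for (uword i = 0; i < dA2.n_elem; ++i)
    if (ps.Z2[i] < 0) dA2[i] *= (ps.A2[i] + 1.0);
  g.b2 += sum(dA2, 1);
  const uword rows = n.nmap * n.nch;
  mat dA1(rows, L1, fill::zeros);
  for (uword k = 0; k < n.klen; ++k) {
    g.W2.cols(k * rows, (k + 1) * rows - 1) +=
      dA2 * ps.A1.cols(k, k + L2 - 1).t();
    dA1.cols(k, k + L2 - 1) +=
      n.W2.cols(k * rows, (k + 1) * rows - 1).t() * dA2;
  }
  for (uword m = 0; m < n.nmap; ++m) {
    const mat dblock = dA1.rows(m * n.nch, (m + 1) * n.nch - 1);
    for (uword k = 0; k < n.klen; ++k)
      g.W1(m, k) += accu(x.cols(k, k + L1 - 1) % dblock);
    g.b1(m) += accu(dblock);
  }
}

struct Adam {
  Grads m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-7, lr = 1e-3;
  long t = 0;
  void init(const Net& n, double lr_, double b1_, double b2_, double eps_) {
    m.zeros_like(n); v.zeros_like(n);
    lr = lr_; b1 = b1_; b2 = b2_; eps = eps_; t = 0;
  }
  template <class T>
  void upd(T& w, T& mm, T& vv, const T& g) {
    mm = b1 * mm + (1 - b1) * g;
    vv = b2 * vv + (1 - b2) * (g % g);
    double c1 = 1 - std::pow(b1, (double)t), c2 = 1 - std::pow(b2, (double)t);
    w -= lr * (mm / c1) / (sqrt(vv / c2) + eps);
  }
  void upd_scalar(double& w, double& mm, double& vv, double g) {
    mm = b1 * mm + (1 - b1) * g;
    vv = b2 * vv + (1 - b2) * g * g;
    double c1 = 1 - std::pow(b1, (double)t), c2 = 1 - std::pow(b2, (double)t);
    w -= lr * (mm / c1) / (std::sqrt(vv / c2) + eps);
  }
  void step(Net& n, const Grads& g) {
    ++t;
    upd(n.W1, m.W1, v.W1, g.W1); upd(n.b1, m.b1, v.b1, g.b1);
    upd(n.W2, m.W2, v.W2, g.W2); upd(n.b2, m.b2, v.b2, g.b2);
    upd(n.W3, m.W3, v.W3, g.W3); upd(n.b3, m.b3, v.b3, g.b3);
    upd(n.W4, m.W4, v.W4, g.W4);
    upd_scalar(n.b4, m.b4, v.b4, g.b4);
  }
};

double rank_auc(const vec& y, const vec& s) {
  uword n = y.n_elem;
  uvec ord = sort_index(s);
  vec ranks(n);
  uword i = 0;
  while (i < n) {
    uword j = i;
    while (j + 1 < n && s[ord[j + 1]] == s[ord[i]]) ++j;
    double r = 0.5 * (i + j) + 1.0;
    for (uword k = i; k <= j; ++k) ranks[ord[k]] = r;
    i = j + 1;
  }
  double n1 = accu(y), n0 = n - n1;
  if (n1 == 0 || n0 == 0) return datum::nan;
  double rsum = dot(ranks, y);
  return (rsum - n1 * (n1 + 1) / 2.0) / (n1 * n0);
}

Net net_from_list(const Rcpp::List& w) {
  Net n;
  n.W1 = Rcpp::as<mat>(w["W1"]); n.b1 = Rcpp::as<vec>(w["b1"]);
  n.W2 = Rcpp::as<mat>(w["W2"]); n.b2 = Rcpp::as<vec>(w["b2"]);
  n.W3 = Rcpp::as<mat>(w["W3"]); n.b3 = Rcpp::as<vec>(w["b3"]);
  mat w4 = Rcpp::as<mat>(w["W4"]);
  n.W4 = w4.row(0);
  n.b4 = Rcpp::as<double>(w["b4"]);
  n.nch = Rcpp::as<int>(w["n_channels"]);
  n.nsamp = Rcpp::as<int>(w["n_samples"]);
  return n;
}

Rcpp::List net_to_list(const Net& n) {
  mat w4(1, n.W4.n_elem);
  w4.row(0) = n.W4;
  return Rcpp::List::create(
    Rcpp::Named("W1") = n.W1, Rcpp::Named("b1") = n.b1,
    Rcpp::Named("W2") = n.W2, Rcpp::Named("b2") = n.b2,
    Rcpp::Named("W3") = n.W3, Rcpp::Named("b3") = n.b3,
    Rcpp::Named("W4") = w4,  Rcpp::Named("b4") = n.b4,
    Rcpp::Named("n_channels") = (int)n.nch,
    Rcpp::Named("n_samples") = (int)n.nsamp);
}

vec predict_all(const Net& n, const cube& X) {
  vec out(X.n_slices);
  Pass ps;
  for (uword i = 0; i < X.n_slices; ++i) {
    forward(n, X.slice(i), ps, false, 1.0, nullptr);
    out[i] = ps.p;
  }
  return out;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cnn_init_cpp(int n_channels, int n_samples, int seed) {
  Rng rng((uint64_t)seed);
  Net n;
  if ((uword)n_samples < 2 * 4) Rcpp::stop("input too short for two 1x4 convolutions");
  init_net(n, n_channels, n_samples, rng);
  return net_to_list(n);
}

// [[Rcpp::export]]
arma::vec cnn_predict_cpp(const Rcpp::List& weights, const arma::cube& X) {
  Net n = net_from_list(weights);
  if (X.n_rows != n.nch || X.n_cols != n.nsamp)
    Rcpp::stop("input shape does not match the network (%d x %d expected)",
               (int)n.nch, (int)n.nsamp);
  return predict_all(n, X);
}

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(const Rcpp::List& weights, const arma::cube& X,
                         const arma::vec& y, const arma::uvec& train_idx,
                         const arma::uvec& val_idx, const Rcpp::List& config) {
  Net n = net_from_list(weights);
  if (X.n_rows != n.nch || X.n_cols != n.nsamp)
    Rcpp::stop("input shape does not match the network");
  const double lr = config["lr"], beta1 = config["beta1"],
               beta2 = config["beta2"], eps = config["eps"],
               dropout = config["dropout"],
               w0 = config["weight0"], w1 = config["weight1"];
  const int batch = config["batch_size"], nepochs = config["n_epochs"],
            patience = config["patience"];
  const bool early = config["early_stopping"];
  const uint64_t seed = (uint64_t)Rcpp::as<int>(config["rng_seed"]);
  const double keep = 1.0 - dropout;
  Rng rng(seed ^ 0xD1B54A32D192ED03ULL);

  Adam opt;
  opt.init(n, lr, beta1, beta2, eps);
  Grads g;
  Pass ps;

  uvec tr = train_idx;
  const bool has_val = val_idx.n_elem > 0;
  cube Xval;
  vec yval;
  if (has_val) {
    Xval.set_size(n.nch, n.nsamp, val_idx.n_elem);
    yval.set_size(val_idx.n_elem);
    for (uword i = 0; i < val_idx.n_elem; ++i) {
      Xval.slice(i) = X.slice(val_idx[i]);
      yval[i] = y[val_idx[i]];
    }
  }

  std::vector<double> h_loss, h_vloss, h_vauc;
  Net best = n;
  double best_auc = -1.0;
  int since_best = 0;
  int stopped_at = nepochs;

  for (int ep = 0; ep < nepochs; ++ep) {
    rng.shuffle(tr);
    double ep_loss = 0.0, ep_w = 0.0;
    for (uword b0 = 0; b0 < tr.n_elem; b0 += batch) {
      uword b1i = std::min<uword>(b0 + batch, tr.n_elem);
      uword nb = b1i - b0;
      g.zeros_like(n);
      for (uword i = b0; i < b1i; ++i) {
        const mat& x = X.slice(tr[i]);
        forward(n, x, ps, true, keep, &rng);
        double yi = y[tr[i]];
        double wi = (yi > 0.5) ? w1 : w0;
        double pc = std::min(std::max(ps.p, 1e-12), 1.0 - 1e-12);
        ep_loss += -wi * (yi * std::log(pc) + (1 - yi) * std::log(1 - pc));
        ep_w += wi;
        double dz4 = wi * (ps.p - yi) / (double)nb;
        backward(n, x, ps, dz4, g);
      }
      opt.step(n, g);
    }
    h_loss.push_back(ep_loss / std::max(ep_w, 1e-12));
    if (has_val) {
      vec pv = predict_all(n, Xval);
      double vl = 0.0, vw = 0.0;
      for (uword i = 0; i < pv.n_elem; ++i) {
        double wi = (yval[i] > 0.5) ? w1 : w0;
        double pc = std::min(std::max(pv[i], 1e-12), 1.0 - 1e-12);
        vl += -wi * (yval[i] * std::log(pc) + (1 - yval[i]) * std::log(1 - pc));
        vw += wi;
      }
      double va = rank_auc(yval, pv);
      h_vloss.push_back(vl / std::max(vw, 1e-12));
      h_vauc.push_back(va);
      if (early) {
        if (va > best_auc) { best_auc = va; best = n; since_best = 0; }
        else if (++since_best >= patience) { stopped_at = ep + 1; break; }
      }
    } else {
      h_vloss.push_back(NA_REAL);
      h_vauc.push_back(NA_REAL);
    }
  }
  if (early && has_val && best_auc >= 0) n = best;

  return Rcpp::List::create(
    Rcpp::Named("weights") = net_to_list(n),
    Rcpp::Named("loss") = h_loss,
    Rcpp::Named("val_loss") = h_vloss,
    Rcpp::Named("val_auc") = h_vauc,
    Rcpp::Named("stopped_at") = stopped_at);
}

// [[Rcpp::export]]
Rcpp::List cnn_forward_shapes_cpp(int n_channels, int n_samples) {
  Net n;
  n.nch = n_channels; n.nsamp = n_samples;
  return Rcpp::List::create(
    Rcpp::Named("conv1") = Rcpp::IntegerVector::create(n_channels, (int)n.L1()),
    Rcpp::Named("conv2") = Rcpp::IntegerVector::create(1, (int)n.L2()),
    Rcpp::Named("pool") = Rcpp::IntegerVector::create(1, (int)n.npool()),
    Rcpp::Named("flatten") = (int)n.nflat(),
    Rcpp::Named("dense") = (int)n.dense,
    Rcpp::Named("output") = 1);
}
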