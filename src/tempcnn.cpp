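// 1-D temporal convolutional network over 10-year x 6-band windows.
// Convolutions run along the time axis with bands as input channels,
// implemented as im2col + GEMM; each conv block and the dense layer are
// batch-normalized before ReLU and dropout, following the reference
// TempCNN design. The whole training loop lives here so a single integer
// seed makes training bit-reproducible: all randomness (weight init,
// shuffling, dropout masks) comes from one mt19937_64 with explicit
// uniform/normal constructions (no implementation-defined
// std::*_distribution).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

constexpr double kBnEps = 1e-5;
constexpr double kBnMomentum = 0.1;

struct Rng {
  std::mt19937_64 g;
  explicit Rng(uint64_t seed) : g(seed) {}
  double unif() {  // in [0,1)
    return (g() >> 11) * (1.0 / 9007199254740992.0);
  }
  double norm() {  // Box-Muller
    double u1 = 0.0;
    while (u1 <= 0.0) u1 = unif();
    double u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  int upto(int n) { return static_cast<int>(unif() * n) % n; }
};

struct BN {  // per-channel batch norm parameters and running stats
  vec gamma, beta, rmean, rvar;
  void init(int ch) {
    gamma.ones(ch);
    beta.zeros(ch);
    rmean.zeros(ch);
    rvar.ones(ch);
  }
};

struct Net {
  std::vector<mat> convW;  // each: hidden x (in_ch * kernel)
  std::vector<BN> convBN;
  mat denseW;              // hidden x (hidden * T)
  BN denseBN;
  mat outW;                // n_classes x hidden
  vec outB;
  int kernel = 3, T = 10, bands = 6, hidden = 64, n_classes = 2;
};

BN bn_from_list(const Rcpp::List& l) {
  BN b;
  b.gamma = Rcpp::as<vec>(l["gamma"]);
  b.beta = Rcpp::as<vec>(l["beta"]);
  b.rmean = Rcpp::as<vec>(l["rmean"]);
  b.rvar = Rcpp::as<vec>(l["rvar"]);
  return b;
}

Rcpp::List bn_to_list(const BN& b) {
  return Rcpp::List::create(
      Rcpp::Named("gamma") = b.gamma, Rcpp::Named("beta") = b.beta,
      Rcpp::Named("rmean") = b.rmean, Rcpp::Named("rvar") = b.rvar);
}

Net net_from_list(const Rcpp::List& w) {
  Net n;
  Rcpp::List cw = w["convW"], cbn = w["convBN"];
  for (int i = 0; i < cw.size(); ++i) {
    n.convW.push_back(Rcpp::as<mat>(cw[i]));
    n.convBN.push_back(bn_from_list(cbn[i]));
  }
  n.denseW = Rcpp::as<mat>(w["denseW"]);
  n.denseBN = bn_from_list(w["denseBN"]);
  n.outW = Rcpp::as<mat>(w["outW"]);
  n.outB = Rcpp::as<vec>(w["outB"]);
  n.kernel = Rcpp::as<int>(w["kernel"]);
  n.hidden = static_cast<int>(n.convW[0].n_rows);
  n.bands = static_cast<int>(n.convW[0].n_cols) / n.kernel;
  n.T = static_cast<int>(n.denseW.n_cols) / n.hidden;
  n.n_classes = static_cast<int>(n.outW.n_rows);
  return n;
}

Rcpp::List net_to_list(const Net& n) {
  Rcpp::List cw(n.convW.size()), cbn(n.convBN.size());
  for (size_t i = 0; i < n.convW.size(); ++i) {
    cw[i] = n.convW[i];
    cbn[i] = bn_to_list(n.convBN[i]);
  }
  return Rcpp::List::create(
      Rcpp::Named("convW") = cw, Rcpp::Named("convBN") = cbn,
      Rcpp::Named("denseW") = n.denseW,
      Rcpp::Named("denseBN") = bn_to_list(n.denseBN),
      Rcpp::Named("outW") = n.outW, Rcpp::Named("outB") = n.outB,
      Rcpp::Named("kernel") = n.kernel);
}

// x: (channels x T*nb), samples side by side. Returns (channels*k x T*nb)
// with zero padding so output length equals T ("same" convolution).
mat im2col(const mat& x, int T, int k) {
  int ch = x.n_rows, nb = x.n_cols / T, half = k / 2;
  mat cols(ch * k, x.n_cols, fill::zeros);
  for (int o = 0; o < k; ++o) {
    int shift = o - half;
    for (int s = 0; s < nb; ++s) {
      int t0 = std::max(0, -shift), t1 = std::min(T, T - shift);
      if (t1 > t0)
        cols.submat(o * ch, s * T + t0, (o + 1) * ch - 1, s * T + t1 - 1) =
            x.cols(s * T + t0 + shift, s * T + t1 - 1 + shift);
    }
  }
  return cols;
}

// adjoint of im2col
mat col2im(const mat& dcols, int ch, int T, int k) {
  int nb = dcols.n_cols / T, half = k / 2;
  mat dx(ch, dcols.n_cols, fill::zeros);
  for (int o = 0; o < k; ++o) {
    int shift = o - half;
    for (int s = 0; s < nb; ++s) {
      int t0 = std::max(0, -shift), t1 = std::min(T, T - shift);
      if (t1 > t0)
        dx.cols(s * T + t0 + shift, s * T + t1 - 1 + shift) +=
            dcols.submat(o * ch, s * T + t0, (o + 1) * ch - 1, s * T + t1 - 1);
    }
  }
  return dx;
}

// X rows are samples, column index = band*T + t; per sample we need a
// (bands x T) block; batch blocks are laid side by side.
mat batch_input(const mat& X, const uvec& idx, int bands, int T) {
  mat out(bands, idx.n_elem * T);
  for (uword s = 0; s < idx.n_elem; ++s) {
    rowvec r = X.row(idx[s]);
    mat sample(r.memptr(), T, bands, true);  // T x bands, t fastest
    out.cols(s * T, (s + 1) * T - 1) = sample.t();
  }
  return out;
}

mat dropout_mask(Rng& rng, uword nr, uword nc, double rate) {
  mat m(nr, nc);
  double scale = 1.0 / (1.0 - rate);
  for (uword j = 0; j < nc; ++j)
    for (uword i = 0; i < nr; ++i) m(i, j) = rng.unif() < rate ? 0.0 : scale;
  return m;
}

struct BnCache {
  mat xhat;
  vec inv_std;
};

// batch norm over columns, per row (channel); updates running stats when
// training
mat bn_forward(BN& bn, const mat& x, bool training, BnCache* cache) {
  vec mu, var;
  if (training) {
    mu = mean(x, 1);
    var = mean(square(x.each_col() - mu), 1);
    bn.rmean = (1 - kBnMomentum) * bn.rmean + kBnMomentum * mu;
    bn.rvar = (1 - kBnMomentum) * bn.rvar + kBnMomentum * var;
  } else {
    mu = bn.rmean;
    var = bn.rvar;
  }
  vec inv_std = 1.0 / sqrt(var + kBnEps);
  mat xhat = (x.each_col() - mu).each_col() % inv_std;
  if (cache) {
    cache->xhat = xhat;
    cache->inv_std = inv_std;
  }
  return (xhat.each_col() % bn.gamma).each_col() + bn.beta;
}

// given dY (gradient at BN output), return dX and accumulate dgamma/dbeta
mat bn_backward(const BN& bn, const BnCache& c, const mat& dy, vec& dgamma,
                vec& dbeta) {
  double N = static_cast<double>(dy.n_cols);
  dgamma = sum(dy % c.xhat, 1);
  dbeta = sum(dy, 1);
  mat t = dy.each_col() - dbeta / N;
  t -= c.xhat.each_col() % (dgamma / N);
  return (t.each_col() % (bn.gamma % c.inv_std));
}

struct Cache {
  std::vector<mat> cols, act, mask;  // per conv block
  std::vector<BnCache> bn;
  mat flat, hidden_act, hidden_mask;
  BnCache dense_bn;
  mat probs;
};

mat forward(Net& net, const mat& xin, int nb, bool training, double dropout,
            Rng* rng, Cache* cache) {
  int T = net.T, h = net.hidden;
  mat cur = xin;
  for (size_t l = 0; l < net.convW.size(); ++l) {
    mat cols = im2col(cur, T, net.kernel);
    mat a = net.convW[l] * cols;
    if (cache) cache->cols.push_back(std::move(cols));
    BnCache bc;
    a = bn_forward(net.convBN[l], a, training, cache ? &bc : nullptr);
    if (cache) cache->bn.push_back(bc);
    a = clamp(a, 0.0, datum::inf);  // ReLU
    if (training && dropout > 0) {
      mat m = dropout_mask(*rng, a.n_rows, a.n_cols, dropout);
      a %= m;
      if (cache) cache->mask.push_back(m);
    }
    if (cache) cache->act.push_back(a);
    cur = a;
  }
  // flatten: per sample (h x T) block -> column vector of h*T
  mat flat(h * T, nb);
  for (int s = 0; s < nb; ++s)
    flat.col(s) = vectorise(cur.cols(s * T, (s + 1) * T - 1));
  mat hid = net.denseW * flat;
  BnCache dbc;
  hid = bn_forward(net.denseBN, hid, training, cache ? &dbc : nullptr);
  hid = clamp(hid, 0.0, datum::inf);
  mat hmask;
  if (training && dropout > 0) {
    hmask = dropout_mask(*rng, hid.n_rows, hid.n_cols, dropout);
    hid %= hmask;
  }
  mat logits = net.outW * hid;
  logits.each_col() += net.outB;
  rowvec mx = max(logits, 0);
  logits.each_row() -= mx;
  mat ex = exp(logits);
  rowvec denom = sum(ex, 0);
  ex.each_row() /= denom;
  if (cache) {
    cache->flat = flat;
    cache->hidden_act = hid;
    cache->hidden_mask = hmask;
    cache->dense_bn = dbc;
    cache->probs = ex;
  }
  return ex;
}

struct Grads {
  std::vector<mat> convW;
  std::vector<vec> convG, convBe;
  mat denseW, outW;
  vec denseG, denseBe, outB;
};

Grads backward(const Net& net, const Cache& c, const uvec& ybatch,
               double dropout) {
  int T = net.T, h = net.hidden, nb = static_cast<int>(ybatch.n_elem);
  Grads g;
  mat dlogits = c.probs;  // probs - onehot, averaged over batch
  for (int s = 0; s < nb; ++s) dlogits(ybatch[s], s) -= 1.0;
  dlogits /= nb;
  g.outW = dlogits * c.hidden_act.t();
  g.outB = sum(dlogits, 1);
  mat dhid = net.outW.t() * dlogits;
  if (dropout > 0) dhid %= c.hidden_mask;
  dhid %= conv_to<mat>::from(c.hidden_act > 0);
  dhid = bn_backward(net.denseBN, c.dense_bn, dhid, g.denseG, g.denseBe);
  g.denseW = dhid * c.flat.t();
  mat dflat = net.denseW.t() * dhid;
  // unflatten to (h x T*nb)
  mat dcur(h, T * nb);
  for (int s = 0; s < nb; ++s)
    dcur.cols(s * T, (s + 1) * T - 1) = reshape(dflat.col(s), h, T);
  g.convW.resize(net.convW.size());
  g.convG.resize(net.convW.size());
  g.convBe.resize(net.convW.size());
  for (int l = static_cast<int>(net.convW.size()) - 1; l >= 0; --l) {
    if (dropout > 0) dcur %= c.mask[l];
    dcur %= conv_to<mat>::from(c.act[l] > 0);  // post relu(+mask): >0 iff kept
    dcur = bn_backward(net.convBN[l], c.bn[l], dcur, g.convG[l], g.convBe[l]);
    g.convW[l] = dcur * c.cols[l].t();
    if (l > 0) {
      mat dcols = net.convW[l].t() * dcur;
      int ch_in = static_cast<int>(net.convW[l].n_cols) / net.kernel;
      dcur = col2im(dcols, ch_in, T, net.kernel);
    }
  }
  return g;
}

struct AdamState {
  mat m, v;
  void init(const mat& w) {
    m.zeros(w.n_rows, w.n_cols);
    v.zeros(w.n_rows, w.n_cols);
  }
  void step(mat& w, const mat& grad, double lr, double wd, int t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    mat gr = grad + wd * w;
    m = b1 * m + (1 - b1) * gr;
    v = b2 * v + (1 - b2) * (gr % gr);
    mat mh = m / (1 - std::pow(b1, t));
    mat vh = v / (1 - std::pow(b2, t));
    w -= lr * mh / (sqrt(vh) + eps);
  }
  void step_vec(vec& w, const vec& grad, double lr, int t) {
    mat wm(w);
    step(wm, mat(grad), lr, 0.0, t);
    w = wm.col(0);
  }
};

mat he_init(Rng& rng, int nr, int nc) {
  mat w(nr, nc);
  double s = std::sqrt(2.0 / nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) w(i, j) = s * rng.norm();
  return w;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cnn_init(int n_bands, int n_timesteps, int n_classes, int hidden,
                    int kernel, int n_conv_blocks, double seed) {
  Rng rng(static_cast<uint64_t>(seed));
  Net net;
  net.kernel = kernel;
  net.T = n_timesteps;
  net.bands = n_bands;
  net.hidden = hidden;
  net.n_classes = n_classes;
  int in_ch = n_bands;
  for (int l = 0; l < n_conv_blocks; ++l) {
    net.convW.push_back(he_init(rng, hidden, in_ch * kernel));
    BN bn;
    bn.init(hidden);
    net.convBN.push_back(bn);
    in_ch = hidden;
  }
  net.denseW = he_init(rng, hidden, hidden * n_timesteps);
  net.denseBN.init(hidden);
  net.outW = he_init(rng, n_classes, hidden);
  net.outB = vec(n_classes, fill::zeros);
  return net_to_list(net);
}

// [[Rcpp::export]]
Rcpp::List cnn_train(const arma::mat& X, const arma::ivec& y,
                     const Rcpp::List& weights, int epochs, int batch_size,
                     double lr0, double lr_decay, double weight_decay,
                     double dropout, double seed) {
  Net net = net_from_list(weights);
  int n = static_cast<int>(X.n_rows);
  Rng rng(static_cast<uint64_t>(seed) + 0x9e3779b97f4a7c15ULL);
  size_t L = net.convW.size();
  std::vector<AdamState> stW(L), stG(L), stBe(L);
  for (size_t l = 0; l < L; ++l) {
    stW[l].init(net.convW[l]);
    stG[l].init(net.convBN[l].gamma);
    stBe[l].init(net.convBN[l].beta);
  }
  AdamState stDW, stDG, stDBe, stOW, stOB;
  stDW.init(net.denseW);
  stDG.init(net.denseBN.gamma);
  stDBe.init(net.denseBN.beta);
  stOW.init(net.outW);
  stOB.init(net.outB);

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  vec epoch_loss(epochs, fill::zeros);
  int step = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    double lr = lr0 * std::pow(lr_decay, ep);
    for (int i = n - 1; i > 0; --i) std::swap(order[i], order[rng.upto(i + 1)]);
    double loss_sum = 0.0;
    int n_batches = 0;
    for (int b0 = 0; b0 < n; b0 += batch_size) {
      int nb = std::min(batch_size, n - b0);
      uvec idx(nb);
      for (int i = 0; i < nb; ++i) idx[i] = order[b0 + i];
      mat xin = batch_input(X, idx, net.bands, net.T);
      Cache cache;
      mat probs = forward(net, xin, nb, true, dropout, &rng, &cache);
      uvec yb(nb);
      double loss = 0.0;
      for (int i = 0; i < nb; ++i) {
        yb[i] = static_cast<uword>(y[idx[i]]);
        loss -= std::log(std::max(probs(yb[i], i), 1e-12));
      }
      loss_sum += loss / nb;
      ++n_batches;
      Grads g = backward(net, cache, yb, dropout);
      ++step;
      for (size_t l = 0; l < L; ++l) {
        stW[l].step(net.convW[l], g.convW[l], lr, weight_decay, step);
        stG[l].step_vec(net.convBN[l].gamma, g.convG[l], lr, step);
        stBe[l].step_vec(net.convBN[l].beta, g.convBe[l], lr, step);
      }
      stDW.step(net.denseW, g.denseW, lr, weight_decay, step);
      stDG.step_vec(net.denseBN.gamma, g.denseG, lr, step);
      stDBe.step_vec(net.denseBN.beta, g.denseBe, lr, step);
      stOW.step(net.outW, g.outW, lr, weight_decay, step);
      stOB.step_vec(net.outB, g.outB, lr, step);
    }
    epoch_loss[ep] = loss_sum / std::max(n_batches, 1);
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("weights") = net_to_list(net),
                            Rcpp::Named("epoch_loss") = epoch_loss);
}

// [[Rcpp::export]]
arma::mat cnn_predict(const arma::mat& X, const Rcpp::List& weights) {
  Net net = net_from_list(weights);
  int n = static_cast<int>(X.n_rows);
  mat out(n, net.n_classes);
  int chunk = 256;
  for (int b0 = 0; b0 < n; b0 += chunk) {
    int nb = std::min(chunk, n - b0);
    uvec idx(nb);
    for (int i = 0; i < nb; ++i) idx[i] = b0 + i;
    mat xin = batch_input(X, idx, net.bands, net.T);
    mat probs = forward(net, xin, nb, false, 0.0, nullptr, nullptr);
    out.rows(b0, b0 + nb - 1) = probs.t();
  }
  return out;
}
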