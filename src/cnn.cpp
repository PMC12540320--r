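// Single-precision training backend for the 1-D convolutional classifiers.
//
// Layout conventions shared with the R level:
//  * a batch of N spectra of length L is carried through conv layers as an
//    (N*L) x C matrix A with row index r = n*L + l (l fastest);
//  * conv weights for a layer are (3*C_in) x C_out, the three kernel taps
//    stacked as [o=-1 | o=0 | o=+1] blocks of C_in columns, zero padding;
//  * flattening maps A(n*L + l, c) to F(n, c*L + l);
//  * the SE block sits after the last convolution's ReLU.
//
// All randomness (batch sampling, dropout) comes from R's RNG so training
// is reproducible from set.seed().

#include <RcppArmadillo.h>
#if defined(__SSE3__)
#include <pmmintrin.h>
// Converged nets produce denormal-range float gradients, which stall the
// FPU; flush-to-zero mode is the conventional deep-learning runtime
// setting and changes results only below ~1e-38.
struct FlushDenormals {
  unsigned int ftz, daz;
  FlushDenormals() : ftz(_MM_GET_FLUSH_ZERO_MODE()),
                     daz(_MM_GET_DENORMALS_ZERO_MODE()) {
    _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
    _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
  }
  ~FlushDenormals() {
    _MM_SET_FLUSH_ZERO_MODE(ftz);
    _MM_SET_DENORMALS_ZERO_MODE(daz);
  }
};
#else
struct FlushDenormals {};
#endif
using namespace Rcpp;
using arma::fmat;
using arma::frowvec;
using arma::fvec;

namespace {

struct Net {
  int n_conv;
  std::vector<int> channels;   // per conv layer output channels
  int L;                       // bands
  int fc_width;
  int n_classes;
  bool use_se;
  int se_mid;                  // bottleneck width C/r (>=1)
  std::vector<fmat> conv_w;    // (3*C_in) x C_out
  std::vector<fvec> conv_b;
  fmat fc1_w; fvec fc1_b;      // (L*C_last) x fc_width
  fmat fc2_w; fvec fc2_b;      // fc_width x n_classes
  fmat se_w1; fvec se_b1;      // C x mid
  fmat se_w2; fvec se_b2;      // mid x C
};

fmat as_f(NumericMatrix m) {
  arma::mat d(m.begin(), m.nrow(), m.ncol(), false);
  return arma::conv_to<fmat>::from(d);
}
fvec as_fv(NumericVector v) {
  arma::vec d(v.begin(), v.size(), false);
  return arma::conv_to<fvec>::from(d);
}
NumericMatrix to_R(const fmat& m) {
  arma::mat d = arma::conv_to<arma::mat>::from(m);
  NumericMatrix out(d.n_rows, d.n_cols);
  std::copy(d.begin(), d.end(), out.begin());
  return out;
}
NumericVector to_Rv(const fvec& v) {
  arma::vec d = arma::conv_to<arma::vec>::from(v);
  return NumericVector(d.begin(), d.end());
}

Net build_net(const List& params, const List& conf) {
  Net net;
  net.n_conv = as<int>(conf["n_conv"]);
  net.channels = as<std::vector<int>>(conf["channels"]);
  net.L = as<int>(conf["n_bands"]);
  net.fc_width = as<int>(conf["fc_width"]);
  net.n_classes = as<int>(conf["n_classes"]);
  net.use_se = as<bool>(conf["use_se"]);
  List cw = params["conv_w"], cb = params["conv_b"];
  for (int l = 0; l < net.n_conv; ++l) {
    net.conv_w.push_back(as_f(cw[l]));
    net.conv_b.push_back(as_fv(cb[l]));
  }
  net.fc1_w = as_f(params["fc1_w"]); net.fc1_b = as_fv(params["fc1_b"]);
  net.fc2_w = as_f(params["fc2_w"]); net.fc2_b = as_fv(params["fc2_b"]);
  if (net.use_se) {
    net.se_w1 = as_f(params["se_w1"]); net.se_b1 = as_fv(params["se_b1"]);
    net.se_w2 = as_f(params["se_w2"]); net.se_b2 = as_fv(params["se_b2"]);
    net.se_mid = net.se_w1.n_cols;
  } else net.se_mid = 0;
  return net;
}

List net_params(const Net& net) {
  List cw(net.n_conv), cb(net.n_conv);
  for (int l = 0; l < net.n_conv; ++l) {
    cw[l] = to_R(net.conv_w[l]);
    cb[l] = to_Rv(net.conv_b[l]);
  }
  List out = List::create(
    _["conv_w"] = cw, _["conv_b"] = cb,
    _["fc1_w"] = to_R(net.fc1_w), _["fc1_b"] = to_Rv(net.fc1_b),
    _["fc2_w"] = to_R(net.fc2_w), _["fc2_b"] = to_Rv(net.fc2_b));
  if (net.use_se) {
    out["se_w1"] = to_R(net.se_w1); out["se_b1"] = to_Rv(net.se_b1);
    out["se_w2"] = to_R(net.se_w2); out["se_b2"] = to_Rv(net.se_b2);
  }
  return out;
}

// im2col for kernel 3, stride 1, zero padding 1.
fmat im2col3(const fmat& A, int N, int L) {
  const int C = A.n_cols, NL = N * L;
  fmat M(NL, 3 * C, arma::fill::zeros);
  // o = -1 : M(r) = A(r-1), invalid at l == 0
  M.submat(1, 0, NL - 1, C - 1) = A.rows(0, NL - 2);
  // o = 0
  M.cols(C, 2 * C - 1) = A;
  // o = +1 : M(r) = A(r+1), invalid at l == L-1
  M.submat(0, 2 * C, NL - 2, 3 * C - 1) = A.rows(1, NL - 1);
  for (int n = 0; n < N; ++n) {
    M(n * L, arma::span(0, C - 1)).zeros();
    M(n * L + L - 1, arma::span(2 * C, 3 * C - 1)).zeros();
  }
  return M;
}

// adjoint of im2col3
fmat col2im3(fmat dM, int N, int L) {
  const int C = dM.n_cols / 3, NL = N * L;
  for (int n = 0; n < N; ++n) {
    dM(n * L, arma::span(0, C - 1)).zeros();
    dM(n * L + L - 1, arma::span(2 * C, 3 * C - 1)).zeros();
  }
  fmat dA = dM.cols(C, 2 * C - 1);
  dA.rows(0, NL - 2) += dM.submat(1, 0, NL - 1, C - 1);
  dA.rows(1, NL - 1) += dM.submat(0, 2 * C, NL - 2, 3 * C - 1);
  return dA;
}

fmat flatten_act(const fmat& A, int N, int L) {
  const int C = A.n_cols;
  fmat F(N, L * C);
  for (int c = 0; c < C; ++c) {
    fmat tmp = arma::reshape(A.col(c), L, N);
    F.cols(c * L, (c + 1) * L - 1) = tmp.t();
  }
  return F;
}

fmat unflatten_act(const fmat& F, int N, int L, int C) {
  fmat A(N * L, C);
  for (int c = 0; c < C; ++c) {
    fmat tmp = F.cols(c * L, (c + 1) * L - 1).t();  // L x N
    A.col(c) = arma::vectorise(tmp);
  }
  return A;
}

// per-sample channel means: (N*L) x C -> N x C
fmat squeeze_means(const fmat& A, int N, int L) {
  const int C = A.n_cols;
  fmat S(N, C);
  for (int c = 0; c < C; ++c)
    S.col(c) = arma::mean(arma::reshape(A.col(c), L, N), 0).t();
  return S;
}

struct Cache {
  std::vector<fmat> conv_in;   // im2col inputs
  std::vector<fmat> conv_act;  // post-ReLU activations
  fmat se_in, se_s, se_h, se_g;
  fmat flat, fc1_act, scores;
  fmat drop_mask;
};

// forward pass; X is N x L (standardized spectra)
fmat forward(const Net& net, const fmat& X, Cache* cache,
             double dropout_p, bool training) {
  const int N = X.n_rows, L = net.L;
  fmat A = arma::reshape(X.t(), (arma::uword)N * L, 1);  // r = n*L + l
  for (int l = 0; l < net.n_conv; ++l) {
    fmat M = im2col3(A, N, L);
    fmat Z = M * net.conv_w[l];
    Z.each_row() += net.conv_b[l].t();
    A = arma::clamp(Z, 0.0f, std::numeric_limits<float>::max());
    if (cache) { cache->conv_in.push_back(std::move(M));
                 cache->conv_act.push_back(A); }
  }
  if (net.use_se) {
    fmat S = squeeze_means(A, N, L);
    fmat H = S * net.se_w1; H.each_row() += net.se_b1.t();
    H = arma::clamp(H, 0.0f, std::numeric_limits<float>::max());
    fmat G = H * net.se_w2; G.each_row() += net.se_b2.t();
    G = 1.0f / (1.0f + arma::exp(-G));
    if (cache) { cache->se_in = A; cache->se_s = S; cache->se_h = H;
                 cache->se_g = G; }
    // scale channel c of sample n by G(n, c)
    for (int c = 0; c < (int)A.n_cols; ++c) {
      fmat tmp = arma::reshape(A.col(c), L, N);
      tmp.each_row() %= G.col(c).t();
      A.col(c) = arma::vectorise(tmp);
    }
  }
  fmat F = flatten_act(A, N, L);
  fmat H1 = F * net.fc1_w; H1.each_row() += net.fc1_b.t();
  H1 = arma::clamp(H1, 0.0f, std::numeric_limits<float>::max());
  if (training && dropout_p > 0) {
    fmat mask(H1.n_rows, H1.n_cols);
    const float keep = 1.0f - (float)dropout_p;
    for (arma::uword i = 0; i < mask.n_elem; ++i)
      mask(i) = (unif_rand() < dropout_p) ? 0.0f : 1.0f / keep;
    H1 %= mask;
    if (cache) cache->drop_mask = std::move(mask);
  }
  fmat S2 = H1 * net.fc2_w; S2.each_row() += net.fc2_b.t();
  if (cache) { cache->flat = std::move(F); cache->fc1_act = std::move(H1);
               cache->scores = S2; }
  return S2;
}

fmat softmax_rows(fmat Z) {
  Z.each_col() -= arma::max(Z, 1);
  Z = arma::exp(Z);
  Z.each_col() /= arma::sum(Z, 1);
  return Z;
}

double mean_ce(const fmat& P, const std::vector<int>& y,
               const arma::uvec& idx) {
  double s = 0;
  for (arma::uword i = 0; i < idx.n_elem; ++i)
    s += -std::log(std::max(P(i, y[idx[i]]), 1e-12f));
  return s / idx.n_elem;
}

struct Adam {
  std::vector<fmat> m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const std::vector<fmat*>& ps) {
    for (auto p : ps) { m.emplace_back(arma::size(*p), arma::fill::zeros);
                        v.emplace_back(arma::size(*p), arma::fill::zeros); }
  }
  void step(std::vector<fmat*>& ps, std::vector<fmat>& gs, double lr) {
    ++t;
    const double bc1 = 1 - std::pow(b1, (double)t);
    const double bc2 = 1 - std::pow(b2, (double)t);
    for (size_t i = 0; i < ps.size(); ++i) {
      m[i] = (float)b1 * m[i] + (float)(1 - b1) * gs[i];
      v[i] = (float)b2 * v[i] + (float)(1 - b2) * arma::square(gs[i]);
      *ps[i] -= (float)(lr / bc1) * m[i] /
        (arma::sqrt(v[i] / (float)bc2) + (float)eps);
    }
  }
};


// Forward + backward on one batch; returns mean CE loss and gradients in
// the order [conv_w..., fc1_w, fc2_w, (se_w1, se_w2), conv_b..., fc1_b,
// fc2_b, (se_b1, se_b2)].
double compute_grads(const Net& net, const fmat& Xb,
                     const std::vector<int>& yb, double dropout_p,
                     double l1, std::vector<fmat>& grads) {
  const int batch = Xb.n_rows, L = net.L;
  Cache cache;
  fmat scores = forward(net, Xb, &cache, dropout_p, true);
  fmat P = softmax_rows(scores);
  double loss = 0;
  for (int i = 0; i < batch; ++i)
    loss += -std::log(std::max(P(i, yb[i]), 1e-12f));
  loss /= batch;

  fmat dS = P;
  for (int i = 0; i < batch; ++i) dS(i, yb[i]) -= 1.0f;
  dS /= (float)batch;

  fmat g_fc2_w = cache.fc1_act.t() * dS;
  fmat g_fc2_b = arma::sum(dS, 0).t();
  fmat dH1 = dS * net.fc2_w.t();
  if (dropout_p > 0) dH1 %= cache.drop_mask;
  dH1 %= arma::conv_to<fmat>::from(cache.fc1_act > 0);

  fmat g_fc1_w = cache.flat.t() * dH1;
  fmat g_fc1_b = arma::sum(dH1, 0).t();
  fmat dF = dH1 * net.fc1_w.t();
  const int C_last = net.channels[net.n_conv - 1];
  fmat dA = unflatten_act(dF, batch, L, C_last);

  fmat g_se_w1, g_se_b1, g_se_w2, g_se_b2;
  if (net.use_se) {
    // out = A .* gates ; dA_pre = dOut .* gates ; dG = sum_l dOut .* A
    fmat dG(batch, C_last);
    fmat dA_pre(arma::size(dA));
    for (int c = 0; c < C_last; ++c) {
      fmat dOc = arma::reshape(dA.col(c), L, batch);        // L x N
      fmat Ac = arma::reshape(cache.se_in.col(c), L, batch);
      dG.col(c) = arma::sum(dOc % Ac, 0).t();
      dOc.each_row() %= cache.se_g.col(c).t();
      dA_pre.col(c) = arma::vectorise(dOc);
    }
    fmat dZ2 = dG % cache.se_g % (1.0f - cache.se_g);   // sigmoid'
    g_se_w2 = cache.se_h.t() * dZ2;
    g_se_b2 = arma::sum(dZ2, 0).t();
    fmat dH = dZ2 * net.se_w2.t();
    dH %= arma::conv_to<fmat>::from(cache.se_h > 0);
    g_se_w1 = cache.se_s.t() * dH;
    g_se_b1 = arma::sum(dH, 0).t();
    fmat dSq = dH * net.se_w1.t();        // N x C, grad wrt channel means
    dSq /= (float)L;
    for (int c = 0; c < C_last; ++c) {
      fmat add(L, batch);
      add.each_row() = dSq.col(c).t();
      dA_pre.col(c) += arma::vectorise(add);
    }
    dA = std::move(dA_pre);
  }

  std::vector<fmat> g_conv_w(net.n_conv), g_conv_b(net.n_conv);
  for (int l = net.n_conv - 1; l >= 0; --l) {
    dA %= arma::conv_to<fmat>::from(cache.conv_act[l] > 0);
    g_conv_w[l] = cache.conv_in[l].t() * dA;
    g_conv_b[l] = arma::sum(dA, 0).t();
    if (l > 0) dA = col2im3(dA * net.conv_w[l].t(), batch, L);
  }

  grads.clear();
  for (int l = 0; l < net.n_conv; ++l) grads.push_back(std::move(g_conv_w[l]));
  grads.push_back(std::move(g_fc1_w));
  grads.push_back(std::move(g_fc2_w));
  if (net.use_se) { grads.push_back(std::move(g_se_w1));
                    grads.push_back(std::move(g_se_w2)); }
  if (l1 > 0) {
    size_t i = 0;
    for (int l = 0; l < net.n_conv; ++l)
      grads[i++] += (float)l1 * arma::sign(net.conv_w[l]);
    grads[i++] += (float)l1 * arma::sign(net.fc1_w);
    grads[i++] += (float)l1 * arma::sign(net.fc2_w);
    if (net.use_se) {
      grads[i++] += (float)l1 * arma::sign(net.se_w1);
      grads[i++] += (float)l1 * arma::sign(net.se_w2);
    }
  }
  for (int l = 0; l < net.n_conv; ++l) grads.push_back(std::move(g_conv_b[l]));
  grads.push_back(std::move(g_fc1_b));
  grads.push_back(std::move(g_fc2_b));
  if (net.use_se) { grads.push_back(std::move(g_se_b1));
                    grads.push_back(std::move(g_se_b2)); }
  return loss;
}

}  // namespace

// [[Rcpp::export(name = ".cnn_forward_cpp")]]
NumericMatrix cnn_forward_cpp(List params, List conf, NumericMatrix X) {
  FlushDenormals ftz_guard;
  Net net = build_net(params, conf);
  fmat Xf = as_f(X);
  const int chunk = 512;
  fmat scores(Xf.n_rows, net.n_classes);
  for (int s = 0; s < (int)Xf.n_rows; s += chunk) {
    int e = std::min<int>(s + chunk, Xf.n_rows) - 1;
    scores.rows(s, e) = forward(net, Xf.rows(s, e), nullptr, 0, false);
  }
  return to_R(scores);
}

// [[Rcpp::export(name = ".cnn_train_cpp")]]
List cnn_train_cpp(List params, List conf, NumericMatrix X_train,
                   IntegerVector y_train, Nullable<NumericMatrix> X_val,
                   Nullable<IntegerVector> y_val) {
  FlushDenormals ftz_guard;
  Net net = build_net(params, conf);
  const int L = net.L;
  const double lr0 = as<double>(conf["learning_rate"]);
  const double lr_decay = as<double>(conf["lr_decay"]);
  const int warmup = as<int>(conf["lr_warmup"]);
  const int batch = as<int>(conf["batch_size"]);
  const int iterations = as<int>(conf["iterations"]);
  const double l1 = as<double>(conf["l1_lambda"]);
  const double dropout_p = as<double>(conf["dropout_p"]);
  const int eval_every = as<int>(conf["eval_every"]);
  const int patience = as<int>(conf["patience"]);  // <= 0 : no early stop
  const double max_norm = as<double>(conf["max_grad_norm"]);  // <= 0 : off

  fmat X = as_f(X_train);
  const int n = X.n_rows;
  std::vector<int> y(n);
  for (int i = 0; i < n; ++i) y[i] = y_train[i] - 1;

  bool has_val = X_val.isNotNull() && y_val.isNotNull();
  fmat Xv; std::vector<int> yv;
  if (has_val) {
    Xv = as_f(NumericMatrix(X_val));
    IntegerVector yvr(y_val);
    yv.resize(yvr.size());
    for (int i = 0; i < (int)yv.size(); ++i) yv[i] = yvr[i] - 1;
  }

  std::vector<fmat*> ps;
  for (int l = 0; l < net.n_conv; ++l) ps.push_back(&net.conv_w[l]);
  ps.push_back(&net.fc1_w); ps.push_back(&net.fc2_w);
  if (net.use_se) { ps.push_back(&net.se_w1); ps.push_back(&net.se_w2); }
  // biases handled as fmat references via wrappers
  std::vector<fvec*> bs;
  for (int l = 0; l < net.n_conv; ++l) bs.push_back(&net.conv_b[l]);
  bs.push_back(&net.fc1_b); bs.push_back(&net.fc2_b);
  if (net.use_se) { bs.push_back(&net.se_b1); bs.push_back(&net.se_b2); }
  std::vector<fmat> bmat(bs.size());
  for (size_t i = 0; i < bs.size(); ++i) bmat[i] = fmat(*bs[i]);
  std::vector<fmat*> all_ps = ps;
  for (auto& b : bmat) all_ps.push_back(&b);

  Adam opt;
  opt.init(all_ps);

  std::vector<double> loss_trace;
  loss_trace.reserve(iterations);
  std::vector<double> val_loss, val_acc; std::vector<int> val_iter;
  double best_val = arma::datum::inf;
  int best_iter = 0, bad_evals = 0, iter_done = 0;
  bool have_best = false;
  List best_params;

  auto eval_val = [&](void) -> std::pair<double, double> {
    const int chunk = 512;
    double s = 0; int correct = 0;
    for (int st = 0; st < (int)Xv.n_rows; st += chunk) {
      int e = std::min<int>(st + chunk, Xv.n_rows) - 1;
      fmat P = softmax_rows(forward(net, Xv.rows(st, e), nullptr, 0, false));
      for (int i = st; i <= e; ++i) {
        s += -std::log(std::max(P(i - st, yv[i]), 1e-12f));
        if ((int)arma::index_max(P.row(i - st)) == yv[i]) ++correct;
      }
    }
    return {s / Xv.n_rows, (double)correct / Xv.n_rows};
  };

  for (int it = 1; it <= iterations; ++it) {
    // sample a minibatch (with replacement) from R's RNG
    arma::uvec idx(batch);
    for (int i = 0; i < batch; ++i)
      idx[i] = (arma::uword)(unif_rand() * n) % n;
    fmat Xb(batch, L);
    for (int i = 0; i < batch; ++i) Xb.row(i) = X.row(idx[i]);

    std::vector<int> yb(batch);
    for (int i = 0; i < batch; ++i) yb[i] = y[idx[i]];
    std::vector<fmat> grads;
    loss_trace.push_back(compute_grads(net, Xb, yb, dropout_p, l1, grads));

    if (max_norm > 0) {
      double sq = 0;
      for (auto& g : grads) sq += arma::accu(arma::square(g));
      const double nrm = std::sqrt(sq);
      if (nrm > max_norm) {
        const float sc = (float)(max_norm / nrm);
        for (auto& g : grads) g *= sc;
      }
    }
    double lr_t = lr0 / (1.0 + lr_decay * it);
    if (warmup > 0 && it < warmup) lr_t *= (double)it / warmup;
    opt.step(all_ps, grads, lr_t);
    for (size_t i = 0; i < bs.size(); ++i) *bs[i] = bmat[i].col(0);
    iter_done = it;

    if (has_val && (it % eval_every == 0 || it == iterations)) {
      auto vl = eval_val();
      val_iter.push_back(it);
      val_loss.push_back(vl.first);
      val_acc.push_back(vl.second);
      if (patience > 0) {
        if (vl.first < best_val - 1e-5) {
          best_val = vl.first; best_iter = it; bad_evals = 0;
          best_params = net_params(net); have_best = true;
        } else if (++bad_evals >= patience) break;
      }
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    _["params"] = (patience > 0 && have_best)
      ? best_params : net_params(net),
    _["loss_trace"] = NumericVector(loss_trace.begin(), loss_trace.end()),
    _["val_iter"] = IntegerVector(val_iter.begin(), val_iter.end()),
    _["val_loss"] = NumericVector(val_loss.begin(), val_loss.end()),
    _["val_accuracy"] = NumericVector(val_acc.begin(), val_acc.end()),
    _["iterations_run"] = iter_done,
    _["best_iter"] = best_iter);
  return out;
}

// [[Rcpp::export(name = ".cnn_grad_cpp")]]
List cnn_grad_cpp(List params, List conf, NumericMatrix X,
                  IntegerVector y) {
  Net net = build_net(params, conf);
  fmat Xf = as_f(X);
  std::vector<int> yb(y.size());
  for (int i = 0; i < (int)yb.size(); ++i) yb[i] = y[i] - 1;
  std::vector<fmat> grads;
  double loss = compute_grads(net, Xf, yb, 0.0, 0.0, grads);
  List gw(net.n_conv), gb(net.n_conv);
  size_t i = 0;
  for (int l = 0; l < net.n_conv; ++l) gw[l] = to_R(grads[i++]);
  List out = List::create(_["loss"] = loss, _["conv_w"] = gw);
  out["fc1_w"] = to_R(grads[i++]);
  out["fc2_w"] = to_R(grads[i++]);
  if (net.use_se) { out["se_w1"] = to_R(grads[i++]);
                    out["se_w2"] = to_R(grads[i++]); }
  for (int l = 0; l < net.n_conv; ++l) gb[l] = to_R(grads[i++]);
  out["conv_b"] = gb;
  out["fc1_b"] = to_R(grads[i++]);
  out["fc2_b"] = to_R(grads[i++]);
  if (net.use_se) { out["se_b1"] = to_R(grads[i++]);
                    out["se_b2"] = to_R(grads[i++]); }
  return out;
}
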