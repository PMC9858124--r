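// Two-layer LSTM binary sequence classifier: forward pass, full BPTT
// gradients, and an Adam training loop with validation checkpointing.
// Scalar input per time step; the linear readout consumes only the last
// hidden state of layer 2, squashed by a sigmoid for binary cross-entropy.
//
// Gate layout in the stacked weight matrices is (i, f, g, o), each block of
// `hidden` rows: W* maps the layer input, U* the previous hidden state.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Weights {
  mat W1, U1, W2, U2;   // (4H x in), (4H x H)
  vec b1, b2, wout;     // (4H), (4H), (H)
  double bout;
};

Weights weights_from_list(const Rcpp::List &wl) {
  Weights w;
  w.W1 = Rcpp::as<mat>(wl["W1"]);
  w.U1 = Rcpp::as<mat>(wl["U1"]);
  w.b1 = Rcpp::as<vec>(wl["b1"]);
  w.W2 = Rcpp::as<mat>(wl["W2"]);
  w.U2 = Rcpp::as<mat>(wl["U2"]);
  w.b2 = Rcpp::as<vec>(wl["b2"]);
  w.wout = Rcpp::as<vec>(wl["wout"]);
  w.bout = Rcpp::as<double>(wl["bout"]);
  return w;
}

Rcpp::List weights_to_list(const Weights &w) {
  return Rcpp::List::create(
      Rcpp::Named("W1") = w.W1, Rcpp::Named("U1") = w.U1,
      Rcpp::Named("b1") = w.b1, Rcpp::Named("W2") = w.W2,
      Rcpp::Named("U2") = w.U2, Rcpp::Named("b2") = w.b2,
      Rcpp::Named("wout") = w.wout, Rcpp::Named("bout") = w.bout);
}

inline mat sigm(const mat &x) { return 1.0 / (1.0 + exp(-x)); }

// Cached per-timestep activations of one layer for BPTT.
struct LayerCache {
  cube i, f, g, o, tc, c, h;  // each: B x H x T
};

// Forward pass of one LSTM layer over a batch. X slices are the layer
// inputs per time step (B x in). Fills the cache when `cache` is non-null.
void layer_forward(const cube &X, const mat &W, const mat &U, const vec &b,
                   int H, LayerCache *cache, mat &h_last) {
  const uword B = X.n_rows, T = X.n_slices;
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  mat bt = repmat(b.t(), B, 1);
  for (uword t = 0; t < T; ++t) {
    mat a = X.slice(t) * W.t() + h * U.t() + bt;  // B x 4H
    mat gi = sigm(a.cols(0, H - 1));
    mat gf = sigm(a.cols(H, 2 * H - 1));
    mat gg = tanh(a.cols(2 * H, 3 * H - 1));
    mat go = sigm(a.cols(3 * H, 4 * H - 1));
    c = gf % c + gi % gg;
    mat tc = tanh(c);
    h = go % tc;
    if (cache) {
      cache->i.slice(t) = gi; cache->f.slice(t) = gf;
      cache->g.slice(t) = gg; cache->o.slice(t) = go;
      cache->tc.slice(t) = tc; cache->c.slice(t) = c;
      cache->h.slice(t) = h;
    }
  }
  h_last = h;
}

void alloc_cache(LayerCache &lc, uword B, int H, uword T) {
  lc.i.set_size(B, H, T); lc.f.set_size(B, H, T); lc.g.set_size(B, H, T);
  lc.o.set_size(B, H, T); lc.tc.set_size(B, H, T); lc.c.set_size(B, H, T);
  lc.h.set_size(B, H, T);
}

// Backward pass through one layer. dh_last seeds the gradient at the final
// step; dh_seq (B x H x T, may be empty) adds per-step gradients flowing in
// from the layer above. Returns input gradients per step in dX and
// accumulates parameter gradients.
void layer_backward(const cube &X, const LayerCache &lc, const mat &W,
                    const mat &U, int H, const mat &dh_last,
                    const cube *dh_seq, cube &dX, mat &dW, mat &dU, vec &db) {
  const uword B = X.n_rows, T = X.n_slices;
  mat dh = dh_last;
  mat dc(B, H, fill::zeros);
  dW.zeros(); dU.zeros(); db.zeros();
  for (uword t = T; t-- > 0;) {
    if (dh_seq && t + 1 < T) dh += dh_seq->slice(t);  // upper-layer grad
    const mat &gi = lc.i.slice(t), &gf = lc.f.slice(t), &gg = lc.g.slice(t),
              &go = lc.o.slice(t), &tc = lc.tc.slice(t);
    mat c_prev = (t == 0) ? mat(B, H, fill::zeros) : lc.c.slice(t - 1);
    mat h_prev = (t == 0) ? mat(B, H, fill::zeros) : lc.h.slice(t - 1);
    mat d_o = dh % tc;
    dc += dh % go % (1.0 - tc % tc);
    mat d_i = dc % gg;
    mat d_g = dc % gi;
    mat d_f = dc % c_prev;
    mat da(B, 4 * H);
    da.cols(0, H - 1) = d_i % gi % (1.0 - gi);
    da.cols(H, 2 * H - 1) = d_f % gf % (1.0 - gf);
    da.cols(2 * H, 3 * H - 1) = d_g % (1.0 - gg % gg);
    da.cols(3 * H, 4 * H - 1) = d_o % go % (1.0 - go);
    dW += da.t() * X.slice(t);
    dU += da.t() * h_prev;
    db += sum(da, 0).t();
    dX.slice(t) = da * W;
    dh = da * U;          // gradient to h_{t-1}
    dc = dc % gf;         // gradient to c_{t-1}
  }
  // At t = T-1 the upper-layer gradient for the last step was merged into
  // dh_last by the caller (see full_backward), so nothing is lost here.
}

// Full forward+backward over a batch; returns mean BCE loss and gradients.
double loss_and_grads(const Weights &w, const mat &Xb, const vec &yb,
                      Weights &grad) {
  const uword B = Xb.n_rows, T = Xb.n_cols;
  const int H = w.U1.n_cols;
  cube X1(B, 1, T);
  for (uword t = 0; t < T; ++t) X1.slice(t) = Xb.col(t);
  LayerCache l1, l2;
  alloc_cache(l1, B, H, T);
  alloc_cache(l2, B, H, T);
  mat h1_last, h2_last;
  layer_forward(X1, w.W1, w.U1, w.b1, H, &l1, h1_last);
  layer_forward(l1.h, w.W2, w.U2, w.b2, H, &l2, h2_last);

  vec z = h2_last * w.wout + w.bout;
  vec p = 1.0 / (1.0 + exp(-z));
  const double eps = 1e-12;
  double loss = -mean(yb % log(p + eps) + (1.0 - yb) % log(1.0 - p + eps));

  vec dz = (p - yb) / static_cast<double>(B);
  grad.wout = h2_last.t() * dz;
  grad.bout = accu(dz);
  mat dh2_last = dz * w.wout.t();  // B x H

  grad.W1.zeros(size(w.W1)); grad.U1.zeros(size(w.U1));
  grad.b1.zeros(size(w.b1)); grad.W2.zeros(size(w.W2));
  grad.U2.zeros(size(w.U2)); grad.b2.zeros(size(w.b2));

  cube dX2(B, H, T), dX1(B, 1, T);
  layer_backward(l1.h, l2, w.W2, w.U2, H, dh2_last, nullptr, dX2,
                 grad.W2, grad.U2, grad.b2);
  // dX2 slices are the gradients w.r.t. h1_t; the last one seeds dh and the
  // earlier ones are merged step-by-step inside layer_backward.
  layer_backward(X1, l1, w.W1, w.U1, H, dX2.slice(T - 1), &dX2, dX1,
                 grad.W1, grad.U1, grad.b1);
  return loss;
}

vec forward_probs(const Weights &w, const mat &X) {
  const uword B = X.n_rows, T = X.n_cols;
  const int H = w.U1.n_cols;
  cube X1(B, 1, T);
  for (uword t = 0; t < T; ++t) X1.slice(t) = X.col(t);
  mat h1(B, H, fill::zeros), c1(B, H, fill::zeros);
  mat h2(B, H, fill::zeros), c2(B, H, fill::zeros);
  mat b1t = repmat(w.b1.t(), B, 1), b2t = repmat(w.b2.t(), B, 1);
  for (uword t = 0; t < T; ++t) {
    mat a = X1.slice(t) * w.W1.t() + h1 * w.U1.t() + b1t;
    mat gi = sigm(a.cols(0, H - 1)), gf = sigm(a.cols(H, 2 * H - 1));
    mat gg = tanh(a.cols(2 * H, 3 * H - 1)), go = sigm(a.cols(3 * H, 4 * H - 1));
    c1 = gf % c1 + gi % gg;
    h1 = go % tanh(c1);
    mat a2 = h1 * w.W2.t() + h2 * w.U2.t() + b2t;
    mat gi2 = sigm(a2.cols(0, H - 1)), gf2 = sigm(a2.cols(H, 2 * H - 1));
    mat gg2 = tanh(a2.cols(2 * H, 3 * H - 1)), go2 = sigm(a2.cols(3 * H, 4 * H - 1));
    c2 = gf2 % c2 + gi2 % gg2;
    h2 = go2 % tanh(c2);
  }
  vec z = h2 * w.wout + w.bout;
  return 1.0 / (1.0 + exp(-z));
}

struct AdamState {
  Weights m, v;
  long step = 0;
  void init(const Weights &w) {
    m.W1.zeros(size(w.W1)); m.U1.zeros(size(w.U1)); m.b1.zeros(size(w.b1));
    m.W2.zeros(size(w.W2)); m.U2.zeros(size(w.U2)); m.b2.zeros(size(w.b2));
    m.wout.zeros(size(w.wout)); m.bout = 0;
    v = m;
  }
};

inline void adam_one(mat &w, mat &m, mat &v, const mat &g, double lr,
                     double bc1, double bc2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  w -= lr * (m / bc1) / (sqrt(v / bc2) + 1e-8);
}
inline void adam_one(vec &w, vec &m, vec &v, const vec &g, double lr,
                     double bc1, double bc2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  w -= lr * (m / bc1) / (sqrt(v / bc2) + 1e-8);
}

void adam_update(Weights &w, AdamState &s, const Weights &g, double lr) {
  s.step += 1;
  double bc1 = 1.0 - std::pow(0.9, (double)s.step);
  double bc2 = 1.0 - std::pow(0.999, (double)s.step);
  adam_one(w.W1, s.m.W1, s.v.W1, g.W1, lr, bc1, bc2);
  adam_one(w.U1, s.m.U1, s.v.U1, g.U1, lr, bc1, bc2);
  adam_one(w.b1, s.m.b1, s.v.b1, g.b1, lr, bc1, bc2);
  adam_one(w.W2, s.m.W2, s.v.W2, g.W2, lr, bc1, bc2);
  adam_one(w.U2, s.m.U2, s.v.U2, g.U2, lr, bc1, bc2);
  adam_one(w.b2, s.m.b2, s.v.b2, g.b2, lr, bc1, bc2);
  adam_one(w.wout, s.m.wout, s.v.wout, g.wout, lr, bc1, bc2);
  {
    double &m = s.m.bout, &v = s.v.bout;
    m = 0.9 * m + 0.1 * g.bout;
    v = 0.999 * v + 0.001 * g.bout * g.bout;
    w.bout -= lr * (m / bc1) / (std::sqrt(v / bc2) + 1e-8);
  }
}

double eval_loss(const Weights &w, const mat &X, const vec &y) {
  vec p = forward_probs(w, X);
  const double eps = 1e-12;
  return -mean(y % log(p + eps) + (1.0 - y) % log(1.0 - p + eps));
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List lstm_train_cpp(const arma::mat &Xtr, const arma::vec &ytr,
                          const arma::mat &Xval, const arma::vec &yval,
                          Rcpp::List init_weights,
                          const arma::imat &batch_order, int batch_size,
                          double lr) {
  Weights w = weights_from_list(init_weights);
  AdamState adam;
  adam.init(w);
  const int epochs = batch_order.n_rows;
  const uword n = Xtr.n_rows;
  Weights best = w;
  double best_val = datum::inf;
  int best_epoch = -1;
  std::vector<double> train_curve, val_curve;

  Weights grad = w;  // shape template
  for (int e = 0; e < epochs; ++e) {
    double epoch_loss = 0;
    uword nb = 0;
    for (uword s = 0; s < n; s += batch_size, ++nb) {
      uword eidx = std::min<uword>(s + batch_size, n);
      uvec idx(eidx - s);
      for (uword k = s; k < eidx; ++k)
        idx[k - s] = (uword)batch_order(e, k) - 1;  // 1-based from R
      mat Xb = Xtr.rows(idx);
      vec yb = ytr.elem(idx);
      double l = loss_and_grads(w, Xb, yb, grad);
      if (!std::isfinite(l)) Rcpp::stop("non-finite training loss");
      adam_update(w, adam, grad, lr);
      epoch_loss += l;
    }
    train_curve.push_back(epoch_loss / nb);
    double vl = eval_loss(w, Xval, yval);
    val_curve.push_back(vl);
    if (vl < best_val) {  // validation checkpoint
      best_val = vl;
      best = w;
      best_epoch = e + 1;
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = weights_to_list(best),
      Rcpp::Named("final_weights") = weights_to_list(w),
      Rcpp::Named("train_loss") = train_curve,
      Rcpp::Named("val_loss") = val_curve,
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("best_val_loss") = best_val);
}

// [[Rcpp::export]]
arma::vec lstm_predict_cpp(Rcpp::List weights, const arma::mat &X) {
  Weights w = weights_from_list(weights);
  return forward_probs(w, X);
}

// [[Rcpp::export]]
Rcpp::List lstm_loss_grad_cpp(Rcpp::List weights, const arma::mat &X,
                              const arma::vec &y) {
  Weights w = weights_from_list(weights);
  Weights g = w;
  double loss = loss_and_grads(w, X, y, g);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = weights_to_list(g));
}

// Chebyshev (L-infinity) distance matrix between row sets.
// [[Rcpp::export]]
arma::mat chebyshev_dist_cpp(const arma::mat &A, const arma::mat &B) {
  mat D(A.n_rows, B.n_rows);
  for (uword j = 0; j < B.n_rows; ++j) {
    rowvec b = B.row(j);
    for (uword i = 0; i < A.n_rows; ++i) {
      D(i, j) = abs(A.row(i) - b).max();
    }
  }
  return D;
}
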