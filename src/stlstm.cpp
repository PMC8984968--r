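// Two-branch LSTM velocity regressor: forward pass, backpropagation
// through time, and a full-batch Adam training loop. Each branch is one
// LSTM layer (gate order i, f, g, o) whose final hidden state feeds a
// linear head producing one scalar velocity; branch 1 is horizontal,
// branch 2 vertical. The loss is mean squared error plus lambda times the
// velocity constraint: per sample, the squared prediction on the
// non-imaginary axis minus the squared prediction on the imaginary axis.
//
// All computation is deterministic: no RNG, single-threaded, fixed
// operation order. Initial weights are supplied from R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Branch {
  mat Wx;     // E x 4H
  mat Wh;     // H x 4H
  rowvec b;   // 4H
  vec wout;   // H
  double bout;
};

struct Cache {
  cube I, F, G, O, C, Hs;  // each N x H x T
};

struct Grads {
  mat Wx, Wh;
  rowvec b;
  vec wout;
  double bout;
};

static Branch branch_from_list(const Rcpp::List& L) {
  Branch br;
  br.Wx = Rcpp::as<mat>(L["Wx"]);
  br.Wh = Rcpp::as<mat>(L["Wh"]);
  br.b = Rcpp::as<rowvec>(L["b"]);
  br.wout = Rcpp::as<vec>(L["wout"]);
  br.bout = Rcpp::as<double>(L["bout"]);
  return br;
}

static Rcpp::List branch_to_list(const Branch& br) {
  return Rcpp::List::create(Rcpp::Named("Wx") = br.Wx,
                            Rcpp::Named("Wh") = br.Wh,
                            Rcpp::Named("b") = br.b,
                            Rcpp::Named("wout") = br.wout,
                            Rcpp::Named("bout") = br.bout);
}

static Rcpp::List grads_to_list(const Grads& g) {
  return Rcpp::List::create(Rcpp::Named("Wx") = g.Wx,
                            Rcpp::Named("Wh") = g.Wh,
                            Rcpp::Named("b") = g.b,
                            Rcpp::Named("wout") = g.wout,
                            Rcpp::Named("bout") = g.bout);
}

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// forward pass; fills the cache when keep = true; returns y-hat (N)
static vec forward_branch(const cube& X, const Branch& br, Cache& cc,
                          bool keep) {
  const uword N = X.n_rows, T = X.n_slices, H = br.Wh.n_rows;
  mat h(N, H, fill::zeros), c(N, H, fill::zeros);
  if (keep) {
    cc.I.set_size(N, H, T); cc.F.set_size(N, H, T); cc.G.set_size(N, H, T);
    cc.O.set_size(N, H, T); cc.C.set_size(N, H, T); cc.Hs.set_size(N, H, T);
  }
  for (uword t = 0; t < T; ++t) {
    mat gates = X.slice(t) * br.Wx + h * br.Wh;
    gates.each_row() += br.b;
    mat ig = sigmoid(gates.cols(0, H - 1));
    mat fg = sigmoid(gates.cols(H, 2 * H - 1));
    mat gg = tanh(gates.cols(2 * H, 3 * H - 1));
    mat og = sigmoid(gates.cols(3 * H, 4 * H - 1));
    c = fg % c + ig % gg;
    h = og % tanh(c);
    if (keep) {
      cc.I.slice(t) = ig; cc.F.slice(t) = fg; cc.G.slice(t) = gg;
      cc.O.slice(t) = og; cc.C.slice(t) = c; cc.Hs.slice(t) = h;
    }
  }
  return h * br.wout + br.bout;
}

// backpropagation through time for one branch given dL/dy-hat
static Grads backward_branch(const cube& X, const Branch& br,
                             const Cache& cc, const vec& dy) {
  const uword N = X.n_rows, T = X.n_slices, H = br.Wh.n_rows;
  Grads g;
  g.Wx = zeros<mat>(br.Wx.n_rows, br.Wx.n_cols);
  g.Wh = zeros<mat>(H, 4 * H);
  g.b = zeros<rowvec>(4 * H);
  g.wout = cc.Hs.slice(T - 1).t() * dy;
  g.bout = accu(dy);
  mat dh = dy * br.wout.t();     // N x H
  mat dc(N, H, fill::zeros);
  for (uword t = T; t-- > 0;) {
    const mat& ig = cc.I.slice(t);
    const mat& fg = cc.F.slice(t);
    const mat& gg = cc.G.slice(t);
    const mat& og = cc.O.slice(t);
    mat tc = tanh(cc.C.slice(t));
    mat do_ = dh % tc;
    dc += dh % og % (1.0 - tc % tc);
    mat di = dc % gg;
    mat dg = dc % ig;
    mat cprev = (t > 0) ? cc.C.slice(t - 1) : zeros<mat>(N, H);
    mat df = dc % cprev;
    mat D(N, 4 * H);
    D.cols(0, H - 1)         = di % ig % (1.0 - ig);
    D.cols(H, 2 * H - 1)     = df % fg % (1.0 - fg);
    D.cols(2 * H, 3 * H - 1) = dg % (1.0 - gg % gg);
    D.cols(3 * H, 4 * H - 1) = do_ % og % (1.0 - og);
    g.Wx += X.slice(t).t() * D;
    if (t > 0) g.Wh += cc.Hs.slice(t - 1).t() * D;
    g.b += sum(D, 0);
    dh = D * br.Wh.t();
    dc = dc % fg;
  }
  return g;
}

// loss components; s is +1 for U/D samples, -1 for L/R
static void loss_terms(const vec& yh, const vec& yv, const mat& Y,
                       const vec& s, double lambda, double& mse, double& vc,
                       double& total, vec& dyh, vec& dyv) {
  const double N = yh.n_elem;
  vec eh = yh - Y.col(0), ev = yv - Y.col(1);
  mse = accu(eh % eh + ev % ev) / N;
  vc = accu(s % (yh % yh - yv % yv)) / N;
  total = mse + lambda * vc;
  dyh = (2.0 * eh + lambda * 2.0 * (s % yh)) / N;
  dyv = (2.0 * ev - lambda * 2.0 * (s % yv)) / N;
}

struct AdamState {
  mat mWx, vWx, mWh, vWh;
  rowvec mb, vb;
  vec mw, vw;
  double mb0 = 0, vb0 = 0;
  explicit AdamState(const Branch& br)
    : mWx(size(br.Wx), fill::zeros), vWx(size(br.Wx), fill::zeros),
      mWh(size(br.Wh), fill::zeros), vWh(size(br.Wh), fill::zeros),
      mb(size(br.b), fill::zeros), vb(size(br.b), fill::zeros),
      mw(size(br.wout), fill::zeros), vw(size(br.wout), fill::zeros) {}
};

template <typename M>
static inline void adam_update(M& theta, const M& grad, M& m, M& v,
                               double lr, double b1, double b2, double eps,
                               double bc1, double bc2) {
  m = b1 * m + (1.0 - b1) * grad;
  v = b2 * v + (1.0 - b2) * (grad % grad);
  theta -= lr * (m / bc1) / (sqrt(v / bc2) + eps);
}

static inline void adam_update_scalar(double& theta, double grad, double& m,
                                      double& v, double lr, double b1,
                                      double b2, double eps, double bc1,
                                      double bc2) {
  m = b1 * m + (1.0 - b1) * grad;
  v = b2 * v + (1.0 - b2) * grad * grad;
  theta -= lr * (m / bc1) / (std::sqrt(v / bc2) + eps);
}

static void adam_step(Branch& br, const Grads& g, AdamState& st, double lr,
                      double b1, double b2, double eps, int t) {
  double bc1 = 1.0 - std::pow(b1, t), bc2 = 1.0 - std::pow(b2, t);
  adam_update(br.Wx, g.Wx, st.mWx, st.vWx, lr, b1, b2, eps, bc1, bc2);
  adam_update(br.Wh, g.Wh, st.mWh, st.vWh, lr, b1, b2, eps, bc1, bc2);
  adam_update(br.b, g.b, st.mb, st.vb, lr, b1, b2, eps, bc1, bc2);
  adam_update(br.wout, g.wout, st.mw, st.vw, lr, b1, b2, eps, bc1, bc2);
  adam_update_scalar(br.bout, g.bout, st.mb0, st.vb0, lr, b1, b2, eps,
                     bc1, bc2);
}

// [[Rcpp::export]]
arma::mat cpp_stlstm_forward(const arma::cube& X, const Rcpp::List& params) {
  Branch bh = branch_from_list(params["horizontal"]);
  Branch bv = branch_from_list(params["vertical"]);
  Cache ch, cv;
  vec yh = forward_branch(X, bh, ch, false);
  vec yv = forward_branch(X, bv, cv, false);
  return join_rows(yh, yv);
}

// [[Rcpp::export]]
Rcpp::List cpp_stlstm_grad(const arma::cube& X, const arma::mat& Y,
                           const arma::vec& s, double lambda,
                           const Rcpp::List& params) {
  Branch bh = branch_from_list(params["horizontal"]);
  Branch bv = branch_from_list(params["vertical"]);
  Cache ch, cv;
  vec yh = forward_branch(X, bh, ch, true);
  vec yv = forward_branch(X, bv, cv, true);
  double mse, vc, total;
  vec dyh, dyv;
  loss_terms(yh, yv, Y, s, lambda, mse, vc, total, dyh, dyv);
  Grads gh = backward_branch(X, bh, ch, dyh);
  Grads gv = backward_branch(X, bv, cv, dyv);
  return Rcpp::List::create(
      Rcpp::Named("mse") = mse, Rcpp::Named("vc") = vc,
      Rcpp::Named("total") = total,
      Rcpp::Named("yhat") = join_rows(yh, yv),
      Rcpp::Named("grads") = Rcpp::List::create(
          Rcpp::Named("horizontal") = grads_to_list(gh),
          Rcpp::Named("vertical") = grads_to_list(gv)));
}

// [[Rcpp::export]]
Rcpp::List cpp_stlstm_train(const arma::cube& X, const arma::mat& Y,
                            const arma::vec& s, double lambda, int epochs,
                            double lr, const Rcpp::List& params,
                            double beta1 = 0.9, double beta2 = 0.999,
                            double adam_eps = 1e-8) {
  Branch bh = branch_from_list(params["horizontal"]);
  Branch bv = branch_from_list(params["vertical"]);
  AdamState sh(bh), sv(bv);
  mat history(epochs, 3);
  int neg_streak = 0;
  double prev_total = datum::inf;
  for (int ep = 0; ep < epochs; ++ep) {
    Cache ch, cv;
    vec yh = forward_branch(X, bh, ch, true);
    vec yv = forward_branch(X, bv, cv, true);
    double mse, vc, total;
    vec dyh, dyv;
    loss_terms(yh, yv, Y, s, lambda, mse, vc, total, dyh, dyv);
    if (!std::isfinite(total))
      Rcpp::stop("non-finite training loss at epoch %d", ep + 1);
    // a VC term dominating the MSE drives the total loss unboundedly
    // negative; abort and flag the pathological lambda
    neg_streak = (total < 0 && total < prev_total) ? neg_streak + 1 : 0;
    if (neg_streak >= 20)
      Rcpp::stop("total loss negative and decreasing for 20 epochs: "
                 "lambda = %g is pathological for this data", lambda);
    prev_total = total;
    history(ep, 0) = mse; history(ep, 1) = vc; history(ep, 2) = total;
    Grads gh = backward_branch(X, bh, ch, dyh);
    Grads gv = backward_branch(X, bv, cv, dyv);
    adam_step(bh, gh, sh, lr, beta1, beta2, adam_eps, ep + 1);
    adam_step(bv, gv, sv, lr, beta1, beta2, adam_eps, ep + 1);
  }
  return Rcpp::List::create(
      Rcpp::Named("params") = Rcpp::List::create(
          Rcpp::Named("horizontal") = branch_to_list(bh),
          Rcpp::Named("vertical") = branch_to_list(bv)),
      Rcpp::Named("history") = history);
}
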