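// Hot loops: Euler-forward integration of the rate dynamics and the
// recursive-least-squares (FORCE) readout update. Everything else lives in R.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static inline void rates_of(const vec& x, vec& r, const int transfer) {
  const uword n = x.n_elem;
  if (transfer == 0) {            // rectified tanh
    for (uword i = 0; i < n; ++i) r[i] = x[i] > 0 ? std::tanh(x[i]) : 0.0;
  } else {                        // logistic sigmoid
    for (uword i = 0; i < n; ++i) r[i] = 1.0 / (1.0 + std::exp(-x[i]));
  }
}

static inline bool diverged(const vec& x, const double thresh) {
  return !x.is_finite() || abs(x).max() > thresh;
}

// Integrate the network. Feedback is W * r unless an external feedback matrix
// (n_outputs x T) is supplied. Returns outputs, final state, optionally the
// full rate and activation matrices, and a divergence flag/step.
// [[Rcpp::export]]
Rcpp::List cpp_run_network(const arma::sp_mat& J, const arma::vec& Jin,
                           const arma::mat& Jfb, const arma::mat& W,
                           const arma::vec& x0, const arma::vec& u,
                           Rcpp::Nullable<Rcpp::NumericMatrix> y_ext,
                           const double dt, const double tau,
                           const int transfer, const bool record,
                           const double div_thresh = 1e6) {
  const uword N = x0.n_elem, T = u.n_elem, k = W.n_rows;
  const double a = dt / tau;
  const bool external = y_ext.isNotNull();
  mat Yext;
  if (external) Yext = Rcpp::as<mat>(y_ext.get());

  vec x = x0, r(N);
  mat outputs(k, T, fill::zeros);
  mat rates, acts;
  if (record) { rates.set_size(N, T); acts.set_size(N, T); }

  rates_of(x, r, transfer);
  vec y = external ? vec(Yext.col(0)) : vec(W * r);
  int div_step = -1;

  for (uword t = 0; t < T; ++t) {
    x = (1.0 - a) * x + a * (J * r + Jfb * y + Jin * u[t]);
    if (diverged(x, div_thresh)) { div_step = (int)t + 1; break; }
    rates_of(x, r, transfer);
    outputs.col(t) = W * r;
    if (record) { rates.col(t) = r; acts.col(t) = x; }
    y = external ? (t + 1 < T ? vec(Yext.col(t + 1)) : vec(Yext.col(t)))
                 : vec(outputs.col(t));
  }

  Rcpp::List res = Rcpp::List::create(
    Rcpp::Named("outputs") = outputs,
    Rcpp::Named("x_final") = x,
    Rcpp::Named("diverged") = div_step > 0,
    Rcpp::Named("divergence_step") = div_step);
  if (record) { res["rates"] = rates; res["activations"] = acts; }
  return res;
}

// One training pass: run with own-output feedback, update (W, P) by standard
// RLS every `update_every` steps. W and P are modified copies returned to R.
// err_trace holds the pre-update RMSE across outputs at each update step.
// [[Rcpp::export]]
Rcpp::List cpp_train_rls(const arma::sp_mat& J, const arma::vec& Jin,
                         const arma::mat& Jfb, arma::mat W, arma::mat P,
                         const arma::vec& x0, const arma::vec& u,
                         const arma::mat& Ytgt, const double dt,
                         const double tau, const int transfer,
                         const int update_every,
                         const double div_thresh = 1e6) {
  const uword N = x0.n_elem, T = u.n_elem;
  const double a = dt / tau;
  vec x = x0, r(N);
  rates_of(x, r, transfer);
  vec y = W * r;
  std::vector<double> err_trace;
  err_trace.reserve(T / update_every + 1);
  int div_step = -1;

  for (uword t = 0; t < T; ++t) {
    x = (1.0 - a) * x + a * (J * r + Jfb * y + Jin * u[t]);
    if (diverged(x, div_thresh)) { div_step = (int)t + 1; break; }
    rates_of(x, r, transfer);
    y = W * r;
    if ((t + 1) % (uword)update_every == 0) {
      vec pr = P * r;
      double denom = 1.0 + dot(r, pr);
      vec kk = pr / denom;
      vec e = y - Ytgt.col(t);
      if (!e.is_finite()) { div_step = (int)t + 1; break; }
      W -= e * kk.t();
      P -= kk * pr.t();
      err_trace.push_back(std::sqrt(mean(square(e))));
      y = W * r;  // feedback uses the freshly updated readout
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("W") = W, Rcpp::Named("P") = P,
    Rcpp::Named("err_trace") = err_trace,
    Rcpp::Named("diverged") = div_step > 0,
    Rcpp::Named("divergence_step") = div_step);
}
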