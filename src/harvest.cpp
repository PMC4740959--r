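// Reservoir state-update loop. Mirrors the pure-R esn_harvest() exactly;
// the two paths are cross-checked in the test suite. Accumulates the
// normal-equation moments (X X', running state sum) so that EMG-scale
// signals never require materializing the full state matrix.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// kind: 0 one_way_ring, 1 two_way_ring, 2 center, 3 hybrid, 4 random
// act:  0 tanh, 1 identity, 2 pwl_tanh

static inline double pwl_tanh_scalar(double x) {
  double ax = std::fabs(x), y;
  if (ax >= 1.5) y = 1.0;
  else if (ax > 0.5) y = 0.5 * ax + 0.25;
  else y = ax;
  return x < 0 ? -y : y;
}

// [[Rcpp::export]]
Rcpp::List harvest_accumulate(const arma::mat& signal, const arma::mat& W_in,
                              const arma::vec& W_ring,
                              const arma::vec& W_ring_rev,
                              const arma::vec& W_up, const arma::vec& W_down,
                              const arma::mat& W_x, int kind, double alpha,
                              int act, int washout, bool return_states) {
  const arma::uword N = W_in.n_rows;
  const arma::uword T = signal.n_cols;
  arma::vec x(N, arma::fill::zeros), x_new(N), pre(N);
  double Xc = 0.0;
  const arma::uword T_kept = T - (arma::uword)washout;
  arma::mat states(N, T_kept);  // buffered so X X' runs as one BLAS call
  arma::uword kept = 0;
  for (arma::uword t = 0; t < T; ++t) {
    if (kind == 2 || kind == 3) Xc = arma::dot(W_up, x);
    pre = W_in * signal.col(t);
    if (kind == 0 || kind == 1 || kind == 3)
      for (arma::uword i = 0; i < N; ++i)
        pre[i] += W_ring[i] * x[(i + N - 1) % N];
    if (kind == 1)
      for (arma::uword i = 0; i < N; ++i)
        pre[i] += W_ring_rev[i] * x[(i + 1) % N];
    if (kind == 2 || kind == 3) pre += W_down * Xc;
    if (kind == 4) pre += W_x * x;
    switch (act) {
      case 0: x_new = arma::tanh(pre); break;
      case 1: x_new = pre; break;
      default:
        for (arma::uword i = 0; i < N; ++i)
          x_new[i] = pwl_tanh_scalar(pre[i]);
    }
    x = alpha * x_new + (1.0 - alpha) * x;
    if ((int)t >= washout) states.col(kept++) = x;
  }
  arma::mat XXt = states * states.t();
  arma::vec xsum = arma::sum(states, 1);
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("XXt") = XXt, Rcpp::Named("state_sum") = xsum,
      Rcpp::Named("T_kept") = (int)T_kept, Rcpp::Named("X_last") = x,
      Rcpp::Named("Xc_last") = Xc);
  if (return_states) out["X_all"] = states;
  return out;
}
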