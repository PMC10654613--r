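// Multiplicative-update NMF minimizing the generalized Kullback-Leibler
// divergence D(V || WH) (Lee & Seung updates, the classic metagene variant).
// Initial factors are drawn in R so all randomness flows through R's RNG.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double kl_div(const mat& V, const mat& WH) {
  double d = 0.0;
  const double* v = V.memptr();
  const double* wh = WH.memptr();
  const uword n = V.n_elem;
  for (uword i = 0; i < n; ++i) {
    double vi = v[i], whi = std::max(wh[i], 1e-300);
    if (vi > 0) d += vi * std::log(vi / whi) - vi + whi;
    else d += whi;
  }
  return d;
}


Rcpp::List nmf_kl_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                      int max_iter, double tol) {
  const double eps = 1e-16;
  std::vector<double> trace;
  trace.reserve(max_iter + 1);
  mat WH = W * H;
  double obj = kl_div(V, WH);
  trace.push_back(obj);
  for (int it = 0; it < max_iter; ++it) {
    // H update: H <- H .* (W' (V ./ WH)) ./ (W' 1)
    mat R = V / (WH + eps);
    H %= (W.t() * R);
    H.each_col() /= (sum(W, 0).t() + eps);
    // W update with refreshed quotient
    WH = W * H;
    R = V / (WH + eps);
    W %= (R * H.t());
    W.each_row() /= (sum(H, 1).t() + eps);
    WH = W * H;
    double obj_new = kl_div(V, WH);
    trace.push_back(obj_new);
    double rel = std::fabs(obj - obj_new) / std::max(std::fabs(obj), 1e-12);
    obj = obj_new;
    if (rel < tol) break;
  }
  return Rcpp::List::create(Rcpp::Named("W") = W, Rcpp::Named("H") = H,
                            Rcpp::Named("trace") = trace);
}
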