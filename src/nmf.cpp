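// Multiplicative-update NMF for the Frobenius objective ||X - WH||_F^2,
// H_{aj} <- H_{aj} (W'X)_{aj} / ((W'WH)_{aj} + eps)
// W_{ia} <- W_{ia} (XH')_{ia} / ((WHH')_{ia} + eps)
// with eps guarding the denominators. The loop is in C++ because the
// pipeline factorizes tens of thousands of tiny segments per subject.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List nmf_mu_cpp(const arma::mat& X, arma::mat W, arma::mat H,
                int max_iter, double tol, double eps) {
  std::vector<double> err;
  err.reserve(max_iter + 1);
  double prev = arma::accu(arma::square(X - W * H));
  err.push_back(prev);
  int it = 0;
  for (; it < max_iter; ++it) {
    H %= (W.t() * X) / (W.t() * W * H + eps);
    W %= (X * H.t()) / (W * H * H.t() + eps);
    double e = arma::accu(arma::square(X - W * H));
    err.push_back(e);
    double denom = std::max(prev, 1e-300);
    if ((prev - e) / denom < tol) { ++it; break; }
    prev = e;
  }
  return List::create(_["W"] = W, _["H"] = H,
                      _["err_trace"] = err, _["n_iter"] = it);
}
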