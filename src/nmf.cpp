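#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Multiplicative-update NMF minimizing the Frobenius reconstruction error
// ||V - WH||_F^2 (Lee & Seung updates).  W and H must be strictly positive
// on entry; the updates preserve non-negativity.  Convergence is declared
// when the relative drop of the objective over `check_every` iterations
// falls below `tol`.
// [[Rcpp::export]]
Rcpp::List nmf_mu_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                      int max_iter, double tol, int check_every) {
  const double eps = 1e-12;
  double prev = datum::inf;
  double obj = prev;
  int it = 0;

  for (it = 1; it <= max_iter; ++it) {
    // H <- H .* (W'V) ./ (W'W H)
    H %= (W.t() * V) / (W.t() * W * H + eps);
    // W <- W .* (V H') ./ (W H H')
    W %= (V * H.t()) / (W * (H * H.t()) + eps);

    if (it % check_every == 0 || it == max_iter) {
      obj = accu(square(V - W * H));
      if (std::isfinite(prev) && prev - obj <= tol * (prev + eps)) break;
      prev = obj;
    }
  }

  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("H") = H,
                            Rcpp::Named("loss") = obj,
                            Rcpp::Named("iterations") = std::min(it, max_iter));
}
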