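// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Bootstrap eigenvalue spectra of an SCV's absolute sample covariance.
//
// For each of B replicates: draw V column indices with replacement (via R's
// RNG, so results are reproducible under set.seed), form the resampled
// K x V matrix, compute abs(S_b S_b' / V) and its eigenvalues.  One shared
// index draw per replicate preserves the cross-row dependence of the SCV.
// Rows of the result are eigenvalue spectra sorted in descending order.
// [[Rcpp::export]]
arma::mat boot_eigs_cpp(const arma::mat& S, const int B) {
  const int K = S.n_rows;
  const int V = S.n_cols;
  arma::mat out(B, K);
  arma::uvec idx(V);
  arma::vec ev(K);
  for (int b = 0; b < B; ++b) {
    Rcpp::IntegerVector draw = Rcpp::sample(V, V, true);
    for (int v = 0; v < V; ++v) idx[v] = draw[v] - 1;
    arma::mat Sb = S.cols(idx);
    arma::mat C = arma::abs(Sb * Sb.t() / double(V));
    arma::eig_sym(ev, C);
    out.row(b) = arma::sort(ev, "descend").t();
  }
  return out;
}
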