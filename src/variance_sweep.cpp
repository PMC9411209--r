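// Kernel-weighted normalized variance sweep.
//
// For each bandwidth sigma, every observation's dependent-variable value is
// compared against a Gaussian-kernel weighted average of all observations,
// taken in the manifold coordinates. The residual variance is normalized by
// the total variance of the variable. One N x N pairwise distance matrix is
// formed once and reused across the whole sigma grid, so the sweep costs
// O(m N^2) per sigma value.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::mat cpp_normalized_variance(const arma::mat& eta,
                                  const arma::mat& phi,
                                  const arma::vec& sigma) {
  const arma::uword n = eta.n_rows;
  const arma::uword m = phi.n_cols;
  const arma::uword s = sigma.n_elem;

  if (phi.n_rows != n) Rcpp::stop("eta and phi must have the same number of rows");

  // squared Euclidean pairwise distances in manifold space
  arma::vec sq = arma::sum(arma::square(eta), 1);
  arma::mat d2 = -2.0 * (eta * eta.t());
  d2.each_col() += sq;
  d2.each_row() += sq.t();
  d2.elem(arma::find(d2 < 0.0)).zeros();  // clamp round-off negatives

  // total variance per dependent variable
  arma::rowvec mu = arma::mean(phi, 0);
  arma::rowvec denom(m);
  for (arma::uword i = 0; i < m; ++i) {
    denom(i) = arma::accu(arma::square(phi.col(i) - mu(i)));
  }

  arma::mat out(s, m);
  arma::mat w(n, n);
  for (arma::uword k = 0; k < s; ++k) {
    const double s2 = sigma(k) * sigma(k);
    w = arma::exp(-d2 / s2);          // self-weight is always exp(0) = 1
    arma::vec wsum = arma::sum(w, 1);
    arma::mat kest = (w * phi);
    kest.each_col() /= wsum;
    for (arma::uword i = 0; i < m; ++i) {
      out(k, i) = arma::accu(arma::square(phi.col(i) - kest.col(i))) / denom(i);
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Weighted-average estimate at arbitrary query locations (not restricted to
// the observations themselves). Underflow of all weights at a query is
// signalled with NaN so the caller can apply its nearest-neighbour fallback.
// [[Rcpp::export]]
arma::mat cpp_kernel_estimate(const arma::mat& query,
                              const arma::mat& eta,
                              const arma::mat& phi,
                              const double sigma) {
  const arma::uword nq = query.n_rows;
  const arma::uword m = phi.n_cols;
  const double s2 = sigma * sigma;
  arma::mat out(nq, m);
  for (arma::uword a = 0; a < nq; ++a) {
    arma::vec d2 = arma::sum(arma::square(eta.each_row() - query.row(a)), 1);
    arma::vec w = arma::exp(-d2 / s2);
    const double wsum = arma::accu(w);
    if (wsum > 0.0) {
      out.row(a) = (w.t() * phi) / wsum;
    } else {
      out.row(a).fill(arma::datum::nan);
    }
  }
  return out;
}
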