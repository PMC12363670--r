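// Dual coordinate descent for the L2-regularized L1-loss (hinge) linear SVM
// (Hsieh et al. 2008).  The bias is handled as an augmented constant feature,
// so the primal problem is
//
//   min_{w,b}  1/2 (||w||^2 + b^2) + sum_i C_i * max(0, 1 - y_i (w'x_i + b))
//
// with a per-sample cost C_i (carries multiclass class weights).  The dual is
// solved coordinate-wise; the permutation of coordinates is drawn from a
// seeded mt19937 so fits are bit-reproducible across platforms.

#include <RcppArmadillo.h>
#include <random>

// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".svm_dcd")]]
Rcpp::List svm_dcd(const arma::mat& X,         // n x d, dense
                   const arma::vec& y,         // +1 / -1
                   const arma::vec& cost,      // per-sample upper bound C_i
                   const int max_iter,
                   const double eps,
                   const unsigned int seed) {
  const arma::uword n = X.n_rows, d = X.n_cols;
  arma::vec w(d, arma::fill::zeros);
  double b = 0.0;
  arma::vec alpha(n, arma::fill::zeros);

  // samples as contiguous columns so coordinate updates stay in cache
  const arma::mat Xt = X.t();

  // Qbar_ii = x_i'x_i + 1 (the +1 is the bias feature)
  arma::vec qbar(n);
  for (arma::uword i = 0; i < n; ++i)
    qbar(i) = arma::dot(Xt.col(i), Xt.col(i)) + 1.0;

  std::mt19937 rng(seed);
  std::vector<arma::uword> idx(n);
  for (arma::uword i = 0; i < n; ++i) idx[i] = i;

  int iter = 0;
  bool converged = false;
  for (iter = 0; iter < max_iter; ++iter) {
    // Fisher-Yates shuffle with the seeded generator
    for (arma::uword i = n - 1; i > 0; --i) {
      std::uniform_int_distribution<arma::uword> pick(0, i);
      std::swap(idx[i], idx[pick(rng)]);
    }
    double max_viol = 0.0;
    for (arma::uword k = 0; k < n; ++k) {
      const arma::uword i = idx[k];
      const double yi = y(i);
      const double G = yi * (arma::dot(w, Xt.col(i)) + b) - 1.0;
      const double U = cost(i);
      double PG;
      if (alpha(i) <= 0.0)      PG = std::min(G, 0.0);
      else if (alpha(i) >= U)   PG = std::max(G, 0.0);
      else                      PG = G;
      if (std::abs(PG) > max_viol) max_viol = std::abs(PG);
      if (std::abs(PG) > 1e-12) {
        const double a_new = std::min(std::max(alpha(i) - G / qbar(i), 0.0), U);
        const double delta = (a_new - alpha(i)) * yi;
        if (delta != 0.0) {
          w += delta * Xt.col(i);
          b += delta;
        }
        alpha(i) = a_new;
      }
    }
    if (max_viol < eps) { converged = true; ++iter; break; }
  }

  return Rcpp::List::create(Rcpp::Named("w") = w,
                            Rcpp::Named("b") = b,
                            Rcpp::Named("iterations") = iter,
                            Rcpp::Named("converged") = converged);
}
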