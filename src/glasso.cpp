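// Graphical lasso by block coordinate descent (lasso regressions on the
// current covariance estimate, Friedman-style). The diagonal is not
// penalised, so W shares its diagonal with S and lambda >= max |S_ij|
// yields the fully disconnected model.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double soft(double x, double l) {
  if (x > l) return x - l;
  if (x < -l) return x + l;
  return 0.0;
}

// [[Rcpp::export(name = ".glassoCpp")]]
List glasso_cpp(arma::mat S, double lambda, double tol, int max_iter,
                Nullable<NumericMatrix> W_init = R_NilValue,
                Nullable<NumericMatrix> B_init = R_NilValue) {
  const int p = S.n_rows;
  arma::mat W = W_init.isNotNull() ? as<arma::mat>(W_init.get()) : S;
  arma::mat B = B_init.isNotNull() ? as<arma::mat>(B_init.get())
                                   : arma::zeros(p, p);   // column j: beta_j
  W.diag() = S.diag();
  double thr = tol * arma::mean(arma::abs(
      S.elem(arma::find(arma::trimatu(arma::ones(p, p), 1)))));
  if (!std::isfinite(thr) || thr <= 0) thr = tol;
  bool converged = false;
  double maxdiff = 0.0;
  for (int it = 0; it < max_iter; ++it) {
    maxdiff = 0.0;
    for (int j = 0; j < p; ++j) {
      arma::uvec idx(p - 1);
      for (int k = 0, c = 0; k < p; ++k) if (k != j) idx[c++] = k;
      arma::mat W11 = W.submat(idx, idx);
      arma::vec s12 = S.col(j); s12 = s12.elem(idx);
      arma::vec beta = B.col(j); beta = beta.elem(idx);
      // inner lasso coordinate descent
      for (int in = 0; in < 1000; ++in) {
        double del = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          double r = s12[k] - arma::dot(W11.row(k).t(), beta) +
                     W11(k, k) * beta[k];
          double bn = soft(r, lambda) / W11(k, k);
          del = std::max(del, std::fabs(bn - beta[k]));
          beta[k] = bn;
        }
        if (del < thr * 0.1) break;
      }
      arma::vec w12 = W11 * beta;
      for (int k = 0; k < p - 1; ++k) {
        maxdiff = std::max(maxdiff, std::fabs(W(idx[k], j) - w12[k]));
        W(idx[k], j) = w12[k];
        W(j, idx[k]) = w12[k];
        B(idx[k], j) = beta[k];
      }
    }
    if (maxdiff < thr) { converged = true; break; }
  }
  // recover Theta from the final regressions
  arma::mat Theta(p, p, arma::fill::zeros);
  for (int j = 0; j < p; ++j) {
    arma::uvec idx(p - 1);
    for (int k = 0, c = 0; k < p; ++k) if (k != j) idx[c++] = k;
    arma::vec beta = B.col(j); beta = beta.elem(idx);
    arma::vec w12 = W.col(j); w12 = w12.elem(idx);
    double t22 = 1.0 / (W(j, j) - arma::dot(w12, beta));
    Theta(j, j) = t22;
    for (int k = 0; k < p - 1; ++k) Theta(idx[k], j) = -beta[k] * t22;
  }
  Theta = 0.5 * (Theta + Theta.t());
  return List::create(_["Theta"] = Theta, _["W"] = W, _["B"] = B,
                      _["converged"] = converged, _["maxdiff"] = maxdiff);
}
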