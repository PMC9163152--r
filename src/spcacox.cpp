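// Compiled kernels: the Efron partial-likelihood derivatives and the
// sparse-PCA variable-projection alternation loop. Both are plain
// O(n p^2) / O(p^2 k) scans whose R-level versions dominated runtime.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Efron log partial likelihood, score, and observed information at
// beta, for subjects sorted by ascending follow-up time. One backward
// scan maintains the risk-set sums S0, S1, S2; at each distinct event
// time the tied set contributes the Efron-averaged terms.
// [[Rcpp::export]]
List cox_deriv_cpp(const arma::vec& time, const arma::ivec& event,
                   const arma::mat& X, const arma::vec& beta,
                   bool hessian) {
  const int n = X.n_rows, p = X.n_cols;
  arma::vec eta = X * beta;
  const double m = arma::mean(eta);
  arma::vec w = arma::exp(eta - m);

  double ll = 0.0;
  arma::vec grad(p, arma::fill::zeros);
  arma::mat H(p, p, arma::fill::zeros);

  double S0 = 0.0;
  arma::vec S1(p, arma::fill::zeros);
  arma::mat S2(p, p, arma::fill::zeros);

  int i = n - 1;
  while (i >= 0) {
    const double t = time[i];
    int j = i;
    while (j >= 0 && time[j] == t) j--;

    // subjects j+1..i enter the risk set at time t
    for (int r = j + 1; r <= i; ++r) {
      const arma::rowvec xr = X.row(r);
      S0 += w[r];
      S1 += w[r] * xr.t();
      if (hessian) S2 += w[r] * (xr.t() * xr);
    }

    // tied event set at time t
    int d = 0;
    double S0D = 0.0;
    arma::vec S1D(p, arma::fill::zeros), xsum(p, arma::fill::zeros);
    arma::mat S2D(p, p, arma::fill::zeros);
    for (int r = j + 1; r <= i; ++r) {
      if (event[r] == 1) {
        const arma::rowvec xr = X.row(r);
        ++d;
        ll += eta[r] - m;
        S0D += w[r];
        S1D += w[r] * xr.t();
        xsum += xr.t();
        if (hessian) S2D += w[r] * (xr.t() * xr);
      }
    }
    if (d > 0) {
      grad += xsum;
      for (int l = 0; l < d; ++l) {
        const double f = double(l) / d;
        const double phi = S0 - f * S0D;
        const arma::vec v1 = (S1 - f * S1D) / phi;
        ll -= std::log(phi);
        grad -= v1;
        if (hessian) H += (S2 - f * S2D) / phi - v1 * v1.t();
      }
    }
    i = j;
  }

  return List::create(_["loglik"] = ll, _["grad"] = grad,
                      _["info"] = hessian ? wrap(H) : R_NilValue);
}

// Alternating variable-projection loop for sparse PCA on the Gram
// matrix G = X'X/(n-1): a capped number of exact coordinate-descent
// sweeps on B (rows updated jointly across components) followed by
// the orthogonal Procrustes update of A. Every partial step descends,
// so the recorded objective trace is non-increasing.
// [[Rcpp::export]]
List spca_vp_cpp(const arma::mat& G, arma::mat B, arma::mat A,
                 double l1, double l2, int max_iter, double tol,
                 int sweeps) {
  const int p = G.n_rows, k = B.n_cols;
  const arma::vec dG = G.diag();
  const double trG = arma::trace(G);

  auto objective = [&](const arma::mat& Bc, const arma::mat& Ac) {
    arma::mat GB = G * Bc;
    return 0.5 * (trG - 2.0 * arma::accu(Ac % GB) + arma::accu(Bc % GB)) +
           l1 * arma::accu(arma::abs(Bc)) + 0.5 * l2 * arma::accu(Bc % Bc);
  };

  std::vector<double> trace;
  trace.push_back(objective(B, A));
  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    arma::mat GA = G * A;
    arma::mat GB = G * B;
    for (int s = 0; s < sweeps; ++s) {
      double dmax = 0.0;
      for (int i = 0; i < p; ++i) {
        for (int j = 0; j < k; ++j) {
          const double r = GA(i, j) - GB(i, j) + dG[i] * B(i, j);
          double bnew = std::abs(r) - l1;
          bnew = bnew > 0.0 ? (r > 0 ? bnew : -bnew) / (dG[i] + l2) : 0.0;
          const double delta = bnew - B(i, j);
          if (delta != 0.0) {
            B(i, j) = bnew;
            GB.col(j) += G.col(i) * delta;
            dmax = std::max(dmax, std::abs(delta));
          }
        }
      }
      if (dmax < 1e-10) break;
    }
    arma::mat U, V;
    arma::vec sv;
    arma::svd_econ(U, sv, V, G * B);
    A = U * V.t();
    const double f = objective(B, A);
    const double prev = trace.back();
    trace.push_back(f);
    if (std::abs(prev - f) <= tol * (std::abs(prev) + 1e-12)) {
      converged = true;
      break;
    }
  }
  if (iter > max_iter) iter = max_iter;

  return List::create(_["B"] = B, _["A"] = A, _["objective"] = trace,
                      _["iterations"] = iter, _["converged"] = converged);
}
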