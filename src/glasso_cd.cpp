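#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Blockwise coordinate-descent graphical lasso with the L1 penalty on
// off-diagonal precision entries only (the diagonal is unpenalized, so the
// working covariance W keeps the sample diagonal throughout).
//
// Solves: maximize log det K - tr(S K) - lambda * sum_{i != j} |k_ij|
// by cycling over columns; each column update is a lasso regression
//   min_b 0.5 b' W11 b - s12' b + lambda ||b||_1
// solved by coordinate descent. K is recovered from the stored block
// coefficients, so its off-diagonal zeros are exact.
//
// W0 / B0 allow warm starts along a penalty path.
// [[Rcpp::export]]
Rcpp::List glasso_cd(const arma::mat& S, double lambda, double tol, int max_iter,
                     Rcpp::Nullable<Rcpp::NumericMatrix> W0 = R_NilValue,
                     Rcpp::Nullable<Rcpp::NumericMatrix> B0 = R_NilValue) {
  const uword p = S.n_rows;
  mat W(p, p), B(p, p, fill::zeros);
  if (W0.isNotNull()) {
    W = Rcpp::as<mat>(W0.get());
  } else {
    W = S;
  }
  if (B0.isNotNull()) B = Rcpp::as<mat>(B0.get());
  // diagonal is unpenalized: w_jj = s_jj always
  W.diag() = S.diag();

  if (p == 1) {
    mat K(1, 1);
    K(0, 0) = 1.0 / S(0, 0);
    return Rcpp::List::create(Rcpp::Named("K") = K, Rcpp::Named("W") = W,
                              Rcpp::Named("B") = B,
                              Rcpp::Named("iterations") = 0,
                              Rcpp::Named("converged") = true);
  }

  const double inner_tol = tol * 1e-2;
  const int inner_max = 200;
  bool converged = false;
  int it = 0;

  uvec all = regspace<uvec>(0, p - 1);
  for (it = 1; it <= max_iter; ++it) {
    double max_change = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx = find(all != j);
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j);
      s12 = s12.elem(idx);
      vec beta = B.col(j);
      beta = beta.elem(idx);

      // coordinate descent on the lasso subproblem
      for (int inner = 0; inner < inner_max; ++inner) {
        double dmax = 0.0;
        for (uword k = 0; k < p - 1; ++k) {
          double wkk = W11(k, k);
          double r = s12(k) - dot(W11.col(k), beta) + wkk * beta(k);
          double bnew = soft(r, lambda) / wkk;
          double d = std::abs(bnew - beta(k));
          if (d > dmax) dmax = d;
          beta(k) = bnew;
        }
        if (dmax < inner_tol) break;
      }

      vec w12 = W11 * beta;
      for (uword k = 0; k < p - 1; ++k) {
        double d = std::abs(w12(k) - W(idx(k), j));
        if (d > max_change) max_change = d;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
        B(idx(k), j) = beta(k);
      }
    }
    if (max_change < tol) { converged = true; break; }
  }

  // recover the precision matrix from the block coefficients
  mat K(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    uvec idx = find(all != j);
    vec beta = B.col(j);
    beta = beta.elem(idx);
    vec w12 = W.col(j);
    w12 = w12.elem(idx);
    double theta22 = 1.0 / (W(j, j) - dot(w12, beta));
    K(j, j) = theta22;
    for (uword k = 0; k < p - 1; ++k) K(idx(k), j) = -beta(k) * theta22;
  }
  K = 0.5 * (K + K.t());
  // the two block estimates of a symmetric zero agree only to solver
  // tolerance; snap near-zeros so the edge set is exact
  for (uword i = 0; i < p; ++i)
    for (uword j = 0; j < p; ++j)
      if (i != j && std::abs(K(i, j)) < 1e-10) K(i, j) = 0.0;

  return Rcpp::List::create(Rcpp::Named("K") = K, Rcpp::Named("W") = W,
                            Rcpp::Named("B") = B,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("converged") = converged);
}
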