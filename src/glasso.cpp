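#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Soft-threshold operator.
static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Graphical lasso by block coordinate descent (Friedman-style sweeps over
// columns of the working covariance W, each block solved by an inner lasso
// coordinate descent).  Maximises
//     log det K - tr(S K) - lambda * sum_{i != j} |k_ij|
// with the diagonal of K unpenalised (so diag(W) stays at diag(S)).
//
// S must be symmetric with strictly positive diagonal; lambda >= 0.
// Returns the estimated covariance W, precision K, convergence info.
// [[Rcpp::export]]
Rcpp::List glasso_cpp(const arma::mat& S, double lambda,
                      int max_iter = 200, double tol = 1e-7,
                      int inner_max_iter = 500, double inner_tol = 1e-9) {
  const uword p = S.n_rows;
  mat W = S;                 // working covariance; diagonal unpenalised
  mat B(p, p, fill::zeros);  // column j holds beta for block j (entry j unused)

  // scale for the convergence criterion: mean absolute off-diagonal of S
  double s_scale = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = 0; j < p; ++j)
      if (i != j) s_scale += std::fabs(S(i, j));
  s_scale /= std::max(1.0, double(p * (p - 1)));
  if (s_scale < 1e-8) s_scale = 1e-8;

  bool converged = false;
  double max_delta = 0.0;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    max_delta = 0.0;
    for (uword j = 0; j < p; ++j) {
      // inner lasso: minimise 1/2 b' W11 b - s12' b + lambda |b|_1
      vec beta(p, fill::zeros);
      for (uword k = 0; k < p; ++k) beta(k) = B(k, j);  // warm start
      for (int it2 = 0; it2 < inner_max_iter; ++it2) {
        double delta2 = 0.0;
        for (uword k = 0; k < p; ++k) {
          if (k == j) continue;
          // gradient residual excluding k
          double r = S(k, j);
          for (uword l = 0; l < p; ++l) {
            if (l == j || l == k) continue;
            r -= W(k, l) * beta(l);
          }
          double bk = soft(r, lambda) / W(k, k);
          double d = std::fabs(bk - beta(k));
          if (d > delta2) delta2 = d;
          beta(k) = bk;
        }
        if (delta2 < inner_tol) break;
      }
      for (uword k = 0; k < p; ++k) B(k, j) = beta(k);
      // update column j of W: w12 = W11 beta
      for (uword k = 0; k < p; ++k) {
        if (k == j) continue;
        double w = 0.0;
        for (uword l = 0; l < p; ++l) {
          if (l == j) continue;
          w += W(k, l) * beta(l);
        }
        double d = std::fabs(w - W(k, j));
        if (d > max_delta) max_delta = d;
        W(k, j) = w;
        W(j, k) = w;
      }
    }
    if (max_delta < tol * s_scale) { converged = true; ++iter; break; }
  }

  // recover the precision matrix from the final blocks
  mat K(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    double q = W(j, j);
    for (uword k = 0; k < p; ++k)
      if (k != j) q -= W(k, j) * B(k, j);
    double kjj = 1.0 / q;
    K(j, j) = kjj;
    for (uword k = 0; k < p; ++k)
      if (k != j) K(k, j) = -B(k, j) * kjj;
  }
  K = 0.5 * (K + K.t());
  // exact zeros can be perturbed by symmetrisation; re-zero where both blocks agree
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j)
      if (B(i, j) == 0.0 && B(j, i) == 0.0) { K(i, j) = 0.0; K(j, i) = 0.0; }

  return Rcpp::List::create(
      Rcpp::Named("W") = W, Rcpp::Named("K") = K,
      Rcpp::Named("iterations") = iter,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("max_delta") = max_delta);
}

// One pass of lasso coordinate descent for block j over the index set `idx`;
// returns the largest coefficient change.
static inline double cd_pass(const mat& S, const mat& W, mat& B, double lambda,
                             uword j, const std::vector<uword>& idx) {
  const uword p = S.n_rows;
  double delta = 0.0;
  for (uword k : idx) {
    double r = S(k, j);
    for (uword l = 0; l < p; ++l) {
      if (l == j || l == k) continue;
      double blj = B(l, j);
      if (blj != 0.0) r -= W(k, l) * blj;
    }
    double bk = soft(r, lambda) / W(k, k);
    double d = std::fabs(bk - B(k, j));
    if (d > delta) delta = d;
    B(k, j) = bk;
  }
  return delta;
}

// One block-coordinate-descent solve with warm-started state (W, B modified
// in place).  Inner lasso uses an active-set strategy: full sweeps to find
// the support, then cheap sweeps over the nonzero set.  Returns true on
// convergence.
static bool glasso_solve(const mat& S, double lambda, mat& W, mat& B,
                         int max_iter, double tol, int inner_max_iter,
                         double inner_tol, double s_scale) {
  const uword p = S.n_rows;
  std::vector<uword> all_idx, act_idx;
  all_idx.reserve(p);
  for (int iter = 0; iter < max_iter; ++iter) {
    double max_delta = 0.0;
    for (uword j = 0; j < p; ++j) {
      all_idx.clear();
      for (uword k = 0; k < p; ++k)
        if (k != j) all_idx.push_back(k);
      int it2 = 0;
      while (it2 < inner_max_iter) {
        double d_full = cd_pass(S, W, B, lambda, j, all_idx);
        ++it2;
        if (d_full < inner_tol) break;
        act_idx.clear();
        for (uword k : all_idx)
          if (B(k, j) != 0.0) act_idx.push_back(k);
        while (it2 < inner_max_iter) {
          double d_act = cd_pass(S, W, B, lambda, j, act_idx);
          ++it2;
          if (d_act < inner_tol) break;
        }
      }
      for (uword k = 0; k < p; ++k) {
        if (k == j) continue;
        double w = 0.0;
        for (uword l = 0; l < p; ++l) {
          if (l == j) continue;
          w += W(k, l) * B(l, j);
        }
        double d = std::fabs(w - W(k, j));
        if (d > max_delta) max_delta = d;
        W(k, j) = w;
        W(j, k) = w;
      }
    }
    if (max_delta < tol * s_scale) return true;
  }
  return false;
}

// Full penalty path with warm starts (lambdas in decreasing order).
// For each lambda returns the precision matrix (slice of a cube), the
// unit log-likelihood term log det K - tr(S K), and the edge count at
// support tolerance 1e-6.
// [[Rcpp::export]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           int max_iter = 200, double tol = 1e-6,
                           int inner_max_iter = 500, double inner_tol = 1e-8) {
  const uword p = S.n_rows;
  const uword L = lambdas.n_elem;
  mat W = S;
  mat B(p, p, fill::zeros);

  double s_scale = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = 0; j < p; ++j)
      if (i != j) s_scale += std::fabs(S(i, j));
  s_scale /= std::max(1.0, double(p * (p - 1)));
  if (s_scale < 1e-8) s_scale = 1e-8;

  cube Ks(p, p, L);
  vec loglik_unit(L);
  ivec edge_count(L);
  Rcpp::LogicalVector conv(L);

  for (uword m = 0; m < L; ++m) {
    bool ok = glasso_solve(S, lambdas(m), W, B, max_iter, tol,
                           inner_max_iter, inner_tol, s_scale);
    conv[m] = ok;
    mat K(p, p, fill::zeros);
    for (uword j = 0; j < p; ++j) {
      double q = W(j, j);
      for (uword k = 0; k < p; ++k)
        if (k != j) q -= W(k, j) * B(k, j);
      double kjj = 1.0 / q;
      K(j, j) = kjj;
      for (uword k = 0; k < p; ++k)
        if (k != j) K(k, j) = -B(k, j) * kjj;
    }
    K = 0.5 * (K + K.t());
    int ec = 0;
    for (uword i = 0; i < p; ++i)
      for (uword j = i + 1; j < p; ++j) {
        if (B(i, j) == 0.0 && B(j, i) == 0.0) { K(i, j) = 0.0; K(j, i) = 0.0; }
        if (std::fabs(K(i, j)) > 1e-6) ++ec;
      }
    Ks.slice(m) = K;
    edge_count(m) = ec;
    double ld, sign;
    log_det(ld, sign, K);
    loglik_unit(m) = ld - accu(S % K);
  }
  return Rcpp::List::create(
      Rcpp::Named("K") = Ks, Rcpp::Named("loglik_unit") = loglik_unit,
      Rcpp::Named("edge_count") = edge_count,
      Rcpp::Named("converged") = conv);
}
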