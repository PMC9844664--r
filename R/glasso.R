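#' Graphical lasso at a single penalty
#'
#' L1-penalized Gaussian maximum likelihood for a sparse precision matrix:
#' maximizes `log det K - tr(S K) - lambda * sum_{i != j} |k_ij|` (diagonal
#' unpenalized) by block coordinate descent over columns of the working
#' covariance, each block solved by an inner lasso coordinate descent.
#'
#' @param S Correlation/covariance matrix (symmetric, unit diagonal expected,
#'   PSD after repair), or a [cor_matrix()].
#' @param lambda Penalty, >= 0.
#' @param tol Outer convergence tolerance on the working covariance, relative
#'   to the mean absolute off-diagonal of `S`.
#' @param max_iter Maximum outer sweeps.
#' @return Object of class `glasso_fit`: `lambda`, `K` (precision estimate),
#'   `W` (covariance estimate), `loglik_unit` (`log det K - tr(S K)`),
#'   `edge_count` (off-diagonal support pairs at tolerance 1e-6),
#'   `converged`, `iterations`.
#' @export
graphical_lasso <- function(S, lambda, tol = 1e-7, max_iter = 200) {
  if (inherits(S, "cor_matrix")) S <- S$R
  S <- as.matrix(S)
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
    stop("S must be symmetric")
  if (lambda < 0 || !is.finite(lambda)) stop("lambda must be finite and >= 0")
  ev_min <- min(eigen((S + t(S)) / 2, symmetric = TRUE,
                      only.values = TRUE)$values)
  if (ev_min < -1e-8)
    stop("S is not positive semidefinite (min eigenvalue ", signif(ev_min, 3),
         "); apply nearest_psd() first")
  fit <- glasso_cpp((S + t(S)) / 2, lambda, max_iter = max_iter, tol = tol)
  if (!fit$converged)
    stop("graphical lasso failed to converge; last parameter change = ",
         signif(fit$max_delta, 3))
  K <- fit$K
  dimnames(K) <- dimnames(S)
  ec <- sum(abs(K[upper.tri(K)]) > 1e-6)
  ld <- determinant(K, logarithm = TRUE)
  loglik_unit <- as.numeric(ld$modulus) - sum(S * K)
  structure(list(lambda = lambda, K = K, W = fit$W,
                 loglik_unit = loglik_unit, edge_count = ec,
                 converged = fit$converged, iterations = fit$iterations),
            class = "glasso_fit")
}

#' Extended BIC of a graphical lasso fit
#'
#' `EBIC = -2 l(K) + E log n + 4 gamma E log p` with
#' `l(K) = (n/2) (log det K - tr(S K))` and `E` the number of selected edges.
#'
#' @param fit A [graphical_lasso()] fit.
#' @param S The correlation matrix the fit was computed on.
#' @param n Sample size.
#' @param gamma EBIC hyperparameter, >= 0 (0 gives plain BIC).
#' @return The EBIC value (smaller is better).
#' @export
ebic_score <- function(fit, S, n, gamma = 0.5) {
  if (gamma < 0) stop("gamma must be >= 0")
  if (inherits(S, "cor_matrix")) S <- S$R
  p <- nrow(S)
  if (n < p) warning("n < p: EBIC is computed but poorly calibrated")
  ll <- (n / 2) * fit$loglik_unit
  E <- fit$edge_count
  -2 * ll + E * log(n) + 4 * gamma * E * log(p)
}

#' Log-spaced penalty path for the graphical lasso
#'
#' From `lambda_max` (the largest absolute off-diagonal of `S`, at or above
#' which the selected network is empty) down to
#' `lambda_max * lambda_min_ratio`.
#'
#' @param S Correlation matrix or `cor_matrix`.
#' @param n_lambda Number of penalties (>= 2).
#' @param lambda_min_ratio Ratio of smallest to largest penalty, in (0, 1).
#' @return Decreasing numeric vector of penalties.
#' @export
lambda_path <- function(S, n_lambda = 100, lambda_min_ratio = 0.01) {
  if (inherits(S, "cor_matrix")) S <- S$R
  if (n_lambda < 2) stop("n_lambda must be >= 2")
  if (lambda_min_ratio <= 0 || lambda_min_ratio >= 1)
    stop("lambda_min_ratio must be in (0, 1)")
  lmax <- max(abs(S[upper.tri(S)]))
  if (lmax <= 0) lmax <- 0.1
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}
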