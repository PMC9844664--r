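# Independent oracles used across tests. These deliberately avoid the code
# paths they check: the glasso oracle is a proximal-gradient ascent on the
# penalized likelihood, the centrality oracle enumerates simple paths.

# Proximal-gradient maximization of
#   log det K - tr(S K) - lambda * sum_{i != j} |k_ij|
# with backtracking to stay positive definite. Slow but independent of the
# block-coordinate-descent implementation.
oracle_glasso <- function(S, lambda, max_iter = 100000, tol = 1e-11) {
  p <- nrow(S)
  K <- diag(p)
  eta <- 0.1
  prox <- function(M, t) {
    O <- sign(M) * pmax(abs(M) - t, 0)
    diag(O) <- diag(M)
    O
  }
  obj <- function(K) {
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return(-Inf)
    sum(log(ev)) - sum(S * K) - lambda * (sum(abs(K)) - sum(abs(diag(K))))
  }
  f_old <- obj(K)
  for (it in seq_len(max_iter)) {
    G <- solve(K) - S
    repeat {
      K_new <- prox(K + eta * G, eta * lambda)
      ev <- min(eigen(K_new, symmetric = TRUE, only.values = TRUE)$values)
      if (ev > 0) {
        f_new <- obj(K_new)
        if (f_new >= f_old - 1e-12) break
      }
      eta <- eta / 2
      if (eta < 1e-12) return(K)
    }
    delta <- max(abs(K_new - K))
    K <- K_new
    f_old <- f_new
    eta <- min(eta * 1.2, 1)
    if (delta < tol) break
  }
  K
}

# All simple paths between a and b in an undirected weighted graph given by
# the length matrix L (Inf = no edge).
.all_simple_paths <- function(L, a, b) {
  p <- nrow(L)
  out <- list()
  walk <- function(path, len) {
    v <- path[length(path)]
    if (v == b) {
      out[[length(out) + 1]] <<- list(path = path, len = len)
      return(invisible())
    }
    for (w in seq_len(p)) {
      if (is.finite(L[v, w]) && !(w %in% path))
        walk(c(path, w), len + L[v, w])
    }
  }
  walk(a, 0)
  out
}

# Exhaustive centrality: distances, closeness (reciprocal sum over reachable),
# betweenness with fractional credit for tied shortest paths.
oracle_centrality <- function(W, tie_tol = 1e-9) {
  p <- nrow(W)
  L <- ifelse(abs(W) > 0, 1 / abs(W), Inf)
  diag(L) <- Inf
  D <- matrix(Inf, p, p)
  diag(D) <- 0
  btw <- numeric(p)
  for (a in seq_len(p - 1)) {
    for (b in (a + 1):p) {
      paths <- .all_simple_paths(L, a, b)
      if (length(paths) == 0) next
      lens <- vapply(paths, `[[`, numeric(1), "len")
      dmin <- min(lens)
      D[a, b] <- D[b, a] <- dmin
      short <- paths[lens <= dmin + tie_tol]
      ns <- length(short)
      for (sp in short) {
        interior <- setdiff(sp$path, c(a, b))
        btw[interior] <- btw[interior] + 1 / ns
      }
    }
  }
  closeness <- vapply(seq_len(p), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else 1 / sum(d)
  }, numeric(1))
  list(distances = D, strength = rowSums(abs(W)), closeness = closeness,
       betweenness = btw, expected_influence = rowSums(W))
}

# Random sparse symmetric weight matrix for centrality tests.
random_weight_matrix <- function(p, edge_prob = 0.5, seed = 1) {
  set.seed(seed)
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (runif(1) < edge_prob)
        W[i, j] <- W[j, i] <- runif(1, 0.1, 0.9) * sample(c(-1, 1), 1)
    }
  }
  W
}

# Random correlation matrix (PD) via random factor structure.
random_correlation <- function(p, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p, p)
  S <- crossprod(A) + diag(p) * 0.5
  stats::cov2cor(S)
}

# Small bivariate ordinal sample from a latent normal with correlation rho.
sim_ordinal_pair <- function(n, rho, cuts_x, cuts_y, seed) {
  set.seed(seed)
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  list(x = findInterval(z1, cuts_x), y = findInterval(z2, cuts_y))
}

# Two-group dataset with a shared base network but different density scales.
two_group_data <- function(n_per_group, scale1, scale2, seed,
                           edge_prob = 0.25, weight_range = c(0.15, 0.35)) {
  spec <- generator_spec(
    n_per_group = c("<5y" = n_per_group, "5-10y" = n_per_group),
    density_scale = c(scale1, scale2),
    edge_prob = edge_prob, weight_range = weight_range,
    covariate_effects = c(chemotherapy = 0, cardiovascular = 0,
                          duration_years = 0),
    seed = seed)
  generate_study(spec)
}
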