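#' Nonparametric bootstrap of edge weights
#'
#' Resamples participants with replacement `B` times, refits the whole
#' network per resample (including per-replicate penalty re-selection, so
#' model-selection uncertainty propagates), and returns percentile confidence
#' intervals per edge. Node strength and expected influence are recorded per
#' replicate as well, for bootstrapped difference tests on centrality.
#'
#' @param data A `symptom_dataset`.
#' @param settings An [estimation_settings()].
#' @param covariates Covariate names passed to [estimate_network()].
#' @param B Number of bootstrap replicates (>= 100 recommended for CI use).
#' @param seed Master seed; replicate `b` uses a counter-derived substream.
#' @param conf Confidence level (default 0.95).
#' @return Object of class `edge_bootstrap`: `edges` (pair labels), `point`
#'   (full-sample weights), `replicate_weights` (B x E), `ci_low`, `ci_high`,
#'   `replicate_strength`, `replicate_ei` (B x p), `B`, `seed`, `failures`.
#' @export
bootstrap_edge_ci <- function(data, settings = estimation_settings(),
                              covariates = NULL, B = 1000, seed = 1,
                              conf = 0.95) {
  stopifnot(inherits(data, "symptom_dataset"))
  if (B < 1) stop("B must be >= 1")
  if (B < 100) warning("B < 100: percentile CIs will be unreliable")
  n <- nrow(data$values)
  full <- estimate_network(data, settings, covariates)
  pairs <- .upper_pairs(full$labels)
  E <- nrow(pairs)
  p <- length(full$labels)
  RW <- matrix(NA_real_, B, E)
  RS <- matrix(NA_real_, B, p, dimnames = list(NULL, full$labels))
  RE <- matrix(NA_real_, B, p, dimnames = list(NULL, full$labels))
  failures <- 0L
  for (b in seq_len(B)) {
    set.seed(.substream_seed(seed, b))
    idx <- sample.int(n, n, replace = TRUE)
    net_b <- tryCatch(estimate_network(subset_rows(data, idx), settings,
                                       covariates),
                      error = function(e) NULL)
    if (is.null(net_b)) { failures <- failures + 1L; next }
    RW[b, ] <- net_b$W[cbind(pairs$i, pairs$j)]
    RS[b, ] <- rowSums(abs(net_b$W))
    RE[b, ] <- rowSums(net_b$W)
  }
  if (failures > 0.1 * B)
    stop(failures, " of ", B, " bootstrap replicates failed")
  a <- (1 - conf) / 2
  ci <- apply(RW, 2, quantile, probs = c(a, 1 - a), na.rm = TRUE)
  structure(list(
    edges = pairs, point = full$W[cbind(pairs$i, pairs$j)],
    replicate_weights = RW, ci_low = ci[1, ], ci_high = ci[2, ],
    replicate_strength = RS, replicate_ei = RE,
    B = B, seed = seed, conf = conf, failures = failures, network = full),
    class = "edge_bootstrap")
}

#' @export
print.edge_bootstrap <- function(x, ...) {
  cat(sprintf("edge_bootstrap: %d edges, B = %d (%d failed)\n",
              nrow(x$edges), x$B, x$failures))
  invisible(x)
}

#' Summarize an edge bootstrap as a data frame
#'
#' @param object An `edge_bootstrap`.
#' @param ... Unused.
#' @return Data frame `node_i, node_j, estimate, ci_low, ci_high`.
#' @export
summary.edge_bootstrap <- function(object, ...) {
  data.frame(node_i = object$edges$node_i, node_j = object$edges$node_j,
             estimate = object$point, ci_low = object$ci_low,
             ci_high = object$ci_high, stringsAsFactors = FALSE)
}

#' Case-dropping stability of centrality and the CS coefficient
#'
#' For each drop proportion `q`, draws `B` subsamples of `ceiling((1 - q) n)`
#' participants without replacement, refits the network, and correlates the
#' chosen node statistic with its full-sample value. The
#' correlation-stability (CS) coefficient is the largest `q` at which at
#' least 95% of replicates correlate >= 0.7 with the full sample (0 if none
#' does); values > 0.5 are preferred and > 0.25 is the minimum for
#' interpretability.
#'
#' @param data A `symptom_dataset`.
#' @param settings An [estimation_settings()].
#' @param statistic `"strength"`, `"expected_influence"`, or `"closeness"`.
#' @param proportions Drop-proportion grid in (0, 0.95)
#'   (default 0.10-0.75 by 0.05).
#' @param B Subsamples per proportion.
#' @param seed Master seed.
#' @param covariates Covariate names passed to [estimate_network()].
#' @param cor_threshold,confidence CS rule parameters (defaults 0.7, 0.95).
#' @return Object of class `stability_result`: `drop_proportions`,
#'   `correlations` (length(grid) x B), `cs_coefficient`, `statistic`,
#'   `skipped` (proportions whose subsample was below p + 1).
#' @export
case_dropping_stability <- function(data, settings = estimation_settings(),
                                    statistic = c("strength",
                                                  "expected_influence",
                                                  "closeness"),
                                    proportions = seq(0.10, 0.75, by = 0.05),
                                    B = 1000, seed = 1, covariates = NULL,
                                    cor_threshold = 0.7, confidence = 0.95) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(data, "symptom_dataset"))
  if (any(proportions <= 0 | proportions >= 0.95))
    stop("proportions must lie in (0, 0.95)")
  if (B < 100) warning("B < 100: CS estimate will be noisy")
  n <- nrow(data$values)
  p <- ncol(data$values)
  col <- c(strength = "strength", expected_influence = "expected_influence",
           closeness = "closeness")[statistic]
  full <- estimate_network(data, settings, covariates)
  s0 <- centrality_table(full)[[col]]
  corr <- matrix(NA_real_, length(proportions), B)
  skipped <- logical(length(proportions))
  flagged <- 0L
  for (qi in seq_along(proportions)) {
    m <- ceiling((1 - proportions[qi]) * n)
    if (m < p + 1) { skipped[qi] <- TRUE; next }
    for (b in seq_len(B)) {
      set.seed(.substream_seed(seed, qi * 100000L + b))
      idx <- sample.int(n, m, replace = FALSE)
      net_b <- tryCatch(estimate_network(subset_rows(data, idx), settings,
                                         covariates),
                        error = function(e) NULL)
      if (is.null(net_b)) next
      sb <- centrality_table(net_b)[[col]]
      if (sd(sb) == 0 || sd(s0) == 0) {
        corr[qi, b] <- 0
        flagged <- flagged + 1L
      } else {
        corr[qi, b] <- cor(sb, s0)
      }
    }
  }
  ok_q <- vapply(seq_along(proportions), function(qi) {
    r <- corr[qi, ]
    r <- r[!is.na(r)]
    length(r) > 0 && mean(r >= cor_threshold) >= confidence
  }, logical(1))
  cs <- if (any(ok_q)) max(proportions[ok_q]) else 0
  structure(list(drop_proportions = proportions, correlations = corr,
                 cs_coefficient = cs, statistic = statistic,
                 skipped = skipped, degenerate_replicates = flagged,
                 B = B, seed = seed, cor_threshold = cor_threshold,
                 confidence = confidence),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("stability_result (%s): CS = %.2f (threshold %.2f at %.0f%%)\n",
              x$statistic, x$cs_coefficient, x$cor_threshold,
              100 * x$confidence))
  invisible(x)
}

#' Bootstrapped difference test between edges or node statistics
#'
#' For every pair of edges (or nodes), forms the bootstrap distribution of
#' the difference and marks the pair significant when the central
#' `(1 - alpha)` percentile interval of the difference excludes 0. No
#' multiplicity correction is applied.
#'
#' @param boot An [bootstrap_edge_ci()] result.
#' @param what `"edges"`, `"strength"`, or `"expected_influence"`.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `diff_matrix`: symmetric logical `significant`
#'   matrix with `FALSE` diagonal, plus `alpha`, `what`, `labels`.
#' @export
bootstrap_difference_test <- function(boot, what = c("edges", "strength",
                                                     "expected_influence"),
                                      alpha = 0.05) {
  what <- match.arg(what)
  stopifnot(inherits(boot, "edge_bootstrap"))
  if (boot$B < 100) warning("B < 100: difference tests will be unreliable")
  R <- switch(what,
              edges = boot$replicate_weights,
              strength = boot$replicate_strength,
              expected_influence = boot$replicate_ei)
  labels <- if (what == "edges")
    paste(boot$edges$node_i, boot$edges$node_j, sep = "--")
  else colnames(R)
  m <- ncol(R)
  sig <- matrix(FALSE, m, m, dimnames = list(labels, labels))
  for (e in seq_len(m - 1)) {
    for (f in (e + 1):m) {
      d <- R[, e] - R[, f]
      d <- d[!is.na(d)]
      qs <- quantile(d, c(alpha / 2, 1 - alpha / 2))
      s <- qs[1] > 0 || qs[2] < 0
      sig[e, f] <- sig[f, e] <- s
    }
  }
  structure(list(significant = sig, alpha = alpha, what = what,
                 labels = labels),
            class = "diff_matrix")
}

#' @export
print.diff_matrix <- function(x, ...) {
  m <- x$significant
  cat(sprintf("diff_matrix (%s, alpha = %.2g): %d of %d pairs significant\n",
              x$what, x$alpha, sum(m[upper.tri(m)]),
              sum(upper.tri(m))))
  invisible(x)
}

#' Permutation test for a subgroup density difference
#'
#' The observed statistic is the absolute difference between the two groups'
#' Spearman-based network densities. The null distribution is built by
#' permuting group labels; the p-value uses the add-one estimator
#' `(1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @param data A `symptom_dataset` with a `group` field.
#' @param groups Length-2 character vector naming the groups to compare.
#' @param n_perm Number of label permutations (>= 100).
#' @param seed Master seed.
#' @return Object of class `permutation_result`: `observed_diff`,
#'   `null_draws`, `p_value`, `densities` (the two observed densities).
#' @export
density_comparison_test <- function(data, groups, n_perm = 1000, seed = 1) {
  stopifnot(inherits(data, "symptom_dataset"))
  if (is.null(data$group)) stop("dataset has no group labels")
  if (length(groups) != 2) stop("exactly two groups must be named")
  if (n_perm < 100) stop("n_perm must be >= 100")
  p <- ncol(data$values)
  sel <- data$group %in% groups
  X <- data$values[sel, , drop = FALSE]
  g <- data$group[sel]
  n1 <- sum(g == groups[1]); n2 <- sum(g == groups[2])
  if (n1 < p + 1 || n2 < p + 1)
    stop("each group needs at least p + 1 = ", p + 1, " rows")
  dens <- function(M) sum(abs(suppressWarnings(
    cor(M, method = "spearman"))[upper.tri(diag(p))]), na.rm = TRUE)
  d1 <- dens(X[g == groups[1], , drop = FALSE])
  d2 <- dens(X[g == groups[2], , drop = FALSE])
  observed <- abs(d1 - d2)
  null_draws <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    set.seed(.substream_seed(seed, k))
    gp <- sample(g)
    null_draws[k] <- abs(dens(X[gp == groups[1], , drop = FALSE]) -
                         dens(X[gp == groups[2], , drop = FALSE]))
  }
  p_value <- (1 + sum(null_draws >= observed)) / (1 + n_perm)
  structure(list(observed_diff = observed, null_draws = null_draws,
                 p_value = p_value,
                 densities = setNames(c(d1, d2), groups),
                 n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "density permutation test: |diff| = %.3f (%s: %.2f vs %s: %.2f), p = %.4g\n",
    x$observed_diff, names(x$densities)[1], x$densities[1],
    names(x$densities)[2], x$densities[2], x$p_value))
  invisible(x)
}
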