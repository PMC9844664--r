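#' Settings for partial-correlation network estimation
#'
#' @param correlation_method `"polychoric"` (default) or `"spearman"` for the
#'   symptom-symptom correlations feeding the graphical lasso.
#' @param gamma EBIC sparsity hyperparameter (default 0.5, the conservative
#'   field standard).
#' @param n_lambda Number of penalties on the log-spaced path (default 100).
#' @param lambda_min_ratio Smallest-to-largest penalty ratio (default 0.01).
#' @param covariate_mode `"as_nodes"` (covariates enter the joint network and
#'   are conditioned out by subnetwork extraction; default) or
#'   `"residualize"` (symptom ranks pre-residualized on covariates).
#' @return Object of class `estimation_settings`.
#' @export
estimation_settings <- function(correlation_method = c("polychoric", "spearman"),
                                gamma = 0.5, n_lambda = 100,
                                lambda_min_ratio = 0.01,
                                covariate_mode = c("as_nodes", "residualize")) {
  correlation_method <- match.arg(correlation_method)
  covariate_mode <- match.arg(covariate_mode)
  if (gamma < 0) stop("gamma must be >= 0")
  if (n_lambda < 2) stop("n_lambda must be >= 2")
  if (lambda_min_ratio <= 0 || lambda_min_ratio >= 1)
    stop("lambda_min_ratio must be in (0, 1)")
  structure(list(correlation_method = correlation_method, gamma = gamma,
                 n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                 covariate_mode = covariate_mode),
            class = "estimation_settings")
}

# Correlation matrix over symptoms (+ optional covariate nodes).
# Symptom-symptom: polychoric or Spearman per settings; any pair involving a
# covariate: Pearson on average ranks (= Spearman).
.input_correlation <- function(data, settings, covariates = NULL) {
  X <- data$values
  if (is.null(covariates) || length(covariates) == 0) {
    if (settings$correlation_method == "polychoric") {
      return(polychoric_matrix(data))
    }
    return(spearman_matrix(data))
  }
  C <- as.matrix(data$covariates[, covariates, drop = FALSE])
  p <- ncol(X); q <- ncol(C)
  Rsym <- if (settings$correlation_method == "polychoric")
    polychoric_matrix(data) else spearman_matrix(data)
  full <- cbind(X, C)
  Rrank <- suppressWarnings(cor(apply(full, 2, rank), method = "pearson"))
  Rrank[is.na(Rrank)] <- 0
  R <- Rrank
  R[1:p, 1:p] <- Rsym$R
  diag(R) <- 1
  dimnames(R) <- list(colnames(full), colnames(full))
  rep <- nearest_psd(R, floor = 1e-6)
  cor_matrix(rep$R, Rsym$method, nrow(X),
             psd_repaired = rep$changed || Rsym$psd_repaired,
             flags = Rsym$flags)
}

# Rank-residualize symptom columns on covariates, then Pearson correlation.
.residualized_correlation <- function(data, covariates) {
  X <- apply(data$values, 2, rank)
  C <- as.matrix(data$covariates[, covariates, drop = FALSE])
  res <- apply(X, 2, function(y) stats::residuals(lm(y ~ C)))
  R <- cor(res)
  rep <- nearest_psd(R, floor = 1e-6)
  cor_matrix(rep$R, "spearman", nrow(X), psd_repaired = rep$changed)
}

#' Estimate a sparse partial-correlation symptom network
#'
#' Builds the input correlation matrix (polychoric among symptoms by default;
#' covariates, if any, enter as extra rank-correlated nodes), fits the
#' graphical lasso along a log-spaced penalty path, selects the penalty
#' minimizing the extended BIC, converts the selected precision matrix to
#' partial correlations, and returns the symptom-by-symptom subnetwork with
#' covariates conditioned out.
#'
#' @param data A `symptom_dataset` with at least 2 symptom columns.
#' @param settings An [estimation_settings()].
#' @param covariates Character vector of covariate names to condition on
#'   (default none).
#' @return Object of class `pcor_network`: `W` (p x p partial-correlation
#'   edge weights, zero diagonal), `labels`, `lambda_selected`, `gamma`,
#'   `conditioned_on`, `K` (selected joint precision matrix), `path`
#'   (lambdas, EBICs, edge counts), `settings`, `n`, `correlation`.
#' @export
estimate_network <- function(data, settings = estimation_settings(),
                             covariates = NULL) {
  stopifnot(inherits(data, "symptom_dataset"))
  if (ncol(data$values) < 2) stop("need at least 2 symptom columns")
  n <- nrow(data$values)
  p <- ncol(data$values)

  if (!is.null(covariates) && length(covariates) &&
      settings$covariate_mode == "residualize") {
    S <- .residualized_correlation(data, covariates)
    cond <- covariates
    covariates_nodes <- NULL
  } else {
    S <- .input_correlation(data, settings, covariates)
    cond <- if (is.null(covariates)) character() else covariates
    covariates_nodes <- cond
  }

  rep <- nearest_psd(S$R, floor = 1e-6)
  Sm <- rep$R
  lambdas <- lambda_path(Sm, settings$n_lambda, settings$lambda_min_ratio)
  pf <- glasso_path_cpp(Sm, lambdas)
  ok <- as.logical(pf$converged)
  if (!any(ok)) stop("graphical lasso failed at every penalty on the path")
  pfull <- nrow(Sm)
  edges <- as.integer(pf$edge_count)
  ebics <- -n * pf$loglik_unit + edges * log(n) +
    4 * settings$gamma * edges * log(pfull)
  ebics[!ok] <- Inf
  best <- which.min(ebics)
  K_best <- pf$K[, , best]
  dimnames(K_best) <- dimnames(Sm)
  fit <- list(K = K_best, loglik_unit = pf$loglik_unit[best],
              edge_count = edges[best])

  Wfull <- precision_to_pcor(fit$K)
  dimnames(Wfull) <- dimnames(S$R)
  sym_idx <- seq_len(p)
  W <- Wfull[sym_idx, sym_idx, drop = FALSE]
  diag(W) <- 0
  structure(list(
    W = W, labels = data$item_labels, lambda_selected = lambdas[best],
    gamma = settings$gamma, conditioned_on = cond,
    K = fit$K, path = data.frame(lambda = lambdas, ebic = ebics,
                                 edge_count = edges, converged = ok),
    settings = settings, n = n, correlation = S),
    class = "pcor_network")
}

#' @export
print.pcor_network <- function(x, ...) {
  ne <- sum(abs(x$W[upper.tri(x$W)]) > 1e-10)
  cat(sprintf(
    "pcor_network: %d nodes, %d edges (lambda = %.4f, gamma = %.2f, n = %d)\n",
    nrow(x$W), ne, x$lambda_selected, x$gamma, x$n))
  if (length(x$conditioned_on))
    cat("  conditioned on:", paste(x$conditioned_on, collapse = ", "), "\n")
  invisible(x)
}

#' Edge list of a partial-correlation network
#'
#' @param net A `pcor_network`.
#' @param all Include zero-weight pairs (default `FALSE`).
#' @return Data frame `node_i, node_j, weight`.
#' @export
edge_list <- function(net, all = FALSE) {
  pr <- .upper_pairs(net$labels)
  pr$weight <- net$W[cbind(pr$i, pr$j)]
  if (!all) pr <- pr[abs(pr$weight) > 1e-10, , drop = FALSE]
  pr[, c("node_i", "node_j", "weight")]
}

#' Write a network to disk (edge list, adjacency, GraphML)
#'
#' @param net A `pcor_network`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(edge_list(net), file.path(dir, "edges.csv"), row.names = FALSE)
  write.csv(as.data.frame(net$W), file.path(dir, "adjacency.csv"),
            row.names = TRUE)
  g <- .net_igraph(net, abs_weights = FALSE)
  igraph::write_graph(g, file.path(dir, "network.graphml"), format = "graphml")
  jsonlite::write_json(
    list(lambda_selected = net$lambda_selected, gamma = net$gamma,
         conditioned_on = net$conditioned_on, n = net$n,
         correlation_method = net$settings$correlation_method,
         covariate_mode = net$settings$covariate_mode),
    file.path(dir, "settings.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# igraph view of the network; edge attribute `weight` is |w| (or signed w),
# `length` is 1/|w| for shortest-path work.
.net_igraph <- function(net, abs_weights = TRUE) {
  A <- if (abs_weights) abs(net$W) else net$W
  g <- igraph::graph_from_adjacency_matrix(abs(net$W), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$length <- 1 / igraph::E(g)$weight
  if (!abs_weights) {
    el <- igraph::as_edgelist(g, names = FALSE)
    igraph::E(g)$weight <- net$W[el]
  }
  g
}
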