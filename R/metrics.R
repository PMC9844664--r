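#' All-pairs shortest-path distances of a weighted network
#'
#' Edge lengths are `1 / |w_ij|` for nonzero edges, so strong associations are
#' short. Unreachable pairs get `Inf`; the diagonal is 0.
#'
#' @param net A `pcor_network` (or square weight matrix).
#' @return p x p distance matrix.
#' @export
shortest_path_distances <- function(net) {
  W <- if (inherits(net, "pcor_network")) net$W else as.matrix(net)
  labels <- rownames(W)
  if (is.null(labels)) labels <- paste0("node_", seq_len(nrow(W)))
  dimnames(W) <- list(labels, labels)
  g <- igraph::graph_from_adjacency_matrix(abs(W), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                         algorithm = "dijkstra")
  D[match(labels, rownames(D)), match(labels, colnames(D)), drop = FALSE]
}

#' Centrality indices of a partial-correlation network
#'
#' Strength is the row sum of absolute edge weights, expected influence the
#' signed row sum. Closeness is the reciprocal of the total shortest-path
#' distance to all *reachable* nodes (0 for an isolated node). Betweenness
#' counts, for every other node pair, the shortest paths through the node,
#' with fractional credit when several shortest paths tie.
#'
#' @param net A `pcor_network` (or square weight matrix).
#' @return Data frame of class `centrality_table`: `node`, `strength`,
#'   `closeness`, `betweenness`, `expected_influence`.
#' @export
centrality_table <- function(net) {
  W <- if (inherits(net, "pcor_network")) net$W else as.matrix(net)
  labels <- rownames(W)
  if (is.null(labels)) labels <- paste0("node_", seq_len(nrow(W)))
  dimnames(W) <- list(labels, labels)
  p <- nrow(W)
  strength <- rowSums(abs(W))
  ei <- rowSums(W)
  D <- shortest_path_distances(W)
  closeness <- vapply(seq_len(p), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else 1 / sum(d)
  }, numeric(1))
  g <- igraph::graph_from_adjacency_matrix(abs(W), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  btw <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight)
  btw_full <- setNames(numeric(p), labels)
  btw_full[names(btw)] <- btw
  out <- data.frame(node = labels, strength = unname(strength),
                    closeness = closeness, betweenness = unname(btw_full),
                    expected_influence = unname(ei),
                    stringsAsFactors = FALSE)
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Network density statistic
#'
#' The sum of absolute pairwise coefficients over all node pairs. The default
#' basis is the Spearman correlation matrix (the prognosis-linked definition);
#' `basis = "edge_weights"` sums the estimated partial-correlation weights
#' instead, for sensitivity analysis.
#'
#' @param x A `symptom_dataset` (Spearman basis), `cor_matrix`, square
#'   matrix, or `pcor_network` (edge-weight basis).
#' @param basis `"spearman"` or `"edge_weights"`.
#' @return Object of class `density_value`: list with `value` and `basis`.
#' @export
network_density <- function(x, basis = c("spearman", "edge_weights")) {
  basis <- match.arg(basis)
  if (inherits(x, "symptom_dataset")) {
    if (basis != "spearman")
      stop("edge_weights basis needs an estimated network, not raw data")
    M <- spearman_matrix(x)$R
  } else if (inherits(x, "pcor_network")) {
    basis <- "edge_weights"
    M <- x$W
  } else if (inherits(x, "cor_matrix")) {
    M <- x$R
  } else {
    M <- as.matrix(x)
  }
  if (nrow(M) != ncol(M)) stop("input must be square")
  v <- sum(abs(M[upper.tri(M)]))
  structure(list(value = v, basis = basis), class = "density_value")
}

#' @export
print.density_value <- function(x, ...) {
  cat(sprintf("network density (%s basis): %.4f\n", x$basis, x$value))
  invisible(x)
}

#' Node predictability
#'
#' For each node, the proportion of variance of its rank-transformed scores
#' explained by ordinary least squares on the rank-transformed scores of its
#' network neighbors. A node with no neighbors has predictability 0. This is
#' a nodewise variance-explained summary on the selected neighborhood, not a
#' separate mixed-graphical-model refit.
#'
#' @param data The `symptom_dataset` the network was estimated from.
#' @param net A `pcor_network` sharing the data's item labels.
#' @return Data frame of class `predictability_table`: `node`, `r_squared`,
#'   `n_neighbors`, `flag` (`"collinear"` when predictors alias).
#' @export
node_predictability <- function(data, net) {
  stopifnot(inherits(data, "symptom_dataset"), inherits(net, "pcor_network"))
  if (!identical(colnames(data$values), rownames(net$W)) &&
      !identical(data$item_labels, net$labels))
    stop("data and network labels differ")
  X <- apply(data$values, 2, rank)
  p <- ncol(X)
  out <- data.frame(node = net$labels, r_squared = 0,
                    n_neighbors = 0L, flag = "", stringsAsFactors = FALSE)
  for (i in seq_len(p)) {
    nb <- which(abs(net$W[i, ]) > 1e-10)
    nb <- setdiff(nb, i)
    out$n_neighbors[i] <- length(nb)
    if (length(nb) == 0) next
    y <- X[, i]
    if (var(y) == 0) { out$flag[i] <- "zero_variance"; next }
    fit <- lm(y ~ X[, nb, drop = FALSE])
    if (anyNA(coef(fit))) out$flag[i] <- "collinear"
    out$r_squared[i] <- summary(fit)$r.squared
  }
  class(out) <- c("predictability_table", "data.frame")
  out
}
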