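#' MDASI severity item labels
#'
#' The 13 symptom-severity items of the MD Anderson Symptom Inventory
#' (severity domain), in questionnaire order.
#'
#' @return Character vector of length 13.
#' @export
mdasi_items <- function() {
  c("pain", "fatigue", "disturbed_sleep", "distress", "shortness_of_breath",
    "drowsiness", "dry_mouth", "sadness", "difficulty_remembering",
    "numbness_tingling", "lack_of_appetite", "nausea", "vomiting")
}

#' Reference marginal distribution of the 13 MDASI severity items
#'
#' Published marginal summaries for a large community cohort of cancer
#' survivors: per-item prevalence (proportion scoring >= 1) and mean severity
#' on the 0-10 scale. Used as the calibration target of the synthetic-data
#' generator.
#'
#' @return Data frame with columns `item`, `prevalence`, `mean`.
#' @export
mdasi_reference_marginals <- function() {
  data.frame(
    item = mdasi_items(),
    prevalence = c(0.4977, 0.7268, 0.6394, 0.5033, 0.4441, 0.4798, 0.4498,
                   0.4291, 0.5840, 0.3906, 0.5221, 0.3296, 0.2779),
    mean = c(1.71, 2.71, 2.34, 1.80, 1.49, 1.69, 1.58, 1.53, 2.12, 1.41,
             1.71, 1.17, 1.02),
    stringsAsFactors = FALSE
  )
}

# Conditional severity distribution over scores 1..10 given symptomatic:
# geometric decay p_j \propto exp(-(j-1)/s), with s solved so the conditional
# mean matches the target.
.conditional_severity_probs <- function(cond_mean) {
  stopifnot(cond_mean > 1, cond_mean < 10)
  j <- 1:10
  mean_at <- function(s) {
    p <- exp(-(j - 1) / s)
    sum(j * p) / sum(p)
  }
  s <- uniroot(function(s) mean_at(s) - cond_mean, c(0.05, 200),
               tol = 1e-10)$root
  p <- exp(-(j - 1) / s)
  p / sum(p)
}

#' Threshold cutpoints calibrated to the MDASI reference marginals
#'
#' Builds, for each item, the 10 ordered cutpoints that map a standard-normal
#' latent severity to the observed 0-10 ordinal scale. The first cutpoint
#' reproduces the item's prevalence exactly (zero inflation lives entirely in
#' the first cutpoint); the remaining cutpoints spread the symptomatic mass
#' over scores 1-10 with a geometric decay whose rate is solved so the item
#' mean matches the reference mean.
#'
#' @param marginals Data frame with columns `item`, `prevalence`, `mean`
#'   (default [mdasi_reference_marginals()]).
#' @return Numeric matrix, one row per item, 10 strictly increasing cutpoints.
#' @export
mdasi_thresholds <- function(marginals = mdasi_reference_marginals()) {
  p <- nrow(marginals)
  tau <- matrix(NA_real_, p, 10,
                dimnames = list(marginals$item, paste0("tau_", 1:10)))
  for (i in seq_len(p)) {
    prev <- marginals$prevalence[i]
    cond_mean <- marginals$mean[i] / prev
    pj <- .conditional_severity_probs(cond_mean)
    cum <- (1 - prev) + prev * cumsum(c(0, pj[1:9]))
    tau[i, ] <- qnorm(cum)
  }
  tau
}

#' Generate a sparse random precision matrix with known partial correlations
#'
#' Draws a random graph on `p` nodes (each pair an edge independently with
#' probability `edge_prob`), assigns each edge a partial correlation with
#' magnitude uniform in `weight_range` and random sign, and builds the
#' corresponding precision (concentration) matrix. Positive definiteness is
#' enforced by diagonal augmentation followed by rescaling so the implied
#' correlation matrix has unit diagonal (which leaves partial correlations
#' unchanged).
#'
#' @param p Number of nodes (>= 2).
#' @param edge_prob Edge probability in \[0, 1\].
#' @param weight_range Length-2 interval inside (0, 1) for the magnitudes of
#'   nonzero partial correlations.
#' @param seed Integer RNG seed.
#' @param fixed_edges Optional data frame with columns `i`, `j`, `weight`
#'   forcing specific edges (row/column indices or labels) to given partial
#'   correlations regardless of the random graph.
#' @param labels Optional node names.
#' @return A `precision_matrix`: list with `K` (p x p), `labels`, and
#'   `pcor` (the implied partial correlation matrix).
#' @export
generate_precision_matrix <- function(p, edge_prob, weight_range, seed,
                                      fixed_edges = NULL, labels = NULL) {
  if (!is.finite(p) || p < 2) stop("p must be a finite count >= 2")
  if (!is.finite(edge_prob) || edge_prob < 0 || edge_prob > 1)
    stop("edge_prob must lie in [0, 1]")
  if (any(!is.finite(weight_range)) || length(weight_range) != 2 ||
      min(weight_range) <= 0 || max(weight_range) >= 1)
    stop("weight_range must be an interval inside (0, 1)")
  set.seed(as.integer(seed))
  if (is.null(labels)) {
    labels <- if (p == 13) mdasi_items() else paste0("node_", seq_len(p))
  }

  P <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (runif(1) < edge_prob) {
        w <- runif(1, weight_range[1], weight_range[2]) * sample(c(-1, 1), 1)
        P[i, j] <- P[j, i] <- w
      }
    }
  }
  if (!is.null(fixed_edges)) {
    for (r in seq_len(nrow(fixed_edges))) {
      i <- fixed_edges$i[r]; j <- fixed_edges$j[r]
      if (is.character(i)) i <- match(i, labels)
      if (is.character(j)) j <- match(j, labels)
      P[i, j] <- P[j, i] <- fixed_edges$weight[r]
    }
  }
  .precision_from_pcor(P, labels)
}

# Build a unit-diagonal-correlation precision matrix from a target partial
# correlation pattern; augment the diagonal until comfortably PD.
.precision_from_pcor <- function(P, labels, min_eig = 0.01) {
  p <- nrow(P)
  K <- -P
  diag(K) <- 1
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < min_eig) {
    K <- K + (min_eig - min(ev)) * diag(p)
  }
  .standardize_precision(K, labels)
}

# Rescale K so the implied correlation matrix solve(K) has unit diagonal;
# partial correlations are invariant under this diagonal scaling.
.standardize_precision <- function(K, labels = NULL) {
  sigma <- solve(K)
  d <- sqrt(diag(sigma))
  K <- diag(d) %*% K %*% diag(d)
  K <- (K + t(K)) / 2
  if (is.null(labels)) labels <- rownames(K)
  if (is.null(labels)) labels <- paste0("node_", seq_len(nrow(K)))
  dimnames(K) <- list(labels, labels)
  structure(list(K = K, labels = labels, pcor = precision_to_pcor(K)),
            class = "precision_matrix")
}

#' Convert a precision matrix to its partial correlation matrix
#'
#' @param K Precision matrix (or a `precision_matrix` object).
#' @return Symmetric matrix with zero diagonal: `-K_ij / sqrt(K_ii K_jj)`.
#' @export
precision_to_pcor <- function(K) {
  if (inherits(K, "precision_matrix")) K <- K$K
  d <- sqrt(diag(K))
  W <- -K / outer(d, d)
  diag(W) <- 0
  W
}

#' @export
print.precision_matrix <- function(x, ...) {
  p <- nrow(x$K)
  ne <- sum(abs(x$pcor[upper.tri(x$pcor)]) > 1e-10)
  cat(sprintf("precision_matrix: %d nodes, %d nonzero partial correlations\n",
              p, ne))
  invisible(x)
}

#' Construct a symptom dataset
#'
#' Container for a wide ordinal severity matrix plus covariates and optional
#' survivorship stratum. Rows with any missing value (in symptoms or
#' covariates) are removed at construction (listwise deletion), so all
#' downstream resampling shares a single effective n.
#'
#' @param values n x p integer matrix, entries in 0..10.
#' @param covariates Optional data frame / matrix of numeric covariates.
#' @param group Optional per-row stratum factor/character.
#' @param item_labels Column names for the symptoms.
#' @return Object of class `symptom_dataset`.
#' @export
symptom_dataset <- function(values, covariates = NULL, group = NULL,
                            item_labels = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(item_labels))
    item_labels <- paste0("sym_", sprintf("%02d", seq_len(ncol(values))))
  colnames(values) <- item_labels
  if (!is.null(covariates)) covariates <- as.data.frame(covariates)
  keep <- complete.cases(values)
  if (!is.null(covariates)) keep <- keep & complete.cases(covariates)
  if (!is.null(group)) keep <- keep & !is.na(group)
  values <- values[keep, , drop = FALSE]
  if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
  if (!is.null(group)) group <- as.character(group)[keep]
  if (nrow(values) < 1) stop("no complete rows")
  rng <- range(values)
  if (any(values != round(values)) || rng[1] < 0 || rng[2] > 10)
    stop("symptom scores must be integers in 0..10")
  structure(list(values = values, covariates = covariates, group = group,
                 item_labels = item_labels),
            class = "symptom_dataset")
}

#' @export
print.symptom_dataset <- function(x, ...) {
  cat(sprintf("symptom_dataset: %d participants x %d items", nrow(x$values),
              ncol(x$values)))
  if (!is.null(x$covariates))
    cat(sprintf(", %d covariates", ncol(x$covariates)))
  if (!is.null(x$group))
    cat(sprintf(", groups: %s", paste(names(table(x$group)), collapse = "/")))
  cat("\n")
  invisible(x)
}

#' @export
dim.symptom_dataset <- function(x) dim(x$values)

#' Subset a symptom dataset by row index
#'
#' @param data A `symptom_dataset`.
#' @param idx Row indices (duplicates allowed, e.g. bootstrap resamples).
#' @return A `symptom_dataset` with the selected rows.
#' @export
subset_rows <- function(data, idx) {
  stopifnot(inherits(data, "symptom_dataset"))
  structure(list(
    values = data$values[idx, , drop = FALSE],
    covariates = if (is.null(data$covariates)) NULL
                 else data$covariates[idx, , drop = FALSE],
    group = if (is.null(data$group)) NULL else data$group[idx],
    item_labels = data$item_labels
  ), class = "symptom_dataset")
}

#' Draw an ordinal dataset from a latent Gaussian graphical model
#'
#' Samples `n` latent vectors from the zero-mean unit-variance Gaussian with
#' precision matrix `K`, optionally shifts latent means by covariate effects,
#' and discretizes each coordinate through its item's ordered cutpoints into
#' scores 0..10.
#'
#' @param n Number of participants.
#' @param K A `precision_matrix` (or plain matrix).
#' @param thresholds p x 10 matrix of strictly increasing cutpoints per item
#'   (`+Inf`/`-Inf` allowed at the ends).
#' @param seed Integer RNG seed.
#' @param covariates Optional n x q numeric matrix/data frame.
#' @param covariate_effects Named numeric vector of latent-SD shifts per unit
#'   of each covariate (applied uniformly to all items).
#' @param group Optional stratum labels.
#' @return A `symptom_dataset`.
#' @export
generate_ordinal_dataset <- function(n, K, thresholds, seed,
                                     covariates = NULL,
                                     covariate_effects = NULL,
                                     group = NULL) {
  if (n < 1) stop("n must be >= 1")
  labels <- NULL
  if (inherits(K, "precision_matrix")) { labels <- K$labels; K <- K$K }
  p <- nrow(K)
  thresholds <- as.matrix(thresholds)
  if (nrow(thresholds) != p || ncol(thresholds) != 10)
    stop("thresholds must be a p x 10 matrix (10 cutpoints for 11 categories)")
  fin <- apply(thresholds, 1, function(r) {
    r <- r[is.finite(r)]
    length(r) < 2 || all(diff(r) > 0)
  })
  if (!all(fin)) stop("thresholds must be strictly increasing per item")
  set.seed(as.integer(seed))
  sigma <- stats::cov2cor(solve(K))
  L <- chol(sigma)
  Z <- matrix(rnorm(n * p), n, p) %*% L
  if (!is.null(covariates) && !is.null(covariate_effects)) {
    X <- as.matrix(as.data.frame(covariates)[, names(covariate_effects),
                                             drop = FALSE])
    shift <- as.numeric(X %*% covariate_effects)
    Z <- Z + shift
  }
  scores <- matrix(0L, n, p)
  for (j in seq_len(p)) {
    scores[, j] <- as.integer(findInterval(Z[, j], thresholds[j, ]))
  }
  if (is.null(labels)) labels <- rownames(thresholds)
  symptom_dataset(scores, covariates = covariates, group = group,
                  item_labels = labels)
}

#' Specification of a synthetic study
#'
#' Bundles every knob of the synthetic-data generator: group sizes, the sparse
#' latent network, item cutpoints, covariate effects, and per-group density
#' multipliers. Defaults emulate a community cancer-survivor cohort: 1065
#' participants split over three survivorship strata, 13 items calibrated to
#' the reference marginals, two strong anchored edges (distress--sadness and
#' nausea--vomiting), and a denser network in the "<5y" stratum.
#'
#' @param n_per_group Named counts for the `<5y`, `5-10y`, `>10y` strata.
#' @param p Number of symptom nodes.
#' @param edge_prob Sparsity of the random true graph.
#' @param weight_range Magnitude interval for nonzero partial correlations.
#' @param thresholds p x 10 cutpoint matrix (default MDASI calibration).
#' @param covariate_effects Named latent shifts per covariate unit.
#' @param density_scale Per-group multiplier on off-diagonal partial
#'   correlations (all > 0).
#' @param fixed_edges Data frame `i, j, weight` of anchored edges.
#' @param seed Integer master seed.
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(n_per_group = c("<5y" = 530, "5-10y" = 320,
                                           ">10y" = 215),
                           p = 13,
                           edge_prob = 0.2,
                           weight_range = c(0.1, 0.4),
                           thresholds = NULL,
                           covariate_effects = c(chemotherapy = 0.25,
                                                 cardiovascular = 0.20,
                                                 duration_years = -0.02),
                           density_scale = c(1.5, 1.0, 1.0),
                           fixed_edges = NULL,
                           seed = 1) {
  # tolerate list-valued fields from YAML/JSON configs
  n_per_group <- unlist(n_per_group)
  if (is.null(names(n_per_group)) && length(n_per_group) <= 3)
    names(n_per_group) <- c("<5y", "5-10y", ">10y")[seq_along(n_per_group)]
  weight_range <- unname(unlist(weight_range))
  covariate_effects <- unlist(covariate_effects)
  density_scale <- unname(unlist(density_scale))
  if (!is.null(thresholds)) thresholds <- as.matrix(thresholds)
  if (is.null(thresholds)) {
    thresholds <- if (p == 13) mdasi_thresholds()
                  else matrix(rep(qnorm(seq(0.5, 0.99, length.out = 10)), each = p), p, 10)
  }
  if (is.null(fixed_edges) && p == 13) {
    fixed_edges <- data.frame(
      i = c("distress", "nausea"), j = c("sadness", "vomiting"),
      weight = c(0.35, 0.35), stringsAsFactors = FALSE)
  }
  spec <- structure(list(
    n_per_group = n_per_group, p = p, edge_prob = edge_prob,
    weight_range = weight_range, thresholds = thresholds,
    covariate_effects = covariate_effects, density_scale = density_scale,
    fixed_edges = fixed_edges, seed = as.integer(seed)),
    class = "generator_spec")
  validate_generator_spec(spec)
  spec
}

#' @rdname generator_spec
#' @param spec A `generator_spec`.
#' @export
validate_generator_spec <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (any(spec$density_scale <= 0)) stop("density_scale must be > 0")
  if (any(spec$n_per_group < spec$p + 1))
    stop("each group needs n >= p + 1 for estimability")
  if (length(spec$density_scale) != length(spec$n_per_group))
    stop("density_scale must have one entry per group")
  fin <- apply(as.matrix(spec$thresholds), 1, function(r) {
    r <- r[is.finite(r)]
    length(r) < 2 || all(diff(r) > 0)
  })
  if (!all(fin)) stop("thresholds must be strictly increasing per item")
  invisible(spec)
}

# Apply a density multiplier to the off-diagonal partial correlations of a
# base precision matrix; re-project to positive definite by eigenvalue
# clipping at 1e-3 then rescale to a unit-diagonal implied correlation.
.scale_precision_density <- function(K_obj, scale) {
  P <- K_obj$pcor * scale
  diag(P) <- 0
  if (max(abs(P)) >= 1)
    stop("density_scale pushes a partial correlation to |r| >= 1; ",
         "max scaled magnitude = ", round(max(abs(P)), 3))
  K <- -P
  diag(K) <- 1
  e <- eigen(K, symmetric = TRUE)
  vals <- pmax(e$values, 1e-3)
  K <- e$vectors %*% diag(vals) %*% t(e$vectors)
  K <- (K + t(K)) / 2
  .standardize_precision(K, K_obj$labels)
}

#' Generate a full synthetic study with subgroups and covariates
#'
#' Draws one base sparse network, applies each group's density multiplier,
#' samples ordinal data per group, and attaches covariates (binary
#' chemotherapy and cardiovascular-disease indicators, continuous survivorship
#' duration drawn uniformly within each stratum's year range) whose effects
#' shift the latent severity means. Ground-truth precision matrices per group
#' are attached for recovery testing.
#'
#' @param spec A [generator_spec()].
#' @return A `symptom_dataset` with attribute `truth`: list with
#'   `precision_by_group`, `base_precision`, `thresholds`,
#'   `covariate_effects`, `seed`.
#' @export
generate_study <- function(spec = generator_spec()) {
  validate_generator_spec(spec)
  K0 <- generate_precision_matrix(spec$p, spec$edge_prob, spec$weight_range,
                                  seed = spec$seed,
                                  fixed_edges = spec$fixed_edges)
  groups <- names(spec$n_per_group)
  if (is.null(groups)) groups <- paste0("group_", seq_along(spec$n_per_group))
  dur_range <- list("<5y" = c(0.5, 5), "5-10y" = c(5, 10), ">10y" = c(10, 26))
  parts <- list()
  truth_K <- list()
  for (g in seq_along(groups)) {
    Kg <- .scale_precision_density(K0, spec$density_scale[g])
    truth_K[[groups[g]]] <- Kg
    n_g <- spec$n_per_group[g]
    gseed <- .substream_seed(spec$seed, 1000L + g)
    set.seed(gseed)
    rng <- dur_range[[groups[g]]]
    if (is.null(rng)) rng <- c(0.5, 26)
    cov_g <- data.frame(
      chemotherapy = rbinom(n_g, 1, 0.5117),
      cardiovascular = rbinom(n_g, 1, 0.1418),
      duration_years = runif(n_g, rng[1], rng[2])
    )
    ds <- generate_ordinal_dataset(
      n_g, Kg, spec$thresholds, seed = .substream_seed(spec$seed, 2000L + g),
      covariates = cov_g, covariate_effects = spec$covariate_effects,
      group = rep(groups[g], n_g))
    parts[[g]] <- ds
  }
  values <- do.call(rbind, lapply(parts, `[[`, "values"))
  covs <- do.call(rbind, lapply(parts, `[[`, "covariates"))
  grp <- unlist(lapply(parts, `[[`, "group"))
  out <- symptom_dataset(values, covariates = covs, group = grp,
                         item_labels = parts[[1]]$item_labels)
  attr(out, "truth") <- list(precision_by_group = truth_K,
                             base_precision = K0,
                             thresholds = spec$thresholds,
                             covariate_effects = spec$covariate_effects,
                             seed = spec$seed)
  out
}

#' Write / read a symptom dataset as wide CSV
#'
#' Columns: `id`, `group` (if present), `sym_01..sym_p`, then covariates
#' prefixed `cov_`.
#'
#' @param data A `symptom_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_symptom_csv <- function(data, path) {
  stopifnot(inherits(data, "symptom_dataset"))
  df <- data.frame(id = seq_len(nrow(data$values)))
  if (!is.null(data$group)) df$group <- data$group
  sym <- as.data.frame(data$values)
  names(sym) <- paste0("sym_", sprintf("%02d", seq_len(ncol(sym))))
  df <- cbind(df, sym)
  if (!is.null(data$covariates)) {
    cv <- data$covariates
    names(cv) <- paste0("cov_", names(cv))
    df <- cbind(df, cv)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_symptom_csv
#' @param item_labels Optional symptom labels to restore on read.
#' @export
read_symptom_csv <- function(path, item_labels = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  sym_cols <- grep("^sym_", names(df), value = TRUE)
  cov_cols <- grep("^cov_", names(df), value = TRUE)
  values <- as.matrix(df[, sym_cols, drop = FALSE])
  if (is.null(item_labels)) {
    item_labels <- if (length(sym_cols) == 13) mdasi_items() else sym_cols
  }
  covs <- if (length(cov_cols)) {
    cv <- df[, cov_cols, drop = FALSE]
    names(cv) <- sub("^cov_", "", names(cv))
    cv
  } else NULL
  grp <- if ("group" %in% names(df)) df$group else NULL
  symptom_dataset(values, covariates = covs, group = grp,
                  item_labels = item_labels)
}

#' Write generator ground truth to JSON
#'
#' @param data A dataset from [generate_study()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(data, path) {
  truth <- attr(data, "truth")
  if (is.null(truth)) stop("dataset carries no ground truth")
  obj <- list(
    seed = truth$seed,
    thresholds = unname(as.matrix(truth$thresholds)),
    covariate_effects = as.list(truth$covariate_effects),
    precision_by_group = lapply(truth$precision_by_group,
                                function(k) unname(k$K))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
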