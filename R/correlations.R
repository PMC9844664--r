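#' Correlation matrix container
#'
#' @param R Symmetric correlation matrix with unit diagonal.
#' @param method One of `"spearman"`, `"polychoric"`, `"pearson"`.
#' @param n_effective Sample size behind the estimate.
#' @param psd_repaired Whether a nearest-PSD repair changed the matrix.
#' @param flags Optional character vector of per-estimate warnings.
#' @return Object of class `cor_matrix`.
#' @export
cor_matrix <- function(R, method, n_effective, psd_repaired = FALSE,
                       flags = character()) {
  R <- as.matrix(R)
  stopifnot(nrow(R) == ncol(R))
  structure(list(R = R, method = method, n_effective = n_effective,
                 psd_repaired = psd_repaired, flags = flags),
            class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, ...) {
  cat(sprintf("cor_matrix (%s): %d x %d, n = %d%s\n", x$method, nrow(x$R),
              ncol(x$R), x$n_effective,
              if (x$psd_repaired) ", PSD-repaired" else ""))
  invisible(x)
}

#' Spearman rank correlation matrix
#'
#' Pairwise Spearman correlations (average ranks for ties), i.e. the Pearson
#' correlation of the rank-transformed columns. A zero-variance column gets 0
#' correlation with everything (flagged) rather than `NaN`.
#'
#' @param data A `symptom_dataset` or numeric matrix (n >= 3 rows).
#' @return A [cor_matrix()] with `method = "spearman"`.
#' @export
spearman_matrix <- function(data) {
  X <- .as_values_matrix(data)
  if (nrow(X) < 3) stop("need n >= 3")
  flags <- character()
  zv <- apply(X, 2, function(v) var(v) == 0)
  R <- suppressWarnings(cor(X, method = "spearman"))
  if (any(zv)) {
    R[zv, ] <- 0
    R[, zv] <- 0
    flags <- paste0("zero_variance:", colnames(X)[zv])
  }
  diag(R) <- 1
  R[is.na(R)] <- 0
  cor_matrix(R, "spearman", nrow(X), psd_repaired = FALSE, flags = flags)
}

# Interior thresholds of one ordinal margin: inverse-normal of the cumulative
# category proportions (observed categories only, so empty categories merge).
.margin_thresholds <- function(counts) {
  pr <- counts / sum(counts)
  cum <- cumsum(pr)
  qnorm(cum[-length(cum)])
}

#' Polychoric correlation of a two-way ordinal table
#'
#' Two-stage maximum likelihood: marginal thresholds are fixed at the
#' inverse-normal cumulative proportions, then the latent bivariate-normal
#' correlation maximizing the cell-probability likelihood is found by bounded
#' 1-D search over (-0.999, 0.999).
#'
#' @param table Two-way contingency matrix of counts, or `NULL` if `x`, `y`
#'   given.
#' @param x,y Ordinal vectors (used when `table` is `NULL`).
#' @return The ML correlation, with attribute `boundary = TRUE` when the
#'   maximizer is clamped at +/-0.999.
#' @export
polychoric_rho <- function(table = NULL, x = NULL, y = NULL) {
  if (is.null(table)) {
    stopifnot(!is.null(x), !is.null(y))
    table <- base::table(x, y)
  }
  tab <- as.matrix(table)
  rows <- rowSums(tab) > 0
  cols <- colSums(tab) > 0
  tab <- tab[rows, cols, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("polychoric correlation undefined: a margin has a single observed category")
  tau_r <- .margin_thresholds(rowSums(tab))
  tau_c <- .margin_thresholds(colSums(tab))
  nll <- function(rho) -polychoric_loglik_cpp(tab, tau_r, tau_c, rho)
  opt <- optimize(nll, interval = c(-0.999, 0.999), tol = 1e-6)
  rho <- opt$minimum
  boundary <- FALSE
  # check the boundary explicitly: optimize() never returns the endpoints
  for (b in c(-0.999, 0.999)) {
    if (nll(b) < opt$objective) { rho <- b; boundary <- TRUE }
  }
  if (abs(rho) > 0.999 - 1e-4) {
    rho <- sign(rho) * 0.999
    boundary <- TRUE
  }
  structure(rho, boundary = boundary)
}

#' Nearest-PSD repair by eigenvalue clipping
#'
#' Clips eigenvalues below `floor`, then rescales to unit diagonal.
#'
#' @param R Symmetric matrix.
#' @param floor Eigenvalue floor (default 1e-6).
#' @return List with `R` (repaired) and `changed` flag.
#' @export
nearest_psd <- function(R, floor = 1e-6) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  changed <- min(e$values) < floor
  if (changed) {
    vals <- pmax(e$values, floor)
    R2 <- e$vectors %*% diag(vals) %*% t(e$vectors)
    d <- sqrt(diag(R2))
    R2 <- R2 / outer(d, d)
    R2 <- (R2 + t(R2)) / 2
    dimnames(R2) <- dimnames(R)
    list(R = R2, changed = TRUE)
  } else {
    list(R = R, changed = FALSE)
  }
}

#' Polychoric correlation matrix
#'
#' Pairwise [polychoric_rho()] over all item pairs, followed by nearest-PSD
#' repair (eigenvalue clipping at 1e-6 and rescaling to unit diagonal).
#'
#' @param data A `symptom_dataset` or integer matrix (n >= 3 rows).
#' @return A [cor_matrix()] with `method = "polychoric"`; `psd_repaired` is
#'   `TRUE` iff clipping changed anything.
#' @export
polychoric_matrix <- function(data) {
  X <- .as_values_matrix(data)
  if (nrow(X) < 3) stop("need n >= 3")
  p <- ncol(X)
  labels <- colnames(X)
  R <- diag(p)
  flags <- character()
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      rho <- tryCatch(polychoric_rho(x = X[, i], y = X[, j]),
                      error = function(e) {
                        stop(sprintf("polychoric failure for pair (%s, %s): %s",
                                     labels[i], labels[j], conditionMessage(e)),
                             call. = FALSE)
                      })
      if (isTRUE(attr(rho, "boundary")))
        flags <- c(flags, sprintf("boundary:%s-%s", labels[i], labels[j]))
      R[i, j] <- R[j, i] <- as.numeric(rho)
    }
  }
  dimnames(R) <- list(labels, labels)
  rep <- nearest_psd(R, floor = 1e-6)
  cor_matrix(rep$R, "polychoric", nrow(X), psd_repaired = rep$changed,
             flags = flags)
}

#' Write a correlation matrix to CSV with a JSON sidecar
#'
#' @param x A `cor_matrix`.
#' @param path CSV path; the sidecar is written next to it as `.json`.
#' @return `path`, invisibly.
#' @export
write_cor_csv <- function(x, path) {
  stopifnot(inherits(x, "cor_matrix"))
  write.csv(as.data.frame(x$R), path, row.names = TRUE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(list(method = x$method, n_effective = x$n_effective,
                            psd_repaired = x$psd_repaired, flags = x$flags),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
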