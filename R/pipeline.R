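#' Linear regression of overall symptom severity on candidate covariates
#'
#' The outcome is the participant's total severity (row sum over the 13
#' items, range 0-130). Outcome and predictors are standardized, so the
#' coefficients are standardized betas. Binary candidates whose positive
#' class holds fewer than `min_positive` participants are screened out before
#' fitting (to protect power); covariates with `p < alpha` form the selected
#' set passed on to network estimation.
#'
#' @param data A `symptom_dataset` with covariates.
#' @param candidate_covariates Covariate names to consider (default: all).
#' @param alpha Two-sided selection level (default 0.05).
#' @param min_positive Minimum positive-class count for binary candidates
#'   (default 100).
#' @return Object of class `regression_table`: `table` (covariate, beta, p),
#'   `selected`, `screened_out`, `r2_adj`, `f_statistic`, `n`.
#' @export
overall_severity_regression <- function(data,
                                        candidate_covariates = NULL,
                                        alpha = 0.05, min_positive = 100) {
  stopifnot(inherits(data, "symptom_dataset"))
  if (is.null(data$covariates)) stop("dataset has no covariates")
  if (is.null(candidate_covariates))
    candidate_covariates <- names(data$covariates)
  C <- data$covariates[, candidate_covariates, drop = FALSE]
  screened_out <- character()
  for (v in candidate_covariates) {
    x <- C[[v]]
    if (all(x %in% c(0, 1)) && sum(x == 1) < min_positive)
      screened_out <- c(screened_out, v)
  }
  keep <- setdiff(candidate_covariates, screened_out)
  if (length(keep) == 0)
    stop("all candidate covariates were screened out (positive class < ",
         min_positive, ")")
  y <- rowSums(data$values)
  z <- function(v) {
    s <- sd(v)
    if (s == 0) stop("zero-variance column in regression: constant input")
    (v - mean(v)) / s
  }
  X <- vapply(keep, function(v) z(C[[v]]), numeric(nrow(C)))
  fit <- lm(z(y) ~ X)
  cf <- coef(fit)
  if (anyNA(cf)) {
    bad <- keep[is.na(cf[-1])]
    stop("rank-deficient design; aliased columns: ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  tab <- data.frame(covariate = keep,
                    beta = unname(cf[-1]),
                    p = unname(sm$coefficients[-1, 4]),
                    stringsAsFactors = FALSE)
  selected <- tab$covariate[tab$p < alpha]
  structure(list(table = tab, selected = selected,
                 screened_out = screened_out,
                 r2_adj = sm$adj.r.squared,
                 f_statistic = unname(sm$fstatistic[1]),
                 n = nrow(C), alpha = alpha),
            class = "regression_table")
}

#' @export
print.regression_table <- function(x, ...) {
  cat(sprintf("severity regression (n = %d): R2_adj = %.3f, F = %.3f\n",
              x$n, x$r2_adj, x$f_statistic))
  print(x$table, row.names = FALSE)
  if (length(x$selected))
    cat("selected (p <", x$alpha, "):",
        paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Default pipeline configuration
#'
#' @param generator Arguments for [generator_spec()] (used when no data file
#'   is given).
#' @param data_csv Optional path to an existing wide-format dataset.
#' @param candidate_covariates Covariate names for the severity regression.
#' @param settings Arguments for [estimation_settings()].
#' @param B Bootstrap replicates.
#' @param n_perm Permutations for the subgroup density test.
#' @param min_positive Screen for binary covariates (see
#'   [overall_severity_regression()]).
#' @param stability_grid Drop-proportion grid for the case-dropping
#'   stability stage (default 0.10-0.75 by 0.05).
#' @param seed Master seed.
#' @param out_dir Output directory (artifacts + summary JSON).
#' @return A named list usable as `config` in [run_full_pipeline()].
#' @export
pipeline_config <- function(generator = list(), data_csv = NULL,
                            candidate_covariates = NULL, settings = list(),
                            B = 1000, n_perm = 1000, min_positive = 100,
                            stability_grid = seq(0.10, 0.75, by = 0.05),
                            seed = 1, out_dir = tempfile("symnet_run_")) {
  list(generator = generator, data_csv = data_csv,
       candidate_covariates = candidate_covariates, settings = settings,
       B = B, n_perm = n_perm, min_positive = min_positive,
       stability_grid = stability_grid, seed = seed, out_dir = out_dir)
}

#' Run the full symptom-network analysis pipeline
#'
#' Stages: (1) load or generate data; (2) severity regression and covariate
#' selection; (3) full-sample network, centrality, density, predictability;
#' (4) edge-weight bootstrap, case-dropping stability, difference tests;
#' (5) per-stratum networks and pairwise density permutation tests (skipped
#' when the data carry no groups). All artifacts are written under
#' `config$out_dir` along with a single `summary.json`; every number is
#' reproducible from the recorded seed and settings.
#'
#' @param config A [pipeline_config()] list, or the path of a YAML/JSON file
#'   with the same fields.
#' @return Object of class `report_bundle` (a list of all stage results),
#'   invisibly.
#' @export
run_full_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- .read_config(config)
  defaults <- pipeline_config()
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message(sprintf("[symnet] stage: %s", name))
    t0 <- proc.time()[3]
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[symnet]   done in %.1fs", proc.time()[3] - t0))
    r
  }

  data <- stage("data", {
    if (!is.null(config$data_csv)) {
      read_symptom_csv(config$data_csv)
    } else {
      gen_args <- config$generator
      if (is.null(gen_args$seed)) gen_args$seed <- config$seed
      spec <- do.call(generator_spec, gen_args)
      d <- generate_study(spec)
      write_symptom_csv(d, file.path(out, "data.csv"))
      write_truth_json(d, file.path(out, "truth.json"))
      d
    }
  })

  reg <- NULL
  selected <- character()
  if (!is.null(data$covariates)) {
    reg <- stage("severity_regression", {
      r <- overall_severity_regression(
        data, config$candidate_covariates,
        min_positive = config$min_positive)
      write.csv(r$table, file.path(out, "regression.csv"), row.names = FALSE)
      r
    })
    selected <- reg$selected
  }

  settings <- do.call(estimation_settings, config$settings)
  net <- stage("network", {
    nw <- estimate_network(data, settings, covariates = selected)
    write_network(nw, file.path(out, "network"))
    nw
  })

  cent <- stage("centrality", {
    ct <- centrality_table(net)
    write.csv(ct, file.path(out, "centrality.csv"), row.names = FALSE)
    ct
  })
  dens <- stage("density", network_density(data, basis = "spearman"))
  pred <- stage("predictability", {
    pt <- node_predictability(data, net)
    write.csv(pt, file.path(out, "predictability.csv"), row.names = FALSE)
    pt
  })

  boot <- stage("bootstrap", {
    bb <- bootstrap_edge_ci(data, settings, covariates = selected,
                            B = config$B, seed = config$seed)
    write.csv(summary(bb), file.path(out, "bootstrap_edges.csv"),
              row.names = FALSE)
    bb
  })
  stab <- stage("stability", {
    grid <- unname(unlist(config$stability_grid))
    res <- list(
      strength = case_dropping_stability(
        data, settings, "strength", proportions = grid, B = config$B,
        seed = config$seed, covariates = selected),
      expected_influence = case_dropping_stability(
        data, settings, "expected_influence", proportions = grid,
        B = config$B, seed = config$seed, covariates = selected))
    cs_df <- data.frame(statistic = names(res),
                        cs = vapply(res, `[[`, numeric(1), "cs_coefficient"))
    write.csv(cs_df, file.path(out, "stability_cs.csv"), row.names = FALSE)
    res
  })
  difftests <- stage("difference_tests", {
    dt <- list(edges = bootstrap_difference_test(boot, "edges"),
               strength = bootstrap_difference_test(boot, "strength"))
    write.csv(as.data.frame(dt$edges$significant),
              file.path(out, "difftest_edges.csv"), row.names = TRUE)
    dt
  })

  subgroup <- NULL
  if (!is.null(data$group) && length(unique(data$group)) >= 2) {
    subgroup <- stage("subgroups", {
      # canonical stratum order first, then locale-independent radix order
      canonical <- c("<5y", "5-10y", ">10y")
      grps <- unique(data$group)
      grps <- c(intersect(canonical, grps),
                sort(setdiff(grps, canonical), method = "radix"))
      nets <- lapply(grps, function(g) {
        idx <- which(data$group == g)
        estimate_network(subset_rows(data, idx), settings,
                         covariates = selected)
      })
      names(nets) <- grps
      comps <- list()
      if (length(grps) >= 2) {
        pairs <- utils::combn(grps, 2, simplify = FALSE)
        comps <- lapply(pairs, function(pr)
          density_comparison_test(data, pr, n_perm = config$n_perm,
                                  seed = config$seed))
        names(comps) <- vapply(pairs, paste, character(1), collapse = "_vs_")
      }
      list(networks = nets, density_tests = comps)
    })
  } else {
    message("[symnet] stage: subgroups skipped (no group labels)")
  }

  provenance <- list(
    seed = config$seed, B = config$B, n_perm = config$n_perm,
    settings = unclass(settings), selected_covariates = selected,
    package_version = as.character(utils::packageVersion("symnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))

  summary_json <- list(
    n = nrow(data$values), p = ncol(data$values),
    density_spearman = dens$value,
    edge_count = sum(abs(net$W[upper.tri(net$W)]) > 1e-10),
    lambda_selected = net$lambda_selected,
    cs_strength = stab$strength$cs_coefficient,
    cs_expected_influence = stab$expected_influence$cs_coefficient,
    predictability_range = range(pred$r_squared),
    top_strength = cent$node[order(-cent$strength)][1:3],
    regression = if (!is.null(reg)) reg$table else NULL,
    subgroup_density_p = if (!is.null(subgroup))
      lapply(subgroup$density_tests, `[[`, "p_value") else NULL,
    subgroup_skipped = is.null(subgroup),
    provenance = provenance)
  jsonlite::write_json(summary_json, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  bundle <- structure(list(
    data = data, regression = reg, network = net, centrality = cent,
    density = dens, predictability = pred, bootstrap = boot,
    stability = stab, difference_tests = difftests, subgroup = subgroup,
    provenance = provenance, out_dir = out),
    class = "report_bundle")
  invisible(bundle)
}

.read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle\n")
  cat(sprintf("  n = %d, density = %.2f, CS(strength) = %.2f\n",
              nrow(x$data$values), x$density$value,
              x$stability$strength$cs_coefficient))
  cat("  artifacts in:", x$out_dir, "\n")
  invisible(x)
}
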