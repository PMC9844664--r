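# Small fixtures shared across resampling tests; spearman input keeps the
# per-replicate refits cheap.
fast_settings <- estimation_settings("spearman", n_lambda = 40)

make_fixture <- function(n, seed, edge_prob = 0.3,
                         weight_range = c(0.25, 0.4), p = 8) {
  K <- generate_precision_matrix(p, edge_prob, weight_range, seed = seed)
  thr <- matrix(qnorm(seq(0.35, 0.95, length.out = 10)), p, 10, byrow = TRUE)
  list(K = K, data = generate_ordinal_dataset(n, K, thr, seed = seed + 1))
}

test_that("bootstrap with B = 1 degenerates to the single replicate", {
  fx <- make_fixture(200, seed = 71)
  expect_warning(bb <- bootstrap_edge_ci(fx$data, fast_settings, B = 1,
                                         seed = 5),
                 "B < 100")
  expect_equal(bb$ci_low, bb$replicate_weights[1, ], ignore_attr = TRUE)
  expect_equal(bb$ci_high, bb$replicate_weights[1, ], ignore_attr = TRUE)
})

test_that("bootstrap CIs are percentile-consistent and seed-reproducible", {
  fx <- make_fixture(250, seed = 72)
  b1 <- bootstrap_edge_ci(fx$data, fast_settings, B = 120, seed = 9)
  b2 <- bootstrap_edge_ci(fx$data, fast_settings, B = 120, seed = 9)
  expect_identical(b1$replicate_weights, b2$replicate_weights)
  med <- apply(b1$replicate_weights, 2, median, na.rm = TRUE)
  expect_true(all(b1$ci_low <= med + 1e-12))
  expect_true(all(med <= b1$ci_high + 1e-12))
  # growing B keeps earlier replicates identical (counter substreams)
  b3 <- bootstrap_edge_ci(fx$data, fast_settings, B = 130, seed = 9)
  expect_identical(b3$replicate_weights[1:120, ], b1$replicate_weights)
})

test_that("a strong edge's bootstrap CI excludes zero", {
  P <- matrix(0, 6, 6)
  P[1, 2] <- P[2, 1] <- 0.4
  K <- symnet:::.precision_from_pcor(P, paste0("n", 1:6))
  thr <- matrix(qnorm(seq(0.35, 0.95, length.out = 10)), 6, 10, byrow = TRUE)
  d <- generate_ordinal_dataset(1000, K, thr, seed = 73)
  bb <- bootstrap_edge_ci(d, fast_settings, B = 150, seed = 10)
  e12 <- which(bb$edges$i == 1 & bb$edges$j == 2)
  expect_gt(bb$ci_low[e12], 0)
})

test_that("case-dropping stability: CS definition, degenerate statistic flagged", {
  fx <- make_fixture(600, seed = 74, edge_prob = 0.4,
                     weight_range = c(0.3, 0.45))
  st <- suppressWarnings(
    case_dropping_stability(fx$data, fast_settings, "strength",
                            proportions = c(0.1, 0.3, 0.5),
                            B = 60, seed = 11))
  expect_warning(case_dropping_stability(fx$data, fast_settings, "strength",
                                         proportions = c(0.1), B = 20,
                                         seed = 1), "B < 100")
  expect_true(st$cs_coefficient %in% c(0, st$drop_proportions))
  ok <- !is.na(st$correlations)
  expect_true(all(st$correlations[ok] >= -1 & st$correlations[ok] <= 1))
  # reproducibility
  st2 <- suppressWarnings(
    case_dropping_stability(fx$data, fast_settings, "strength",
                            proportions = c(0.1, 0.3, 0.5),
                            B = 60, seed = 11))
  expect_identical(st$correlations, st2$correlations)
})

test_that("subsamples below p + 1 rows are skipped and flagged", {
  fx <- make_fixture(40, seed = 75, p = 8)
  st <- suppressWarnings(case_dropping_stability(
    fx$data, fast_settings, "strength", proportions = c(0.1, 0.8),
    B = 10, seed = 2))
  expect_true(st$skipped[2])
  expect_true(all(is.na(st$correlations[2, ])))
})

test_that("difference tests: identical edges never differ; level monotone", {
  fx <- make_fixture(200, seed = 76)
  bb <- bootstrap_edge_ci(fx$data, fast_settings, B = 120, seed = 12)
  # duplicate an edge column: its self-difference is exactly zero
  bb2 <- bb
  bb2$replicate_weights <- cbind(bb$replicate_weights,
                                 bb$replicate_weights[, 1])
  bb2$edges <- rbind(bb$edges, bb$edges[1, ])
  dt <- bootstrap_difference_test(bb2, "edges", alpha = 0.05)
  m <- ncol(bb2$replicate_weights)
  expect_false(dt$significant[1, m])

  dt_all <- bootstrap_difference_test(bb, "edges", alpha = 1)
  sig_all <- dt_all$significant[upper.tri(dt_all$significant)]
  dt_none <- bootstrap_difference_test(bb, "edges", alpha = 1e-9)
  sig_none <- dt_none$significant[upper.tri(dt_none$significant)]
  expect_true(all(sig_none <= sig_all))
  expect_equal(sum(sig_none), 0)
  expect_false(any(diag(dt_all$significant)))
  expect_equal(dt_all$significant, t(dt_all$significant))
})

test_that("a true 0.5-vs-0 weight contrast is detected", {
  P <- matrix(0, 6, 6)
  P[1, 2] <- P[2, 1] <- 0.5
  K <- symnet:::.precision_from_pcor(P, paste0("n", 1:6))
  thr <- matrix(qnorm(seq(0.35, 0.95, length.out = 10)), 6, 10, byrow = TRUE)
  d <- generate_ordinal_dataset(1000, K, thr, seed = 77)
  bb <- bootstrap_edge_ci(d, fast_settings, B = 150, seed = 13)
  dt <- bootstrap_difference_test(bb, "edges")
  e_strong <- which(bb$edges$i == 1 & bb$edges$j == 2)
  e_null <- which(bb$edges$i == 3 & bb$edges$j == 4)
  expect_true(dt$significant[e_strong, e_null])
})

test_that("density permutation test: identical groups give p = 1, contrast gives small p", {
  fx <- make_fixture(160, seed = 78, p = 6)
  X <- fx$data$values
  d2 <- symptom_dataset(rbind(X, X), group = rep(c("a", "b"), each = nrow(X)))
  pr <- density_comparison_test(d2, c("a", "b"), n_perm = 100, seed = 3)
  expect_equal(pr$observed_diff, 0)
  expect_equal(pr$p_value, 1)

  dd <- two_group_data(400, 1.6, 1.0, seed = 79, edge_prob = 0.3,
                       weight_range = c(0.2, 0.35))
  pr2 <- density_comparison_test(dd, c("<5y", "5-10y"), n_perm = 200,
                                 seed = 4)
  expect_lt(pr2$p_value, 0.05)
  # reproducible under the same seed
  pr3 <- density_comparison_test(dd, c("<5y", "5-10y"), n_perm = 200,
                                 seed = 4)
  expect_identical(pr2$null_draws, pr3$null_draws)
})

test_that("permutation test validates group sizes", {
  fx <- make_fixture(30, seed = 80, p = 8)
  d <- symptom_dataset(fx$data$values,
                       group = c(rep("a", 5), rep("b", 25)))
  expect_error(density_comparison_test(d, c("a", "b"), n_perm = 100, seed = 1),
               "p \\+ 1")
})
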