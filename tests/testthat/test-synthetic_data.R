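test_that("generated precision matrices are symmetric PD with the requested support", {
  K0 <- generate_precision_matrix(2, 0, c(0.2, 0.4), seed = 1)
  expect_equal(K0$K, diag(2), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(max(abs(K0$pcor)), 0)

  K3 <- generate_precision_matrix(3, 1, c(0.3, 0.3), seed = 7)
  pc <- -K3$K / sqrt(outer(diag(K3$K), diag(K3$K)))
  diag(pc) <- 0
  off <- pc[upper.tri(pc)]
  # all three partial correlations at magnitude 0.3 (up to sign) unless the
  # random sign pattern forced diagonal augmentation, which shrinks them all
  expect_true(all(abs(off) > 0))
  expect_lt(diff(range(abs(off))), 1e-8)
  expect_lte(max(abs(off)), 0.3 + 1e-8)

  counts <- integer(50)
  for (s in 1:50) {
    K <- generate_precision_matrix(13, 0.25, c(0.1, 0.4), seed = s)
    ev <- eigen(K$K, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    expect_equal(K$K, t(K$K), tolerance = 1e-12)
    counts[s] <- sum(abs(K$pcor[upper.tri(K$pcor)]) > 1e-10)
  }
  expect_equal(mean(counts), 0.25 * 78, tolerance = 0.15)
})

test_that("precision generator rejects invalid inputs", {
  expect_error(generate_precision_matrix(1, 0.5, c(0.1, 0.4), 1))
  expect_error(generate_precision_matrix(5, 1.5, c(0.1, 0.4), 1))
  expect_error(generate_precision_matrix(5, 0.5, c(0, 0.4), 1))
  expect_error(generate_precision_matrix(5, 0.5, c(0.1, 1), 1))
})

test_that("ordinal discretization respects thresholds and marginal targets", {
  K <- generate_precision_matrix(3, 0.5, c(0.2, 0.3), seed = 2)
  # degenerate: first cutpoint at +Inf gives an all-zero column
  thr <- matrix(qnorm(seq(0.5, 0.95, length.out = 10)), 3, 10, byrow = TRUE)
  thr[2, ] <- Inf
  d <- generate_ordinal_dataset(500, K, thr, seed = 3)
  expect_true(all(d$values[, 2] == 0))
  expect_true(all(d$values >= 0 & d$values <= 10))

  # prevalence of the fatigue item matches its calibration target
  thr13 <- mdasi_thresholds()
  K13 <- generate_precision_matrix(13, 0.2, c(0.1, 0.4), seed = 4)
  d13 <- generate_ordinal_dataset(10000, K13, thr13, seed = 5)
  prev_fatigue <- mean(d13$values[, "fatigue"] >= 1)
  expect_equal(prev_fatigue, 0.7268, tolerance = 0.015 / 0.7268)
  # item means land near their calibration targets too
  ref <- mdasi_reference_marginals()
  expect_equal(unname(colMeans(d13$values)), ref$mean, tolerance = 0.06)
})

test_that("a single strong latent edge yields the largest rank correlation", {
  P <- matrix(0, 4, 4)
  P[1, 2] <- P[2, 1] <- 0.5
  K <- symnet:::.precision_from_pcor(P, paste0("n", 1:4))
  thr <- matrix(qnorm(seq(0.45, 0.95, length.out = 10)), 4, 10, byrow = TRUE)
  d <- generate_ordinal_dataset(5000, K, thr, seed = 11)
  R <- spearman_matrix(d)$R
  off <- abs(R[upper.tri(R)])
  expect_equal(which.max(off), 1L)  # pair (1,2) is the first upper-tri entry
  expect_gt(abs(R[1, 2]), max(off[-1]))
})

test_that("same seed reproduces the study bit-for-bit; discretization is monotone", {
  spec <- generator_spec(n_per_group = c("<5y" = 60, "5-10y" = 60, ">10y" = 60),
                         seed = 42)
  d1 <- generate_study(spec)
  d2 <- generate_study(spec)
  expect_identical(d1$values, d2$values)
  expect_identical(d1$covariates, d2$covariates)

  thr <- mdasi_thresholds()[1, ]
  z <- sort(rnorm(200))
  sc <- findInterval(z, thr)
  expect_true(all(diff(sc) >= 0))
})

test_that("large-n category frequencies converge to the normal-mass targets", {
  thr <- mdasi_thresholds()
  probs_target <- diff(c(0, pnorm(thr["vomiting", ]), 1))
  K <- generate_precision_matrix(13, 0, c(0.1, 0.2), seed = 6)
  d <- generate_ordinal_dataset(1e5, K, thr, seed = 7)
  freq <- tabulate(d$values[, "vomiting"] + 1L, nbins = 11) / 1e5
  expect_true(all(abs(freq - probs_target) < 0.01))
})

test_that("density scaling orders the true group densities as requested", {
  spec <- generator_spec(n_per_group = c("<5y" = 50, "5-10y" = 50, ">10y" = 50),
                         density_scale = c(1.5, 1.0, 1.0), seed = 9)
  d <- generate_study(spec)
  truth <- attr(d, "truth")
  dens <- vapply(truth$precision_by_group, function(K)
    sum(abs(K$pcor[upper.tri(K$pcor)])), numeric(1))
  expect_gt(dens[["<5y"]], dens[["5-10y"]])
  expect_equal(dens[["5-10y"]], dens[[">10y"]], tolerance = 1e-10)

  # null configuration: identical scales give identical true networks
  spec0 <- generator_spec(n_per_group = c("<5y" = 50, "5-10y" = 50, ">10y" = 50),
                          density_scale = c(1, 1, 1), seed = 9)
  t0 <- attr(generate_study(spec0), "truth")
  expect_equal(t0$precision_by_group[["<5y"]]$K,
               t0$precision_by_group[[">10y"]]$K, tolerance = 1e-10)
})

test_that("excessive density scaling is rejected with a diagnostic", {
  spec <- generator_spec(n_per_group = c("<5y" = 50, "5-10y" = 50, ">10y" = 50),
                         weight_range = c(0.3, 0.4), edge_prob = 0.6,
                         density_scale = c(4, 1, 1), seed = 10)
  expect_error(generate_study(spec), "density_scale")
})

test_that("covariate effects shift severity in the stated direction", {
  signs <- matrix(NA_real_, 5, 2)
  for (s in 1:5) {
    spec <- generator_spec(
      n_per_group = c("<5y" = 334, "5-10y" = 333, ">10y" = 333),
      covariate_effects = c(chemotherapy = 0.3, cardiovascular = 0.2,
                            duration_years = -0.02),
      seed = 100 + s)
    d <- generate_study(spec)
    reg <- overall_severity_regression(d, min_positive = 50)
    tab <- reg$table
    signs[s, ] <- c(tab$beta[tab$covariate == "chemotherapy"],
                    tab$beta[tab$covariate == "duration_years"])
  }
  expect_true(all(signs[, 1] > 0))
  expect_true(all(signs[, 2] < 0))
})

test_that("CSV round trip preserves the dataset and truth JSON is written", {
  spec <- generator_spec(n_per_group = c("<5y" = 40, "5-10y" = 40, ">10y" = 40),
                         seed = 12)
  d <- generate_study(spec)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_symptom_csv(d, csv)
  write_truth_json(d, js)
  d2 <- read_symptom_csv(csv)
  expect_identical(unname(d$values), unname(d2$values))
  expect_equal(d$covariates$duration_years, d2$covariates$duration_years)
  expect_identical(d$group, d2$group)
  truth <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(truth$seed, 12)
  expect_length(truth$precision_by_group, 3)
})

test_that("dataset construction applies listwise deletion and validates scores", {
  v <- matrix(c(1, 2, NA, 3, 4, 5), 3, 2)
  d <- symptom_dataset(v)
  expect_equal(nrow(d$values), 2)
  expect_error(symptom_dataset(matrix(c(1, 11), 1, 2)), "0..10")
  expect_error(symptom_dataset(matrix(c(1.5, 2), 1, 2)), "0..10")
})
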