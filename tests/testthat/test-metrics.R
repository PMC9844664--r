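test_that("shortest-path distances use reciprocal absolute weights", {
  W <- matrix(0, 2, 2); W[1, 2] <- W[2, 1] <- 0.5
  D <- shortest_path_distances(W)
  expect_equal(D[1, 2], 2.0)

  # A-B (0.5), B-C (0.5), A-C (0.1): the indirect route wins, d(A,C) = 4
  W <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  W["A", "B"] <- W["B", "A"] <- 0.5
  W["B", "C"] <- W["C", "B"] <- 0.5
  W["A", "C"] <- W["C", "A"] <- 0.1
  D <- shortest_path_distances(W)
  expect_equal(D["A", "C"], 4)

  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 0.4
  D <- shortest_path_distances(W)
  expect_equal(D[1, 3], Inf)
  expect_equal(unname(diag(D)), rep(0, 3))
})

test_that("centrality on canonical graphs: star strength, path betweenness, handshake", {
  p <- 5
  W <- matrix(0, p, p)
  W[1, 2:p] <- W[2:p, 1] <- 0.5
  ct <- centrality_table(W)
  expect_equal(ct$strength[1], 0.5 * (p - 1))
  expect_equal(ct$strength[-1], rep(0.5, p - 1))

  W4 <- matrix(0, 4, 4)
  W4[1, 2] <- W4[2, 1] <- 0.3
  W4[2, 3] <- W4[3, 2] <- 0.3
  W4[3, 4] <- W4[4, 3] <- 0.3
  ct4 <- centrality_table(W4)
  expect_equal(ct4$betweenness, c(0, 2, 2, 0))

  W6 <- random_weight_matrix(6, 0.6, seed = 51)
  ct6 <- centrality_table(W6)
  expect_equal(sum(ct6$strength), 2 * sum(abs(W6[upper.tri(W6)])))
})

test_that("centrality matches exhaustive path enumeration on random networks", {
  for (s in 1:25) {
    W <- random_weight_matrix(6, edge_prob = 0.5, seed = 900 + s)
    ct <- centrality_table(W)
    oc <- oracle_centrality(W)
    expect_equal(ct$strength, oc$strength, tolerance = 1e-12)
    expect_equal(ct$expected_influence, oc$expected_influence,
                 tolerance = 1e-12)
    expect_equal(ct$closeness, oc$closeness, tolerance = 1e-10)
    expect_equal(ct$betweenness, oc$betweenness, tolerance = 1e-9)
  }
})

test_that("betweenness splits credit fractionally on constructed ties", {
  # square: 1-2, 2-4, 1-3, 3-4 all equal weights; two tied shortest 1->4 paths
  W <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(2, 4), c(1, 3), c(3, 4)))
    W[e[1], e[2]] <- W[e[2], e[1]] <- 0.5
  ct <- centrality_table(W)
  expect_equal(ct$betweenness, c(0.5, 0.5, 0.5, 0.5))
  expect_equal(oracle_centrality(W)$betweenness, c(0.5, 0.5, 0.5, 0.5))
})

test_that("isolated nodes get zero strength, closeness, and betweenness", {
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 0.6
  ct <- centrality_table(W)
  expect_equal(ct$strength[3], 0)
  expect_equal(ct$closeness[3], 0)
  expect_equal(ct$betweenness[3], 0)
})

test_that("density statistic: arithmetic, bounds, invariances", {
  expect_equal(network_density(diag(5))$value, 0)
  M <- diag(3)
  M[1, 2] <- M[2, 1] <- 0.5
  M[1, 3] <- M[3, 1] <- -0.2
  M[2, 3] <- M[3, 2] <- 0.1
  expect_equal(network_density(M)$value, 0.8)
  allone <- matrix(1, 13, 13)
  expect_equal(network_density(allone)$value, 78)

  # invariant under relabeling; strictly increasing in any |entry|
  perm <- c(2, 3, 1)
  expect_equal(network_density(M[perm, perm])$value,
               network_density(M)$value)
  M2 <- M; M2[1, 3] <- M2[3, 1] <- -0.3
  expect_gt(network_density(M2)$value, network_density(M)$value)
})

test_that("predictability: exact copy, isolated node, and simulation check", {
  set.seed(61)
  x <- sample(0:10, 400, replace = TRUE)
  vals <- cbind(a = x, b = x, c = sample(0:10, 400, replace = TRUE))
  d <- symptom_dataset(vals)
  W <- matrix(0, 3, 3, dimnames = list(colnames(vals), colnames(vals)))
  W[1, 2] <- W[2, 1] <- 0.8
  net <- structure(list(W = W, labels = colnames(vals)),
                   class = "pcor_network")
  pt <- node_predictability(d, net)
  expect_equal(pt$r_squared[1], 1)
  expect_equal(pt$r_squared[3], 0)  # isolated

  # latent rho = 0.6 single edge: R^2 close to squared Spearman correlation
  P <- matrix(0, 2, 2); P[1, 2] <- P[2, 1] <- 0.6
  K <- symnet:::.precision_from_pcor(P, c("a", "b"))
  thr <- matrix(qnorm(seq(0.3, 0.95, length.out = 10)), 2, 10, byrow = TRUE)
  dd <- generate_ordinal_dataset(5000, K, thr, seed = 62)
  W2 <- matrix(c(0, 0.6, 0.6, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  net2 <- structure(list(W = W2, labels = c("a", "b")),
                    class = "pcor_network")
  pt2 <- node_predictability(dd, net2)
  rho_s <- spearman_matrix(dd)$R[1, 2]
  expect_lt(abs(pt2$r_squared[1] - rho_s^2), 0.05)
  expect_true(all(pt2$r_squared >= 0 & pt2$r_squared <= 1))
})

test_that("predictability is invariant to monotone recoding of predictors", {
  set.seed(63)
  vals <- cbind(a = sample(0:4, 200, TRUE), b = sample(0:4, 200, TRUE))
  W <- matrix(c(0, 0.5, 0.5, 0), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  net <- structure(list(W = W, labels = c("a", "b")), class = "pcor_network")
  p1 <- node_predictability(symptom_dataset(vals), net)
  recoded <- cbind(a = c(0L, 2L, 3L, 7L, 10L)[vals[, "a"] + 1L], b = vals[, "b"])
  p2 <- node_predictability(symptom_dataset(recoded), net)
  expect_equal(p1$r_squared, p2$r_squared, tolerance = 1e-12)
})
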