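test_that("the two-dyad worked example evaluates to Q = 0.5", {
  tens <- two_dyad_tensor()
  g <- matrix(c(1, 1, 2, 2), 4, 1)
  expect_equal(multilayer_modularity(tens, g, modularity_params(1, 0)),
               0.5)
  expect_equal(brute_modularity(tens, g, omega = 0), 0.5)
})

test_that("implementation Q matches the brute-force double sum", {
  for (case in 1:30) {
    n <- sample(3:8, 1)
    L <- sample(1:3, 1)
    tens <- random_tensor(n, L, seed = 100 + case)
    set.seed(200 + case)
    g <- matrix(sample.int(3, n * L, replace = TRUE), n, L)
    gamma <- runif(1, 0.5, 2)
    omega <- runif(1, 0, 2)
    expect_equal(
      multilayer_modularity(tens, g, modularity_params(gamma, omega)),
      brute_modularity(tens, g, gamma, omega),
      tolerance = 1e-10)
  }
})

test_that("omega = 0 reduces to normalized single-layer NG modularity", {
  tens <- random_tensor(6, 3, seed = 42)
  set.seed(43)
  g <- matrix(sample.int(2, 18, replace = TRUE), 6, 3)
  # manual: sum over layers of per-layer NG sums, all over total weight
  total <- 0
  denom <- 0
  for (l in 1:3) {
    A <- tens$weights[, , l]
    k <- rowSums(A)
    denom <- denom + sum(k)
    same <- outer(g[, l], g[, l], "==")
    total <- total + sum((A - outer(k, k) / sum(k)) * same)
  }
  expect_equal(multilayer_modularity(tens, g, modularity_params(1, 0)),
               total / denom, tolerance = 1e-12)
})

test_that("one-community partitions leave only the coupling term", {
  for (case in 1:10) {
    tens <- random_tensor(6, 3, seed = 300 + case)
    g <- matrix(1L, 6, 3)
    omega <- runif(1, 0.1, 2)
    sm <- dyncore:::supra_modularity_matrix(tens,
                                            modularity_params(1, omega))
    # intra-layer NG sums vanish exactly when everything is together
    expect_equal(
      multilayer_modularity(tens, g, modularity_params(1, omega)),
      2 * omega * 6 * 2 / sm$two_mu,
      tolerance = 1e-10)
  }
})

test_that("errors surface for invalid modularity inputs", {
  tens <- random_tensor(4, 2, seed = 1)
  g <- matrix(1L, 4, 2)
  neg <- tens$weights
  neg[1, 2, 1] <- neg[2, 1, 1] <- -0.5
  expect_error(multilayer_modularity(neg, g), "negative")
  asym <- tens$weights
  asym[1, 2, 1] <- asym[1, 2, 1] + 1e-3
  expect_error(multilayer_modularity(asym, g), "symmetric")
  expect_error(multilayer_modularity(tens, g[, 1, drop = FALSE]),
               "4 x 2")
})

test_that("Louvain recovers the exhaustive optimum on the two-dyad graph", {
  tens <- two_dyad_tensor()
  params <- modularity_params(1, 0)
  parts <- all_set_partitions(4)
  best_q <- max(vapply(parts, function(p)
    multilayer_modularity(tens, matrix(p, 4, 1), params), numeric(1)))
  expect_equal(best_q, 0.5)
  res <- louvain_multilayer(tens, params, seed = 3)
  expect_equal(res$Q, best_q)
  expect_equal(adjusted_rand_index(res$partition[, 1], c(1, 1, 2, 2)), 1)
})

test_that("Louvain is deterministic given the seed and reports its own Q", {
  tens <- random_tensor(7, 3, seed = 55)
  a <- louvain_multilayer(tens, seed = 9)
  b <- louvain_multilayer(tens, seed = 9)
  expect_identical(a$partition, b$partition)
  expect_equal(a$Q, multilayer_modularity(tens, a$partition),
               tolerance = 1e-12)
})

test_that("Louvain recovers a strongly planted multilayer partition", {
  aris <- sapply(1:5, function(seed) {
    cfg <- synthetic_config(n_regions = 40, n_layers = 6,
                            n_communities = 3, core_fraction = 0.2,
                            periphery_fraction = 0.25,
                            periphery_switch_prob = 0.8, seed = seed)
    gen <- generate_adjacency_tensor(cfg, community_block_params())
    res <- louvain_multilayer(gen$tensor, modularity_params(1, 1),
                              seed = seed)
    mean(sapply(seq_len(6), function(l)
      adjusted_rand_index(res$partition[, l],
                          gen$truth$planted_partition[, l])))
  })
  expect_true(all(aris >= 0.9))
})

test_that("flexibility implements the change-count definition", {
  g <- rbind(c(1, 1, 1, 1), c(1, 2, 1, 2), c(1, 2, 3, 4))
  f <- flexibility(g)
  expect_equal(f$per_node, c(0, 1, 1))
  expect_equal(f$mean, 2 / 3)
  g10 <- matrix(1L, 1, 10)
  g10[1, 5] <- 2L  # changes at transitions 4->5 and 5->6
  expect_equal(flexibility(g10)$per_node, 2 / 9)
  g10b <- matrix(1L, 1, 10)
  g10b[1, 10] <- 2L  # one change among 9 transitions
  expect_equal(flexibility(g10b)$per_node, 1 / 9)
  expect_error(flexibility(matrix(1L, 3, 1)), "single-layer")
})

test_that("count_communities counts distinct labels globally", {
  expect_equal(count_communities(matrix(1L, 5, 3)), 1)
  expect_equal(count_communities(matrix(1:15, 5, 3)), 15)
  expect_equal(count_communities(matrix(c(1, 1, 2, 2), 4, 1)), 2)
})

test_that("diagnostics are invariant under community relabelling", {
  tens <- random_tensor(6, 3, seed = 77)
  set.seed(78)
  g <- matrix(sample.int(4, 18, replace = TRUE), 6, 3)
  relab <- matrix(c(4L, 3L, 1L, 2L)[g], 6, 3)
  expect_equal(multilayer_modularity(tens, g),
               multilayer_modularity(tens, relab))
  expect_equal(flexibility(g), flexibility(relab))
  expect_equal(count_communities(g), count_communities(relab))
})

test_that("large omega drives partitions layer-constant", {
  cfg <- synthetic_config(n_regions = 20, n_layers = 5, n_communities = 3,
                          core_fraction = 0.2, periphery_fraction = 0.3,
                          periphery_switch_prob = 0.8, seed = 5)
  gen <- generate_adjacency_tensor(cfg, community_block_params())
  res <- louvain_multilayer(gen$tensor, modularity_params(1, 50), seed = 6)
  expect_lt(flexibility(res$partition)$mean, 0.01)
})

test_that("a 100-optimization ensemble has the reference shape", {
  tens <- random_tensor(6, 2, seed = 17)
  ens <- run_ensemble(tens, n_runs = 100, seed = 8)
  expect_length(ens$runs, 100)
  expect_length(ens$Q, 100)
  expect_equal(dim(ens$flexibility), c(6, 100))
  expect_true(is.finite(ens$summary$Q_se))
  expect_true(is.finite(ens$summary$flexibility_se))
})

test_that("run_ensemble reports per-run and averaged diagnostics", {
  tens <- random_tensor(8, 3, seed = 90)
  ens <- run_ensemble(tens, n_runs = 5, seed = 4)
  expect_length(ens$runs, 5)
  expect_length(ens$Q, 5)
  expect_true(all(is.finite(ens$summary$Q_se)))
  one <- run_ensemble(tens, n_runs = 1, seed = 4)
  expect_equal(one$summary$Q_mean, one$Q[1])
  # degenerate empty tensor: no crash, Q <= 0 handled
  empty <- adjacency_tensor(array(0, c(5, 5, 2)))
  res <- louvain_multilayer(empty, modularity_params(1, 0), seed = 1)
  expect_true(res$Q <= 0)
  expect_equal(count_communities(res$partition), 10)
})
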