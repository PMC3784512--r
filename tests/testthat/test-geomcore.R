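# Exhaustive-search oracle for the best core quality over all node orders
# (N <= 7): independent of the annealing path.
exhaustive_best_R <- function(A, params) {
  n <- nrow(A)
  Cv <- dyncore:::transition_unit(n, params)
  diag(A) <- 0
  best <- -Inf
  perms <- dyncore:::all_permutations(n)
  for (p in perms) {
    cv <- numeric(n)
    cv[p] <- Cv
    R <- as.numeric(t(cv) %*% A %*% cv)
    if (R > best) best <- R
  }
  best
}

test_that("transition vectors take the stated two-segment form", {
  expect_equal(transition_vector(10, transition_params(0, 0.5)),
               seq(0.1, 1, by = 0.1))
  v1 <- transition_vector(12, transition_params(1, 0.5))
  expect_equal(v1, c(rep(0, 6), rep(1, 6)))  # binary at alpha = 1
  # alpha = 0: maximum jump equals the linear increment (fuzziest)
  v0 <- transition_vector(10, transition_params(0, 0.5))
  expect_equal(max(diff(v0)), 0.1, tolerance = 1e-12)
  # generic properties over a parameter sweep
  for (a in c(0, 0.3, 0.8, 1)) {
    for (b in c(0, 0.25, 0.5, 0.9, 1)) {
      v <- transition_vector(17, transition_params(a, b))
      expect_true(all(v >= 0))
      expect_true(all(diff(v) >= -1e-12))
      m <- floor(b * 17)
      if (m >= 1 && m < 17)  # boundary jump is at least alpha
        expect_gte(v[m + 1] - v[m], a - 1e-12)
    }
  }
  expect_error(transition_params(1.5, 0.5), "\\[0, 1\\]")
})

test_that("core quality matches hand evaluation on small graphs", {
  # 2-node graph, single edge weight w: R = 2 w c1 c2
  w <- 0.7
  A <- matrix(c(0, w, w, 0), 2, 2)
  p <- transition_params(0.4, 0.5)
  Cv <- dyncore:::transition_unit(2, p)
  expect_equal(core_quality(A, 1:2, p), 2 * w * Cv[1] * Cv[2])
  # empty graph
  expect_equal(core_quality(matrix(0, 4, 4), 1:4,
                            transition_params(0.5, 0.5)), 0)
  # joint relabelling invariance
  set.seed(3)
  M <- matrix(runif(25), 5, 5)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  ord <- c(2, 5, 1, 4, 3)
  perm <- sample.int(5)
  M2 <- M[perm, perm]
  ord2 <- match(ord, perm)
  expect_equal(core_quality(M, ord, p), core_quality(M2, ord2, p))
  expect_error(core_quality(matrix(runif(9), 3, 3), 1:3, p),
               "not symmetric")
})

test_that("annealing finds the exhaustive optimum on tiny instances", {
  hits <- 0
  n_cases <- 12
  for (case in seq_len(n_cases)) {
    set.seed(400 + case)
    n <- sample(5:7, 1)
    A <- matrix(runif(n * n), n, n)
    A <- (A + t(A)) / 2
    diag(A) <- 0
    p <- transition_params(runif(1), runif(1, 0.2, 0.8))
    res <- anneal_assignment(A, p, n_restarts = 3, seed = case)
    best <- exhaustive_best_R(A, p)
    expect_lte(res$R, best + 1e-10)
    if (abs(res$R - best) < 1e-10) hits <- hits + 1
  }
  expect_gte(hits / n_cases, 0.95)
})

test_that("a dominant hub receives the largest local value", {
  n <- 7
  A <- matrix(0.05, n, n)
  A[1, ] <- A[, 1] <- 0.9   # star-like dominant node
  diag(A) <- 0
  p <- transition_params(0.5, 0.8)
  res <- anneal_assignment(A, p, n_restarts = 3, seed = 2)
  expect_equal(which.max(res$local_values), 1L)
})

test_that("returned R dominates the strength-ranked initial order and
           is monotone in restarts", {
  set.seed(11)
  A <- matrix(runif(400), 20, 20)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  p <- transition_params(0.5, 0.7)
  strength_R <- core_quality(A, order(rowSums(A)), p)
  r1 <- anneal_assignment(A, p, n_restarts = 1, seed = 5)
  r3 <- anneal_assignment(A, p, n_restarts = 3, seed = 5)
  expect_gte(r1$R, strength_R)
  expect_gte(r3$R, r1$R - 1e-12)  # best-of-k monotone, shared seed stream
})

test_that("planted core nodes occupy the top core-score positions", {
  wins <- sapply(1:5, function(seed) {
    cfg <- synthetic_config(n_regions = 30, n_layers = 2,
                            n_communities = 2, core_fraction = 0.2,
                            periphery_fraction = 0.8, seed = seed)
    gen <- generate_adjacency_tensor(cfg, gradient_block_params())
    A <- gen$tensor$weights[, , 1]
    core <- gen$truth$planted_core_nodes
    beta <- 1 - length(core) / 30
    res <- anneal_assignment(A, transition_params(0.5, beta),
                             n_restarts = 3, seed = seed)
    top <- res$permutation[(floor(beta * 30) + 1):30]
    all(core %in% top)
  })
  expect_gte(mean(wins), 0.9)
})

test_that("the landscape recovers the planted core-size convention", {
  # planted core fraction 0.15 -> argmax beta near 0.85
  betas <- sapply(1:3, function(seed) {
    cfg <- synthetic_config(n_regions = 26, n_layers = 2,
                            n_communities = 2, core_fraction = 0.15,
                            periphery_fraction = 0.85, seed = 40 + seed)
    gen <- generate_adjacency_tensor(cfg, gradient_block_params())
    land <- rscore_landscape(gen$tensor$weights[, , 1],
                             alpha_grid = c(0.3, 0.6, 0.9),
                             beta_grid = seq(0.1, 0.9, by = 0.1),
                             n_restarts = 1, seed = seed)
    expect_equal(dim(land$R), c(3, 9))
    expect_true(all(is.finite(land$R)))
    land$beta_star
  })
  expect_true(all(abs(betas - 0.85) <= 0.15))
})

test_that("core scores are normalized with max exactly 1 and separate
           planted strata", {
  gaps <- sapply(1:5, function(seed) {
    cfg <- synthetic_config(n_regions = 24, n_layers = 2,
                            n_communities = 2, core_fraction = 0.2,
                            periphery_fraction = 0.8, seed = 60 + seed)
    gen <- generate_adjacency_tensor(cfg, gradient_block_params())
    cs <- core_scores(gen$tensor$weights[, , 1], 0.5, 0.8,
                      n_restarts = 2, seed = seed)
    expect_equal(max(cs$score), 1)
    expect_true(all(cs$score >= 0 & cs$score <= 1))
    mean(cs$score[gen$truth$planted_core_nodes]) -
      mean(cs$score[gen$truth$planted_periphery_nodes])
  })
  expect_true(all(gaps > 0))
})

test_that("aggregate-mode scores are also normalized and well-formed", {
  set.seed(9)
  A <- matrix(runif(144), 12, 12)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  cs <- core_scores(A, 0.5, 0.8, n_restarts = 1, seed = 3,
                    mode = "aggregate",
                    alpha_grid = c(0.3, 0.7), beta_grid = c(0.4, 0.8))
  expect_equal(max(cs$score), 1)
  expect_true(all(cs$score >= 0))
})

test_that("degenerate equal block means leave no recoverable core", {
  overlaps <- sapply(1:20, function(seed) {
    cfg <- synthetic_config(n_regions = 20, n_layers = 2,
                            n_communities = 2, core_fraction = 0.2,
                            periphery_fraction = 0.8, seed = 600 + seed)
    gen <- generate_adjacency_tensor(cfg,
      list(core_core = 0.4, core_periphery = 0.4,
           periphery_periphery = 0.4, concentration = 30,
           community_contrast = 0))
    res <- anneal_assignment(gen$tensor$weights[, , 1],
                             transition_params(0.5, 0.8),
                             n_restarts = 1, seed = seed)
    core <- gen$truth$planted_core_nodes
    top <- res$permutation[17:20]
    length(intersect(top, core)) / length(core)
  })
  # 4 planted core nodes, 4 top slots of 20: chance overlap = 0.2
  expect_lt(mean(overlaps), 0.5)
})

test_that("core_score_summary aggregates means and variance over nodes", {
  prof <- c(0.2, 0.4, 1, 0.1)
  s <- core_score_summary(cbind(prof, prof, prof))
  expect_equal(s$node_mean, prof)
  expect_equal(s$variance, mean((prof - mean(prof))^2))
  expect_equal(core_score_summary(matrix(0.5, 6, 3))$variance, 0)
  # independent shuffles across many layers shrink the variance of means
  set.seed(13)
  base <- seq(0, 1, length.out = 20)
  one <- mean((base - mean(base))^2)
  shuffled <- sapply(1:50, function(i) sample(base))
  s50 <- core_score_summary(shuffled)
  expect_lt(s50$variance, one / 5)
})
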