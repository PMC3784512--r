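test_that("synthetic_config validates its arguments", {
  expect_error(synthetic_config(n_regions = 10, n_communities = 11),
               "n_communities")
  expect_error(synthetic_config(core_fraction = 0.7,
                                periphery_fraction = 0.5),
               "<= 1")
  expect_error(synthetic_config(periphery_switch_prob = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_config(n_layers = 1), "n_layers")
  expect_error(synthetic_config(coupling_strength = -0.1), "\\[0, 1\\]")
  cfg <- synthetic_config(periphery_switch_prob = 0.8)
  expect_equal(cfg$bulk_switch_prob, sqrt(0.02 * 0.8))
})

test_that("generators are deterministic given the seed", {
  cfg <- synthetic_config(n_regions = 12, n_layers = 3, window_len = 32,
                          n_communities = 2, seed = 9)
  a <- generate_timeseries(cfg)
  b <- generate_timeseries(cfg)
  expect_identical(a$ts$values, b$ts$values)
  expect_identical(a$truth$planted_partition, b$truth$planted_partition)
  ta <- generate_adjacency_tensor(cfg)
  tb <- generate_adjacency_tensor(cfg)
  expect_identical(ta$tensor$weights, tb$tensor$weights)
  ca <- generate_learning_cohort(4, seed = 5)
  cb <- generate_learning_cohort(4, seed = 5)
  expect_identical(ca$trials, cb$trials)
  expect_identical(ca$truth$subject_kappa, cb$truth$subject_kappa)
})

test_that("adjacency tensors have the contracted shape and properties", {
  cfg <- synthetic_config(seed = 2)   # defaults: 112 regions, 10 layers
  gen <- generate_adjacency_tensor(cfg)
  expect_equal(dim(gen$tensor$weights), c(112, 112, 10))
  for (l in c(1, 5, 10)) {
    W <- gen$tensor$weights[, , l]
    expect_equal(W, t(W))
    expect_true(all(diag(W) == 0))
    expect_true(min(W) >= 0 && max(W) <= 1)
  }
  expect_true(length(intersect(gen$truth$planted_core_nodes,
                               gen$truth$planted_periphery_nodes)) == 0)
  expect_equal(dim(gen$truth$planted_partition), c(112, 10))
})

test_that("block weight means order core-core above periphery-periphery", {
  cfg <- synthetic_config(n_regions = 30, n_layers = 2, n_communities = 2,
                          core_fraction = 0.3, periphery_fraction = 0.4,
                          seed = 4)
  gen <- generate_adjacency_tensor(cfg, list(core_core = 0.9,
                                             core_periphery = 0.5,
                                             periphery_periphery = 0.1,
                                             concentration = 30))
  W <- gen$tensor$weights[, , 1]
  core <- gen$truth$planted_core_nodes
  per <- gen$truth$planted_periphery_nodes
  cc <- W[core, core][upper.tri(W[core, core])]
  pp <- W[per, per][upper.tri(W[per, per])]
  expect_gt(mean(cc), mean(pp))
  expect_error(
    generate_adjacency_tensor(cfg, list(core_core = 1.2,
                                        core_periphery = 0.5,
                                        periphery_periphery = 0.1)),
    "\\[0, 1\\]")
  expect_error(
    generate_adjacency_tensor(cfg, list(core_core = 0.2,
                                        core_periphery = 0.5,
                                        periphery_periphery = 0.1)),
    "ordered")
})

test_that("planted coupling produces within > between scale-2 coherence", {
  cfg <- synthetic_config(n_regions = 20, n_layers = 4, window_len = 64,
                          n_communities = 2, core_fraction = 0.5,
                          periphery_fraction = 0, coupling_strength = 0.9,
                          seed = 3)
  gen <- generate_timeseries(cfg)
  tens <- build_tensor(gen$ts)
  lab <- gen$truth$planted_partition
  for (l in seq_len(4)) {
    W <- tens$weights[, , l]
    same <- outer(lab[, l], lab[, l], "==") & upper.tri(W)
    diff <- !outer(lab[, l], lab[, l], "==") & upper.tri(W)
    expect_gt(mean(W[same]), mean(W[diff]))
  }
})

test_that("zero coupling gives coherence at the independent-noise level", {
  cfg <- synthetic_config(n_regions = 10, n_layers = 2, window_len = 64,
                          n_communities = 2, coupling_strength = 0,
                          seed = 4)
  tens <- build_tensor(generate_timeseries(cfg)$ts)
  vals <- tens$weights[upper.tri(tens$weights[, , 1])]
  # Welch with 3 half-overlapping segments has an independence bias near
  # 1/3; shared signal would push well above it
  expect_lt(mean(vals), 0.45)
})

test_that("coherence contrast grows with coupling strength", {
  gap <- sapply(c(0.2, 0.6, 0.9), function(cs) {
    cfg <- synthetic_config(n_regions = 12, n_layers = 2, window_len = 64,
                            n_communities = 2, core_fraction = 0.5,
                            periphery_fraction = 0, coupling_strength = cs,
                            seed = 11)
    gen <- generate_timeseries(cfg)
    tens <- build_tensor(gen$ts)
    lab <- gen$truth$planted_partition
    mean(sapply(1:2, function(l) {
      W <- tens$weights[, , l]
      same <- outer(lab[, l], lab[, l], "==") & upper.tri(W)
      mean(W[same]) - mean(W[!outer(lab[, l], lab[, l], "==") &
                              upper.tri(W)])
    }))
  })
  expect_true(all(diff(gap) > 0))
})

test_that("learning cohort plants the stated behavioral world", {
  expect_error(generate_learning_cohort(2), "n_subjects")
  expect_error(generate_learning_cohort(5, A = -1), "positive")
  # noiseless: fitted kappa equals planted kappa
  coh <- generate_learning_cohort(4, noise_model = list(scale = 0,
                                                        outlier_rate = 0),
                                  seed = 8)
  kap <- fit_cohort_kappa(coh$trials)
  expect_equal(kap, coh$truth$subject_kappa, tolerance = 1e-4)
  # all ground truth recorded
  expect_length(coh$truth$subject_kappa, 4)
  expect_length(coh$partitions, 4)
  expect_true(all(coh$truth$subject_kappa < 0))
})

test_that("effect_size = 0 leaves moment-kappa correlation centered on 0", {
  rhos <- sapply(1:12, function(s) {
    coh <- generate_learning_cohort(12, effect_size = 0, seed = 3000 + s)
    flex <- lapply(coh$partitions, function(p) flexibility(p)$per_node)
    link_flexibility_learning(flex,
                              coh$truth$subject_kappa)$skewness$coefficient
  })
  expect_lt(abs(mean(rhos)), 0.25)
  expect_gt(mean(rhos > 0), 0.15)  # both signs occur
  expect_gt(mean(rhos < 0), 0.15)
})
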