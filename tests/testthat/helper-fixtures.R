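# Shared fixtures and independent oracles used across test files.

# Random valid multilayer tensor (symmetric layers, zero diagonal,
# weights in [0, 1]).
random_tensor <- function(n, L, seed, density = 1) {
  set.seed(seed)
  w <- array(0, c(n, n, L))
  for (l in seq_len(L)) {
    m <- matrix(0, n, n)
    iu <- upper.tri(m)
    vals <- runif(sum(iu))
    if (density < 1) vals <- vals * (runif(sum(iu)) < density)
    m[iu] <- vals
    w[, , l] <- m + t(m)
  }
  adjacency_tensor(w)
}

# Brute-force multilayer modularity: explicit double sum over all
# (node, layer) slot pairs, independent of the package's vectorized path.
brute_modularity <- function(tensor, partition, gamma = 1, omega = 1) {
  A <- tensor$weights
  n <- dim(A)[1]
  L <- dim(A)[3]
  g <- as.matrix(partition)
  gamma <- rep_len(gamma, L)
  total <- 0
  two_mu <- 0
  for (l in seq_len(L)) {
    k <- rowSums(A[, , l])
    two_m <- sum(k)
    two_mu <- two_mu + two_m
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (g[i, l] == g[j, l]) {
          null_ij <- if (two_m > 0) gamma[l] * k[i] * k[j] / two_m else 0
          total <- total + A[i, j, l] - null_ij
        }
      }
    }
  }
  # inter-layer: ordered pairs (l, l+1) and (l+1, l)
  for (l in seq_len(L - 1)) {
    for (i in seq_len(n)) {
      if (g[i, l] == g[i, l + 1]) total <- total + 2 * omega
      two_mu <- two_mu + 2 * omega
    }
  }
  total / two_mu
}

# All set partitions of 1..n (restricted growth strings); for exhaustive
# modularity optimization on tiny graphs.
all_set_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxv) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxv + 1)) grow(c(prefix, v), max(maxv, v))
  }
  grow(integer(0), 0L)
  out
}

# Tiny single-layer tensor with unit edges {1-2}, {3-4}.
two_dyad_tensor <- function() {
  A <- array(0, c(4, 4, 1))
  A[1, 2, 1] <- A[2, 1, 1] <- 1
  A[3, 4, 1] <- A[4, 3, 1] <- 1
  adjacency_tensor(A)
}

# Planted community-contrast tensor config (uniform strata means so that
# only the community structure carries signal).
community_block_params <- function(contrast = 0.7) {
  list(core_core = 0.45, core_periphery = 0.45, periphery_periphery = 0.45,
       community_contrast = contrast, concentration = 30)
}

# Core-periphery gradient block params (no community contrast).
gradient_block_params <- function() {
  list(core_core = 0.9, core_periphery = 0.4, periphery_periphery = 0.05,
       community_contrast = 0, concentration = 30)
}

laplace_noise <- function(n, scale, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u <- runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}
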