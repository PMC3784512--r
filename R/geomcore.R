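# Continuous geometrical core-periphery scoring of individual layers:
# two-parameter transition vectors, core quality R, simulated-annealing
# search over node orders, (alpha, beta) landscapes and core-score
# summaries.

#' Transition-vector parameters
#'
#' @param alpha Boundary sharpness in `[0, 1]`: 0 gives the fuzziest
#'   boundary, 1 a binary core/periphery split.
#' @param beta Core-size parameter in `[0, 1]`: the fraction of nodes in
#'   the low (periphery) segment, so the core holds `N - floor(beta N)`
#'   nodes.
#' @return An object of class `dyncore_transition`.
#' @export
transition_params <- function(alpha, beta) {
  assert_prob(alpha, "alpha")
  assert_prob(beta, "beta")
  structure(list(alpha = alpha, beta = beta), class = "dyncore_transition")
}

#' Ordered two-segment transition vector
#'
#' The first `m = floor(beta * N)` entries rise linearly from near 0 to
#' `(1 - alpha) / 2`; the remaining entries rise linearly from
#' `(1 + alpha) / 2` to 1, so the jump at the boundary equals `alpha`.
#' At `alpha = 1` the vector is exactly 0 on the first segment and 1 on the
#' second (binary transition).
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param params A [transition_params()].
#' @return Nonnegative, non-decreasing numeric vector of length `n_nodes`.
#' @export
transition_vector <- function(n_nodes, params) {
  n <- assert_count(n_nodes, "n_nodes", 2L)
  a <- params$alpha
  m <- floor(params$beta * n)
  v <- numeric(n)
  if (m > 0)
    v[seq_len(m)] <- seq_len(m) * (1 - a) / (2 * m)
  if (m < n) {
    i <- seq(m + 1, n)
    v[i] <- (i - m) * (1 - a) / (2 * (n - m)) + (1 + a) / 2
  }
  v
}

# Unit-Euclidean-norm transition vector, making R comparable across
# (alpha, beta).
transition_unit <- function(n_nodes, params) {
  v <- transition_vector(n_nodes, params)
  v / sqrt(sum(v^2))
}

check_layer <- function(layer) {
  check_square_symmetric(layer, "layer")
  if (min(layer) < 0) stop_data("layer weights must be nonnegative")
  layer
}

#' Core quality of a node order
#'
#' `R = sum over ordered pairs (i != j) of A_ij C_pos(i) C_pos(j)`, where
#' the transition vector `C` is unit-normalized.  The diagonal is excluded
#' and symmetric pairs are counted in both directions.
#'
#' @param layer Symmetric nonnegative weight matrix (zero diagonal).
#' @param node_order Permutation of nodes; the node at position `k`
#'   receives the `k`-th transition value (position `N` is the deepest
#'   core).
#' @param params A [transition_params()].
#' @return Scalar core quality `R`.
#' @export
core_quality <- function(layer, node_order, params) {
  layer <- check_layer(layer)
  n <- nrow(layer)
  if (!setequal(node_order, seq_len(n)))
    stop_data("node_order must be a permutation of 1..%d", n)
  Cv <- transition_unit(n, params)
  c_node <- numeric(n)
  c_node[node_order] <- Cv
  A <- layer
  diag(A) <- 0
  as.numeric(t(c_node) %*% A %*% c_node)
}

default_schedule <- function() {
  list(cooling = 0.995, swaps_per_temp_factor = 100L, patience = 20L,
       max_temps = 5000L, n_probe = 100L)
}

anneal_once <- function(A, Cv, init) {
  sch <- attr(A, "schedule")
  anneal_core_cpp(A, Cv, init, sch$cooling,
                  as.integer(sch$swaps_per_temp_factor * nrow(A)),
                  as.integer(sch$patience), as.integer(sch$max_temps),
                  as.integer(sch$n_probe))
}

#' Simulated-annealing search for the best core assignment
#'
#' Metropolis search over node orders (pairwise position swaps) maximizing
#' the core quality `R` at fixed `(alpha, beta)`.  The first restart is
#' initialized from the strength-ranked order (weakest node in the lowest
#' position), further restarts from random orders; the best assignment over
#' all restarts is returned, so the returned `R` is at least the `R` of the
#' strength-ranked order.
#'
#' @inheritParams core_quality
#' @param schedule Annealing schedule: `cooling` (geometric factor,
#'   default 0.995), `swaps_per_temp_factor` (proposals per temperature =
#'   factor * N, default 100), `patience` (stop after this many
#'   temperatures without improvement, default 20), `max_temps`,
#'   `n_probe` (random swaps probing the initial temperature).
#' @param n_restarts Number of annealing restarts (reference analysis
#'   uses 10).
#' @param seed Integer seed.
#' @return A list with `permutation` (position -> node; last position is
#'   the deepest core), `local_values` (per-node transition values under
#'   the best order), `R`, `params`.
#' @export
anneal_assignment <- function(layer, params, schedule = default_schedule(),
                              n_restarts = 10L, seed = 1L) {
  layer <- check_layer(layer)
  n_restarts <- assert_count(n_restarts, "n_restarts", 1L)
  n <- nrow(layer)
  A <- layer
  diag(A) <- 0
  attr(A, "schedule") <- utils::modifyList(default_schedule(), schedule)
  Cv <- transition_unit(n, params)
  strength_order <- order(rowSums(A))  # weakest first
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(substream_seed(seed, 300L + r))
    init <- if (r == 1) strength_order else sample.int(n)
    res <- anneal_once(A, Cv, init)
    if (is.null(best) || res$R > best$R) best <- res
  }
  c_node <- numeric(n)
  c_node[best$perm] <- Cv
  list(permutation = best$perm, local_values = c_node, R = best$R,
       params = params)
}

#' Core-quality landscape over an (alpha, beta) grid
#'
#' Maximizes `R` by annealing at each lattice point and reports the
#' maximizing `(alpha, beta)`.
#'
#' @inheritParams anneal_assignment
#' @param alpha_grid,beta_grid Numeric vectors in `[0, 1]` (defaults: 21
#'   evenly spaced values each).
#' @param n_restarts Restarts per lattice point.
#' @return A list with `R` (matrix, rows = alpha, cols = beta),
#'   `alpha_grid`, `beta_grid`, `alpha_star`, `beta_star`, `R_max`.
#' @export
rscore_landscape <- function(layer, alpha_grid = seq(0, 1, length.out = 21),
                             beta_grid = seq(0, 1, length.out = 21),
                             schedule = default_schedule(),
                             n_restarts = 1L, seed = 1L) {
  assert_prob(alpha_grid, "alpha_grid")
  assert_prob(beta_grid, "beta_grid")
  R <- matrix(NA_real_, length(alpha_grid), length(beta_grid),
              dimnames = list(format(alpha_grid), format(beta_grid)))
  for (ai in seq_along(alpha_grid)) {
    for (bi in seq_along(beta_grid)) {
      res <- anneal_assignment(layer,
                               transition_params(alpha_grid[ai],
                                                 beta_grid[bi]),
                               schedule, n_restarts,
                               seed = substream_seed(seed,
                                                     ai * 1000L + bi))
      R[ai, bi] <- res$R
    }
  }
  am <- which(R == max(R), arr.ind = TRUE)[1, ]
  list(R = R, alpha_grid = alpha_grid, beta_grid = beta_grid,
       alpha_star = alpha_grid[am[1]], beta_star = beta_grid[am[2]],
       R_max = max(R))
}

#' Per-node geometrical core scores
#'
#' `mode = "point"` (default): each node's score is its local transition
#' value under the best annealed order at `(alpha_used, beta_used)`,
#' normalized so the maximum score is exactly 1.  `mode = "aggregate"`:
#' the score is the normalized sum over an `(alpha, beta)` grid of the
#' node's local value weighted by that point's core quality `R`.
#'
#' @inheritParams anneal_assignment
#' @param alpha_used,beta_used Transition parameters (typically the means
#'   of the landscape-maximizing distributions).
#' @param mode `"point"` or `"aggregate"`.
#' @param alpha_grid,beta_grid Grid for `mode = "aggregate"`.
#' @return An object of class `dyncore_corescore`: `score` (in `[0, 1]`,
#'   max exactly 1), `alpha_used`, `beta_used`, `R_best`, `n_restarts`.
#' @export
core_scores <- function(layer, alpha_used, beta_used,
                        schedule = default_schedule(), n_restarts = 10L,
                        seed = 1L, mode = c("point", "aggregate"),
                        alpha_grid = seq(0, 1, length.out = 5),
                        beta_grid = seq(0, 1, length.out = 5)) {
  mode <- match.arg(mode)
  if (mode == "point") {
    res <- anneal_assignment(layer,
                             transition_params(alpha_used, beta_used),
                             schedule, n_restarts, seed)
    raw <- res$local_values
    R_best <- res$R
  } else {
    n <- nrow(layer)
    raw <- numeric(n)
    R_best <- -Inf
    for (ai in seq_along(alpha_grid)) {
      for (bi in seq_along(beta_grid)) {
        res <- anneal_assignment(layer,
                                 transition_params(alpha_grid[ai],
                                                   beta_grid[bi]),
                                 schedule, n_restarts,
                                 seed = substream_seed(seed,
                                                       ai * 977L + bi))
        raw <- raw + res$local_values * res$R
        R_best <- max(R_best, res$R)
      }
    }
  }
  score <- if (max(raw) > 0) raw / max(raw) else raw
  structure(list(score = score, alpha_used = alpha_used,
                 beta_used = beta_used, R_best = R_best,
                 n_restarts = n_restarts, mode = mode),
            class = "dyncore_corescore")
}

#' Summarize core-score profiles across layers
#'
#' @param profiles A numeric matrix (nodes x layers) of per-layer core
#'   scores, or a list of [core_scores()] results / numeric vectors.
#' @return A list with `node_mean` (per-node mean score over layers) and
#'   `variance` (variance of those means over nodes).
#' @export
core_score_summary <- function(profiles) {
  if (is.list(profiles) && !is.data.frame(profiles))
    profiles <- do.call(cbind, lapply(profiles, function(p)
      if (inherits(p, "dyncore_corescore")) p$score else as.numeric(p)))
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 1) stop_data("at least one profile is required")
  node_mean <- rowMeans(profiles)
  list(node_mean = node_mean,
       variance = mean((node_mean - mean(node_mean))^2))
}
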