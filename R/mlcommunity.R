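# Multilayer modularity with the Newman-Girvan intra-layer null model,
# a Louvain-like greedy optimizer on the supra-modularity matrix, and the
# dynamic diagnostics (Q, number of communities, flexibility).

#' Multilayer modularity parameters
#'
#' @param gamma Structural resolution parameter, scalar or one value per
#'   layer (> 0).  Scales the Newman-Girvan null model within each layer.
#' @param omega Inter-layer coupling weight (>= 0) between a node and
#'   itself in neighboring layers (temporal coupling).
#' @return An object of class `dyncore_mlparams`.
#' @export
modularity_params <- function(gamma = 1, omega = 1) {
  if (any(!is.finite(gamma)) || any(gamma <= 0))
    stop_config("gamma must be > 0")
  if (!is.finite(omega) || omega < 0)
    stop_config("omega must be >= 0")
  structure(list(gamma = gamma, omega = omega), class = "dyncore_mlparams")
}

as_tensor_array <- function(tensor) {
  if (inherits(tensor, "dyncore_tensor")) return(tensor$weights)
  if (is.array(tensor) && length(dim(tensor)) == 3) return(tensor)
  stop_data("expected a dyncore_tensor or a 3-d array")
}

check_interlayer <- function(interlayer, n, L) {
  if (is.null(interlayer))
    interlayer <- replicate(L - 1, seq_len(n), simplify = FALSE)
  if (length(interlayer) != L - 1)
    stop_data("interlayer must have one permutation per layer interface")
  for (p in interlayer)
    if (length(p) != n || !setequal(p, seq_len(n)))
      stop_data("each interlayer entry must be a permutation of 1..%d", n)
  interlayer
}

# Supra-modularity matrix over the N*L (node, layer) slots: intra-layer
# diagonal blocks hold A_l - gamma_l k k' / (2 m_l); inter-layer entries
# hold omega on the (possibly permuted) couplings.  Slot (i, l) maps to row
# (l - 1) * N + i.
supra_modularity_matrix <- function(tensor, params, interlayer = NULL) {
  A <- as_tensor_array(tensor)
  n <- dim(A)[1]
  L <- dim(A)[3]
  if (min(A) < 0) stop_data("negative weights are not supported")
  gamma <- rep_len(params$gamma, L)
  omega <- params$omega
  interlayer <- check_interlayer(interlayer, n, L)
  B <- matrix(0, n * L, n * L)
  total_intra <- 0
  for (l in seq_len(L)) {
    Al <- A[, , l]
    check_square_symmetric(Al, sprintf("layer %d", l))
    k <- rowSums(Al)
    two_m <- sum(k)
    total_intra <- total_intra + two_m
    P <- if (two_m > 0) gamma[l] * outer(k, k) / two_m else 0
    idx <- (l - 1) * n + seq_len(n)
    B[idx, idx] <- Al - P
  }
  if (L > 1 && omega > 0) {
    for (l in seq_len(L - 1)) {
      rows <- (l - 1) * n + seq_len(n)
      cols <- l * n + interlayer[[l]]
      B[cbind(rows, cols)] <- omega
      B[cbind(cols, rows)] <- omega
    }
  }
  two_mu <- total_intra + 2 * omega * n * (L - 1)
  if (two_mu == 0) two_mu <- 1  # empty network: Q = 0 by convention
  list(B = B, two_mu = two_mu, n = n, L = L)
}

as_partition_matrix <- function(partition, n, L) {
  g <- as.matrix(partition)
  if (!all(dim(g) == c(n, L)))
    stop_data("partition must be %d x %d (nodes x layers)", n, L)
  if (any(!is.finite(g)) || any(g != round(g)) || any(g < 1))
    stop_data("community ids must be positive integers")
  matrix(as.integer(g), n, L)
}

#' Multilayer modularity of a partition
#'
#' Exact evaluation of the multilayer quality function: per layer, the sum
#' over all (ordered) node pairs sharing a community of
#' `A_ijl - gamma_l k_il k_jl / (2 m_l)` (Newman-Girvan null model), plus
#' the inter-layer coupling reward `omega` for every (ordered) coupled slot
#' pair sharing a community, all divided by `2 mu` (total intra-layer
#' strength plus total coupling strength).
#'
#' @param tensor A `dyncore_tensor` or 3-d array with symmetric,
#'   nonnegative layers.
#' @param partition Integer matrix, nodes x layers, of community ids
#'   (global label space).
#' @param params A [modularity_params()].
#' @param interlayer Optional list of `L - 1` permutations describing
#'   rewired inter-layer couplings (default: identity, node to itself).
#' @return The scalar modularity value `Q`.
#' @export
multilayer_modularity <- function(tensor, partition,
                                  params = modularity_params(),
                                  interlayer = NULL) {
  A <- as_tensor_array(tensor)
  n <- dim(A)[1]
  L <- dim(A)[3]
  g <- as_partition_matrix(partition, n, L)
  sm <- supra_modularity_matrix(tensor, params, interlayer)
  gv <- as.vector(g)
  same <- outer(gv, gv, "==")
  sum(sm$B[same]) / sm$two_mu
}

compact_labels <- function(x) match(x, unique(x))

# Louvain phase 1 on a (symmetric) modularity matrix: greedy single-node
# moves from `init` until a full pass makes no move.  Moves are accepted
# only for a strictly positive gain (> tol), so Q is non-decreasing.
louvain_phase1 <- function(B, init = seq_len(nrow(B)), tol = 1e-12) {
  n <- nrow(B)
  labels <- init
  repeat {
    moved <- FALSE
    for (v in sample.int(n)) {
      w <- B[v, ]
      cw <- rowsum(w, labels)            # sum of B[v, u] by community
      comm_ids <- as.integer(rownames(cw))
      cur <- labels[v]
      cur_pos <- match(cur, comm_ids)
      # links to current community excluding self-loop
      cw[cur_pos] <- cw[cur_pos] - w[v]
      gains <- cw - cw[cur_pos]
      best <- which.max(gains)
      if (gains[best] > tol && comm_ids[best] != cur) {
        labels[v] <- comm_ids[best]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  compact_labels(labels)
}

partition_quality <- function(B, labels) {
  sum(rowsum(t(rowsum(B, labels)), labels)[cbind(seq_len(max(labels)),
                                                 seq_len(max(labels)))])
}

# Louvain with aggregation and slot-level refinement: after each
# aggregation pass the partition is re-refined by single-slot moves on the
# full matrix, and aggregation/refinement cycles repeat until the quality
# stops improving.  Refinement avoids the local optima that plain
# aggregation locks in on strongly coupled multilayer problems.
louvain_matrix <- function(B, tol = 1e-12) {
  labels <- louvain_phase1(B)
  q <- partition_quality(B, labels)
  repeat {
    k <- max(labels)
    if (k > 1) {
      S <- outer(labels, seq_len(k), "==") * 1
      Bc <- t(S) %*% B %*% S
      sub <- louvain_phase1(Bc)
      labels_new <- sub[labels]
    } else labels_new <- labels
    labels_new <- louvain_phase1(B, init = labels_new)
    q_new <- partition_quality(B, labels_new)
    if (q_new <= q + tol) break
    labels <- labels_new
    q <- q_new
  }
  compact_labels(labels)
}

#' Louvain-like optimization of multilayer modularity
#'
#' Greedy local maximization on the supra-modularity matrix: nodes (slots)
#' are moved one at a time in a seeded random order whenever the move
#' strictly increases Q, then communities are aggregated and the procedure
#' recurses, stopping when a full pass makes no move.  The optimizer is
#' stochastic by node-visit order but fully deterministic given `seed`.
#'
#' @inheritParams multilayer_modularity
#' @param seed Integer seed controlling the node-visit order.
#' @return A list with `partition` (nodes x layers integer matrix, global
#'   label space) and `Q` (its multilayer modularity).
#' @export
louvain_multilayer <- function(tensor, params = modularity_params(),
                               seed = 1L, interlayer = NULL) {
  sm <- supra_modularity_matrix(tensor, params, interlayer)
  set.seed(substream_seed(seed, 1L))
  labels <- louvain_matrix(sm$B)
  partition <- matrix(labels, sm$n, sm$L)
  Q <- sum(sm$B[outer(labels, labels, "==")]) / sm$two_mu
  list(partition = partition, Q = Q)
}

#' Node flexibility of a multilayer partition
#'
#' Fraction of adjacent-layer transitions at which a node changes
#' community assignment, out of the `L - 1` possible changes.
#'
#' @param partition Integer matrix, nodes x layers.
#' @return A list with `per_node` (values in `[0, 1]`) and `mean`.
#' @export
flexibility <- function(partition) {
  g <- as.matrix(partition)
  L <- ncol(g)
  if (L < 2)
    stop_data("flexibility is undefined for a single-layer partition")
  changes <- g[, -1, drop = FALSE] != g[, -L, drop = FALSE]
  f <- rowMeans(changes)
  list(per_node = f, mean = mean(f))
}

#' Number of communities in a multilayer partition
#'
#' Distinct community ids with at least one member across all layers.
#'
#' @param partition Integer matrix, nodes x layers.
#' @return Integer count.
#' @export
count_communities <- function(partition) {
  length(unique(as.vector(as.matrix(partition))))
}

#' Ensemble of multilayer modularity optimizations
#'
#' Runs `n_runs` independent Louvain optimizations with derived seeds and
#' reports per-run and averaged diagnostics (Q, number of communities,
#' node flexibility), with standard errors over runs.
#'
#' @inheritParams louvain_multilayer
#' @param n_runs Number of optimizations (the reference analysis uses 100).
#' @return A list with `runs` (list of `louvain_multilayer()` results),
#'   `Q`, `n_communities`, `mean_flexibility` (per-run vectors),
#'   `flexibility` (node x run matrix), and `summary` (means and standard
#'   errors over runs).
#' @export
run_ensemble <- function(tensor, params = modularity_params(),
                         n_runs = 100L, seed = 1L, interlayer = NULL) {
  n_runs <- assert_count(n_runs, "n_runs", 1L)
  sm <- supra_modularity_matrix(tensor, params, interlayer)
  runs <- vector("list", n_runs)
  Qs <- numeric(n_runs)
  ncs <- integer(n_runs)
  fx <- matrix(0, sm$n, n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(substream_seed(seed, 1000L + r))
    labels <- louvain_matrix(sm$B)
    partition <- matrix(labels, sm$n, sm$L)
    Qs[r] <- sum(sm$B[outer(labels, labels, "==")]) / sm$two_mu
    ncs[r] <- count_communities(partition)
    fx[, r] <- flexibility(partition)$per_node
    runs[[r]] <- list(partition = partition, Q = Qs[r])
  }
  se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  mf <- colMeans(fx)
  list(runs = runs, Q = Qs, n_communities = ncs, mean_flexibility = mf,
       flexibility = fx,
       summary = list(Q_mean = mean(Qs), Q_se = se(Qs),
                      n_communities_mean = mean(ncs),
                      n_communities_se = se(ncs),
                      flexibility_mean = mean(mf),
                      flexibility_se = se(mf),
                      node_flexibility = rowMeans(fx)))
}
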