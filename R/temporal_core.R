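# Nodal null model (inter-layer edge rewiring) and classification of nodes
# into temporal core / bulk / periphery from flexibility confidence bounds.

#' Rewire the inter-layer couplings of a multilayer network
#'
#' Intra-layer adjacency is left untouched; at each adjacent-layer
#' interface the identity coupling (node `i` to itself) is replaced by an
#' independent, uniformly random permutation (node `i` in layer `l` couples
#' to node `pi_l(i)` in layer `l + 1`).  Coupling weights are preserved, so
#' each layer's weighted adjacency and the multiset of coupling weights are
#' conserved exactly.
#'
#' @param tensor A `dyncore_tensor` or 3-d array.
#' @param seed Integer seed.
#' @param global_permutation If `TRUE`, draw one permutation and reuse it
#'   at every interface instead of one independent draw per interface.
#' @return A list with `tensor` (unchanged input) and `interlayer` (list of
#'   `L - 1` permutations) suitable for [louvain_multilayer()].
#' @export
rewire_interlayer <- function(tensor, seed = 1L,
                              global_permutation = FALSE) {
  A <- as_tensor_array(tensor)
  n <- dim(A)[1]
  L <- dim(A)[3]
  if (L < 2) stop_data("rewiring needs at least 2 layers")
  set.seed(substream_seed(seed, 7L))
  interlayer <- if (global_permutation) {
    p <- sample.int(n)
    replicate(L - 1, p, simplify = FALSE)
  } else {
    replicate(L - 1, sample.int(n), simplify = FALSE)
  }
  list(tensor = tensor, interlayer = interlayer)
}

#' Null ensemble of nodal flexibilities under inter-layer rewiring
#'
#' For each of `n_rewirings` independent rewirings, multilayer modularity
#' is optimized `n_opts` times and nodal flexibility computed; the null
#' band is the 2.5/97.5 percentile interval of the null flexibility
#' distribution.  `pooling = "mean"` (default, matching the reference
#' procedure) first averages each node's flexibility over rewirings and
#' takes percentiles of those per-node means; `pooling = "all"` takes
#' percentiles of all pooled (node, rewiring) values.
#'
#' @inheritParams louvain_multilayer
#' @param n_rewirings Number of independent rewirings (reference: 100).
#' @param n_opts Optimizations per rewiring (flexibility averaged over
#'   them).
#' @return An object of class `dyncore_null_ensemble`: `null_flexibility`
#'   (node x rewiring matrix), `band_low`, `band_high`, `n_rewirings`,
#'   `pooling`.
#' @export
null_flexibility_ensemble <- function(tensor, params = modularity_params(),
                                      n_rewirings = 100L, n_opts = 1L,
                                      seed = 1L, pooling = c("mean", "all")) {
  n_rewirings <- assert_count(n_rewirings, "n_rewirings", 1L)
  n_opts <- assert_count(n_opts, "n_opts", 1L)
  pooling <- match.arg(pooling)
  A <- as_tensor_array(tensor)
  n <- dim(A)[1]
  sm_proto <- supra_modularity_matrix(tensor, params)  # validates input
  nf <- matrix(0, n, n_rewirings)
  for (r in seq_len(n_rewirings)) {
    rw <- rewire_interlayer(tensor, seed = substream_seed(seed, 5000L + r))
    fr <- matrix(0, n, n_opts)
    for (o in seq_len(n_opts)) {
      res <- tryCatch(
        louvain_multilayer(tensor, params,
                           seed = substream_seed(seed,
                                                 6000L + r * 101L + o),
                           interlayer = rw$interlayer),
        error = function(e) stop_numeric(
          "optimizer failed on rewiring %d: %s", r, conditionMessage(e)))
      fr[, o] <- flexibility(res$partition)$per_node
    }
    nf[, r] <- rowMeans(fr)
  }
  pool <- if (pooling == "mean") rowMeans(nf) else as.vector(nf)
  band <- quantile(pool, c(0.025, 0.975), type = 7, names = FALSE)
  structure(list(null_flexibility = nf, band_low = band[1],
                 band_high = band[2], n_rewirings = n_rewirings,
                 n_opts = n_opts, pooling = pooling),
            class = "dyncore_null_ensemble")
}

#' Classify regions into temporal core, bulk and periphery
#'
#' A region is temporal *core* if its empirical mean flexibility falls
#' strictly below the 2.5% bound of the null distribution, *periphery* if
#' strictly above the 97.5% bound, and *bulk* otherwise (boundary equality
#' is assigned to bulk).
#'
#' @param empirical_flexibility Numeric vector of mean nodal flexibilities
#'   (typically averaged over optimizations and replicates).
#' @param ensemble A [null_flexibility_ensemble()] result.
#' @param per_region If `TRUE`, compare each region against the 2.5/97.5
#'   percentiles of its own row of the null ensemble instead of the global
#'   band (one band for all regions, the default).
#' @return Factor with levels `core`, `bulk`, `periphery`, one per region.
#' @export
classify_temporal_roles <- function(empirical_flexibility, ensemble,
                                    per_region = FALSE) {
  if (!inherits(ensemble, "dyncore_null_ensemble"))
    stop_data("ensemble must come from null_flexibility_ensemble()")
  if (nrow(ensemble$null_flexibility) != length(empirical_flexibility))
    stop_data("region count mismatch: %d empirical vs %d in ensemble",
              length(empirical_flexibility),
              nrow(ensemble$null_flexibility))
  if (ncol(ensemble$null_flexibility) == 0)
    stop_data("empty null ensemble")
  if (per_region) {
    lo <- apply(ensemble$null_flexibility, 1, quantile, probs = 0.025,
                names = FALSE)
    hi <- apply(ensemble$null_flexibility, 1, quantile, probs = 0.975,
                names = FALSE)
  } else {
    lo <- ensemble$band_low
    hi <- ensemble$band_high
  }
  lab <- ifelse(empirical_flexibility < lo, "core",
                ifelse(empirical_flexibility > hi, "periphery", "bulk"))
  factor(lab, levels = c("core", "bulk", "periphery"))
}
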