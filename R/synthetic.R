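# Synthetic-data generators with planted ground truth.
#
# These generators state a small, explicit world: regions are split into a
# stiff core (community label constant in time), a switching periphery
# (label resampled at each layer with a stated probability) and an
# intermediate bulk.  Signals, adjacency weights and movement times are all
# derived from that world so every downstream stage can be scored against
# known truth.

#' Configuration for the synthetic generators
#'
#' Defaults emulate the data regime the pipeline is designed for:
#' ~112 regions observed in ~10 windows of ~60 samples at a 2 s sampling
#' interval, with coherence-valued edge weights in `[0, 1]`.  Core and
#' periphery fractions default to 19/112 and 25/112, matching the strata
#' proportions reported for the motor-learning data set this emulates.
#'
#' @param n_regions Number of regions (network nodes).
#' @param n_layers Number of time windows / network layers (>= 2).
#' @param window_len Samples per window.
#' @param sampling_interval Sampling interval in seconds.
#' @param n_communities Number of planted communities.
#' @param core_fraction Fraction of nodes in the stiff core.
#' @param periphery_fraction Fraction of nodes in the switching periphery.
#' @param periphery_switch_prob Per-layer probability that a periphery node
#'   switches its community label.
#' @param periphery_switch_mode `"resample"` (default): on a switch the
#'   label is redrawn uniformly over all communities (memoryless);
#'   `"change"`: redrawn uniformly over the *other* communities
#'   (anti-persistent), so at probability 1 the node changes community at
#'   every layer transition.
#' @param bulk_switch_prob Per-layer resampling probability for bulk nodes
#'   (always memoryless resampling); defaults to the geometric mean of a
#'   0.02 core surrogate floor and `periphery_switch_prob`, giving three
#'   distinguishable strata.
#' @param coupling_strength Proportion of shared-signal variance in
#'   `[0, 1]`: each node's windowed signal is
#'   `sqrt(cs) * z_community + sqrt(1 - cs) * noise`.
#' @param noise_sd Amplitude of the independent noise component.
#' @param seed Integer seed; every generator is deterministic given it.
#' @param strata_seed Optional separate seed for the core/bulk/periphery
#'   stratum assignment; lets replicate subjects share one stratum layout
#'   while drawing independent label dynamics and weights.  Defaults to
#'   `seed`.
#' @return An object of class `dyncore_config` (a validated list).
#' @export
synthetic_config <- function(n_regions = 112L, n_layers = 10L,
                             window_len = 60L, sampling_interval = 2,
                             n_communities = 4L,
                             core_fraction = 19 / 112,
                             periphery_fraction = 25 / 112,
                             periphery_switch_prob = 0.8,
                             periphery_switch_mode = c("resample", "change"),
                             bulk_switch_prob = NULL,
                             coupling_strength = 0.7,
                             noise_sd = 1, seed = 1L,
                             strata_seed = NULL) {
  n_regions <- assert_count(n_regions, "n_regions", 2L)
  n_layers <- assert_count(n_layers, "n_layers", 2L)
  window_len <- assert_count(window_len, "window_len", 8L)
  n_communities <- assert_count(n_communities, "n_communities", 1L)
  if (n_communities > n_regions)
    stop_config("n_communities (%d) exceeds n_regions (%d)",
                n_communities, n_regions)
  if (!is.numeric(sampling_interval) || sampling_interval <= 0)
    stop_config("sampling_interval must be a positive number of seconds")
  assert_prob(core_fraction, "core_fraction")
  assert_prob(periphery_fraction, "periphery_fraction")
  if (core_fraction + periphery_fraction > 1)
    stop_config("core_fraction + periphery_fraction must be <= 1")
  assert_prob(periphery_switch_prob, "periphery_switch_prob")
  periphery_switch_mode <- match.arg(periphery_switch_mode)
  if (is.null(bulk_switch_prob))
    bulk_switch_prob <- sqrt(0.02 * periphery_switch_prob)
  assert_prob(bulk_switch_prob, "bulk_switch_prob")
  assert_prob(coupling_strength, "coupling_strength")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_config("noise_sd must be nonnegative")
  structure(list(
    n_regions = n_regions, n_layers = n_layers, window_len = window_len,
    sampling_interval = sampling_interval, n_communities = n_communities,
    core_fraction = core_fraction, periphery_fraction = periphery_fraction,
    periphery_switch_prob = periphery_switch_prob,
    periphery_switch_mode = periphery_switch_mode,
    bulk_switch_prob = bulk_switch_prob,
    coupling_strength = coupling_strength, noise_sd = noise_sd,
    seed = assert_count(seed, "seed", 0L),
    strata_seed = if (is.null(strata_seed)) assert_count(seed, "seed", 0L)
                  else assert_count(strata_seed, "strata_seed", 0L)
  ), class = "dyncore_config")
}

# Deterministic strata assignment: core first, then periphery, then bulk,
# in a seeded random node order.
assign_strata <- function(config) {
  n <- config$n_regions
  n_core <- floor(config$core_fraction * n)
  n_per <- floor(config$periphery_fraction * n)
  set.seed(substream_seed(config$strata_seed %||% config$seed, 11L))
  ord <- sample.int(n)
  strata <- rep("bulk", n)
  if (n_core > 0) strata[ord[seq_len(n_core)]] <- "core"
  if (n_per > 0) strata[ord[n_core + seq_len(n_per)]] <- "periphery"
  strata
}

# Planted label dynamics: layer-1 labels balanced over communities; at each
# later layer a node switches its label with its stratum's probability.
# Core nodes never switch; bulk nodes resample memorylessly (uniform over
# all communities); periphery nodes either resample or, in "change" mode,
# draw uniformly from the other communities (anti-persistent).
plant_partition <- function(config, strata) {
  n <- config$n_regions
  L <- config$n_layers
  k <- config$n_communities
  p_switch <- c(core = 0, bulk = config$bulk_switch_prob,
                periphery = config$periphery_switch_prob)[strata]
  anti <- (strata == "periphery") &
    identical(config$periphery_switch_mode %||% "resample", "change")
  set.seed(substream_seed(config$seed, 23L))
  labels <- matrix(0L, n, L)
  labels[, 1] <- sample(rep_len(seq_len(k), n))
  if (L > 1) {
    for (l in 2:L) {
      switch_now <- runif(n) < p_switch
      labels[, l] <- labels[, l - 1]
      res <- switch_now & !anti
      if (any(res))
        labels[res, l] <- sample.int(k, sum(res), replace = TRUE)
      chg <- switch_now & anti
      if (any(chg) && k > 1) {
        shift <- sample.int(k - 1, sum(chg), replace = TRUE)
        labels[chg, l] <- 1L + (labels[chg, l - 1] - 1L + shift) %% k
      }
    }
  }
  labels
}

region_names <- function(n) sprintf("R%03d", seq_len(n))

ground_truth <- function(config, strata, labels) {
  list(planted_partition = labels,
       planted_core_nodes = which(strata == "core"),
       planted_periphery_nodes = which(strata == "periphery"),
       strata = strata,
       config = config)
}

# Band-pass filter a matrix of column signals to [f_lo, f_hi] Hz by FFT
# masking (zero-phase).  Used to band-limit latent community signals to the
# wavelet band the pipeline analyzes.
bandpass_fft <- function(x, dt, f_lo, f_hi) {
  n <- length(x)
  freqs <- (seq_len(n) - 1) / (n * dt)
  freqs <- pmin(freqs, 1 / dt - freqs)  # two-sided
  keep <- freqs >= f_lo & freqs <= f_hi
  xf <- fft(x)
  xf[!keep] <- 0
  out <- Re(fft(xf, inverse = TRUE)) / n
  s <- sd(out)
  if (s > 0) out / s else out
}

#' Generate windowed multichannel time series with planted structure
#'
#' In each window, every node's signal is a mixture of a latent community
#' signal (white noise band-limited to the second wavelet scale,
#' 0.0625-0.125 Hz at 2 s sampling) and independent white noise, with
#' mixing proportion `coupling_strength` on the variance scale.  Community
#' membership follows the planted core/bulk/periphery label dynamics.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `ts` (a `dyncore_timeseries`, see
#'   [timeseries_set()]) and `truth` (planted partition, core and periphery
#'   node sets, strata, config).
#' @export
generate_timeseries <- function(config) {
  stopifnot(inherits(config, "dyncore_config"))
  n <- config$n_regions
  L <- config$n_layers
  W <- config$window_len
  dt <- config$sampling_interval
  nyq <- 1 / (2 * dt)
  band <- c(nyq / 4, nyq / 2)  # scale-2 dyadic band
  strata <- assign_strata(config)
  labels <- plant_partition(config, strata)
  cs <- config$coupling_strength
  set.seed(substream_seed(config$seed, 37L))
  values <- matrix(0, n, L * W)
  for (l in seq_len(L)) {
    latent <- sapply(seq_len(config$n_communities), function(c_id)
      bandpass_fft(rnorm(W), dt, band[1], band[2]))
    noise <- matrix(rnorm(n * W, sd = 1), n, W)
    shared <- t(latent)[labels[, l], , drop = FALSE]
    values[, (l - 1) * W + seq_len(W)] <-
      config$noise_sd * (sqrt(cs) * shared + sqrt(1 - cs) * noise)
  }
  blocks <- lapply(seq_len(L), function(l) c((l - 1) * W, l * W))
  ts <- timeseries_set(values, region_labels = region_names(n),
                       sampling_interval = dt, blocks = blocks)
  list(ts = ts, truth = ground_truth(config, strata, labels))
}

#' Generate a multilayer adjacency tensor with planted structure
#'
#' Fast fixture that bypasses spectral estimation: per-layer symmetric
#' weight matrices are drawn from beta distributions on `[0, 1]` whose
#' means encode (a) a core-periphery gradient given by the stated
#' core-core / core-periphery / periphery-periphery means (bulk nodes sit
#' halfway between core and periphery) and (b) an optional planted
#' community contrast added within / subtracted between communities of the
#' planted label dynamics.
#'
#' @param config A [synthetic_config()].
#' @param block_params List with elements `core_core`, `core_periphery`,
#'   `periphery_periphery` (weight means in `[0, 1]`, ordered
#'   `core_core >= core_periphery >= periphery_periphery`),
#'   `community_contrast` (mean shift `+cc/2` within, `-cc/2` between
#'   planted communities; default 0) and `concentration` (beta
#'   concentration; larger = less weight noise).
#' @return A list with `tensor` (a `dyncore_tensor`, see
#'   [adjacency_tensor()]) and `truth`.
#' @export
generate_adjacency_tensor <- function(config,
                                      block_params = list(
                                        core_core = 0.8,
                                        core_periphery = 0.4,
                                        periphery_periphery = 0.1,
                                        community_contrast = 0,
                                        concentration = 30)) {
  stopifnot(inherits(config, "dyncore_config"))
  bp <- block_params
  for (f in c("core_core", "core_periphery", "periphery_periphery"))
    if (is.null(bp[[f]])) stop_config("block_params$%s is required", f)
  means <- c(bp$core_core, bp$core_periphery, bp$periphery_periphery)
  assert_prob(means, "block weight means")
  if (!(bp$core_core >= bp$core_periphery &&
        bp$core_periphery >= bp$periphery_periphery))
    stop_config(
      "block means must be ordered core_core >= core_periphery >= periphery_periphery")
  cc_shift <- if (is.null(bp$community_contrast)) 0 else bp$community_contrast
  assert_prob(cc_shift, "community_contrast")
  conc <- if (is.null(bp$concentration)) 30 else bp$concentration
  n <- config$n_regions
  L <- config$n_layers
  strata <- assign_strata(config)
  labels <- plant_partition(config, strata)
  coreness <- c(core = 1, bulk = 0.5, periphery = 0)[strata]
  # pairwise base mean: piecewise-linear through pp (s=0), cp (s=1/2),
  # cc (s=1) in s = mean coreness of the pair
  s <- outer(coreness, coreness, "+") / 2
  base <- ifelse(s <= 0.5,
                 bp$periphery_periphery +
                   (bp$core_periphery - bp$periphery_periphery) * 2 * s,
                 bp$core_periphery +
                   (bp$core_core - bp$core_periphery) * 2 * (s - 0.5))
  set.seed(substream_seed(config$seed, 53L))
  weights <- array(0, c(n, n, L))
  iu <- upper.tri(base)
  for (l in seq_len(L)) {
    same <- outer(labels[, l], labels[, l], "==")
    m <- pmin(pmax(base + cc_shift * (same - 0.5), 0.02), 0.98)
    W <- matrix(0, n, n)
    mu <- m[iu]
    W[iu] <- rbeta(sum(iu), mu * conc, (1 - mu) * conc)
    W <- W + t(W)
    weights[, , l] <- W
  }
  tensor <- adjacency_tensor(weights, region_labels = region_names(n),
                             layer_labels = sprintf("layer_%03d", seq_len(L)))
  list(tensor = tensor, truth = ground_truth(config, strata, labels))
}

# Laplace (double-exponential) sampler.
rlaplace <- function(n, scale) {
  u <- runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}

#' Generate a synthetic learning cohort with a planted brain-behavior link
#'
#' Each subject `s` receives a separation score `d_s` in `[0, 1]`.  Larger
#' `d_s` shrinks the subject's periphery fraction, which increases the
#' skewness and kurtosis of the subject's flexibility distribution over
#' regions (a smaller high-flexibility minority makes the distribution more
#' right-tailed), and makes the planted learning parameter `kappa_s` more
#' negative, so that flexibility-distribution moments correlate negatively
#' with `kappa` by construction.  Movement times follow
#' `MT(t) = A * exp(kappa_s * t) + B` with additive Laplace noise and
#' occasional multiplicative outliers (factor drawn uniformly from
#' `[2, 4]`), which exercises the robust least-absolute-residuals fit.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param effect_size Strength in `[0, 1]` of the planted monotone link
#'   between separation and `kappa`; 0 makes `kappa` independent of the
#'   flexibility structure.
#' @param noise_model List with `scale` (Laplace scale of the MT noise, in
#'   seconds) and `outlier_rate` (per-trial probability of an outlier).
#' @param seed Integer seed.
#' @param n_trials Trials per subject.
#' @param A,B Amplitude and asymptote of the planted learning curve
#'   (both must be positive).
#' @param n_regions,n_layers,n_communities Dimensions of each subject's
#'   planted flexibility world.
#' @return A list with `trials` (one TrialTable `data.frame` per subject:
#'   subject, sequence, type, trial, MT_s), `configs` (per-subject
#'   [synthetic_config()]), `partitions` (per-subject planted label
#'   matrices) and `truth` (`subject_kappa`, `separation`, `A`, `B`).
#' @export
generate_learning_cohort <- function(n_subjects, effect_size = 1,
                                     noise_model = list(scale = 0.1,
                                                        outlier_rate = 0.05),
                                     seed = 1L, n_trials = 100L,
                                     A = 4, B = 1,
                                     n_regions = 112L, n_layers = 10L,
                                     n_communities = 4L) {
  n_subjects <- assert_count(n_subjects, "n_subjects", 3L)
  assert_prob(effect_size, "effect_size")
  if (A <= 0 || B <= 0)
    stop_config("A and B must be positive (got A=%g, B=%g)", A, B)
  scale <- noise_model$scale %||% 0.1
  outlier_rate <- noise_model$outlier_rate %||% 0.05
  assert_prob(outlier_rate, "outlier_rate")
  set.seed(substream_seed(seed, 71L))
  d <- runif(n_subjects)
  u <- runif(n_subjects)
  kappa <- -0.01 - 0.05 * (effect_size * d + (1 - effect_size) * u)
  trials <- vector("list", n_subjects)
  configs <- vector("list", n_subjects)
  partitions <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    cfg <- synthetic_config(
      n_regions = n_regions, n_layers = n_layers,
      n_communities = n_communities,
      core_fraction = 0.15,
      periphery_fraction = 0.35 - 0.25 * d[s],
      periphery_switch_prob = 0.8,
      seed = substream_seed(seed, 100L + s))
    configs[[s]] <- cfg
    partitions[[s]] <- plant_partition(cfg, assign_strata(cfg))
    t_idx <- seq_len(n_trials)
    mt <- A * exp(kappa[s] * t_idx) + B +
      rlaplace(n_trials, scale)
    out <- runif(n_trials) < outlier_rate
    mt[out] <- mt[out] * runif(sum(out), 2, 4)
    mt <- pmax(mt, 0.05)
    trials[[s]] <- data.frame(
      subject = sprintf("S%02d", s), sequence = "seq1", type = "EXT",
      trial = t_idx, MT_s = mt, stringsAsFactors = FALSE)
  }
  list(trials = trials, configs = configs, partitions = partitions,
       truth = list(subject_kappa = kappa, separation = d, A = A, B = B))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
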