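# Pipeline orchestration: simulate -> build -> communities -> nullband ->
# corescore -> behavior -> link, with JSON configuration, per-stage
# logging, and a run manifest sufficient to reproduce the run.

default_pipeline_config <- function() {
  list(
    out_dir = "dyncore_run",
    seed = 1L,
    simulate = list(n_subjects = 8L, n_regions = 40L, n_layers = 8L,
                    window_len = 64L, sampling_interval = 2,
                    n_communities = 3L, coupling_strength = 0.7,
                    mode = "tensor",      # "tensor" (fast) or "timeseries"
                    effect_size = 1,
                    block_params = list(core_core = 0.8,
                                        core_periphery = 0.4,
                                        periphery_periphery = 0.1,
                                        community_contrast = 0.5,
                                        concentration = 30)),
    netbuild = list(scale = 2L, family = "d4",
                    estimator = list(segment_length = 32L, overlap = 0.5,
                                     window = "hann")),
    communities = list(gamma = 1, omega = 1, n_opts = 10L),
    nullband = list(n_rewirings = 20L, n_opts = 1L, pooling = "mean"),
    corescore = list(alpha = 0.5, beta = 0.8, n_restarts = 3L),
    behavior = list(loss = "lar"),
    verbose = FALSE)
}

merge_config <- function(user) {
  cfg <- default_pipeline_config()
  if (is.null(user)) return(cfg)
  utils::modifyList(cfg, user)
}

log_stage <- function(cfg, stage, msg, ...) {
  if (isTRUE(cfg$verbose))
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                    stage, sprintf(msg, ...)))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> build -> communities -> nullband -> corescore ->
#' behavior -> link with the given configuration (a nested list; missing
#' entries take documented defaults), writing each stage's outputs under
#' `config$out_dir` and returning a run manifest.  The run is
#' deterministic given `config$seed`.
#'
#' @param config Nested configuration list; see
#'   `dyncore:::default_pipeline_config()` for the full structure.
#' @return The run manifest (also written to `out_dir/manifest.json`):
#'   seeds, config, per-stage output paths, headline results.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- merge_config(config)
  if (!is.null(cfg$simulate$n_layers) && cfg$simulate$n_layers < 2)
    stop_config("n_layers must be >= 2: flexibility is undefined for a single layer")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- assert_count(cfg$seed, "seed", 0L)
  stage <- "simulate"
  manifest <- list(seed = seed, config = cfg, outputs = list(),
                   started = format(Sys.time()))
  result <- tryCatch({
    sim <- cfg$simulate
    ns <- assert_count(sim$n_subjects, "n_subjects", 4L)
    # the planted behavioral world keeps full-size defaults so that
    # per-subject flexibility distributions have enough support for
    # moment estimation, independent of the (speed-scaled) tensor size
    cohort <- generate_learning_cohort(
      ns, effect_size = sim$effect_size %||% 1,
      seed = substream_seed(seed, 2L),
      n_regions = sim$cohort_regions %||% 112L,
      n_layers = sim$cohort_layers %||% 10L,
      n_communities = sim$n_communities)
    log_stage(cfg, stage, "cohort of %d subjects generated", ns)

    stage <- "build"
    tensors <- vector("list", ns)
    for (s in seq_len(ns)) {
      scfg <- synthetic_config(
        n_regions = sim$n_regions, n_layers = sim$n_layers,
        window_len = sim$window_len %||% 64L,
        sampling_interval = sim$sampling_interval %||% 2,
        n_communities = sim$n_communities,
        coupling_strength = sim$coupling_strength %||% 0.7,
        core_fraction = sim$core_fraction %||% (19 / 112),
        periphery_fraction = cohort$configs[[s]]$periphery_fraction,
        periphery_switch_prob = sim$periphery_switch_prob %||% 0.8,
        periphery_switch_mode = sim$periphery_switch_mode %||% "resample",
        bulk_switch_prob = sim$bulk_switch_prob,
        seed = substream_seed(seed, 10L + s),
        strata_seed = substream_seed(seed, 3L))
      if (identical(sim$mode, "timeseries")) {
        ts <- generate_timeseries(scfg)$ts
        tensors[[s]] <- build_tensor(ts, scale = cfg$netbuild$scale,
                                     family = cfg$netbuild$family,
                                     params = cfg$netbuild$estimator)
      } else {
        tensors[[s]] <- generate_adjacency_tensor(
          scfg, sim$block_params)$tensor
      }
    }
    log_stage(cfg, stage, "%d multilayer tensors built", ns)

    stage <- "communities"
    mlp <- modularity_params(cfg$communities$gamma, cfg$communities$omega)
    ensembles <- lapply(seq_len(ns), function(s)
      run_ensemble(tensors[[s]], mlp, n_runs = cfg$communities$n_opts,
                   seed = substream_seed(seed, 40L + s)))
    flex <- sapply(ensembles, function(e) e$summary$node_flexibility)
    write_results_json(
      list(Q_mean = sapply(ensembles, function(e) e$summary$Q_mean),
           n_communities_mean = sapply(ensembles, function(e)
             e$summary$n_communities_mean),
           mean_flexibility = sapply(ensembles, function(e)
             e$summary$flexibility_mean)),
      file.path(cfg$out_dir, "communities.json"))
    log_stage(cfg, stage, "ensembles of %d optimizations done",
              cfg$communities$n_opts)

    stage <- "nullband"
    nulls <- lapply(seq_len(ns), function(s)
      null_flexibility_ensemble(tensors[[s]], mlp,
                                n_rewirings = cfg$nullband$n_rewirings,
                                n_opts = cfg$nullband$n_opts,
                                seed = substream_seed(seed, 70L + s),
                                pooling = if (cfg$nullband$pooling == "all")
                                  "all" else "mean"))
    pooled_null <- do.call(cbind, lapply(nulls, function(e)
      e$null_flexibility))
    pooled <- structure(list(null_flexibility = pooled_null,
                             band_low = NA, band_high = NA,
                             n_rewirings = ncol(pooled_null),
                             n_opts = cfg$nullband$n_opts,
                             pooling = cfg$nullband$pooling),
                        class = "dyncore_null_ensemble")
    # "matched": average the null matrices across subjects elementwise and
    # pool the (node, rewiring) means, so null and empirical means carry
    # the same replicate-averaging variance; "mean": per-node means over
    # everything; "all": raw pooled values
    pool_vec <- switch(cfg$nullband$pooling,
      matched = as.vector(Reduce(`+`, lapply(nulls, function(e)
        e$null_flexibility)) / length(nulls)),
      mean = rowMeans(pooled_null),
      all = as.vector(pooled_null),
      stop_config("unknown pooling '%s'", cfg$nullband$pooling))
    band <- quantile(pool_vec, c(0.025, 0.975), names = FALSE)
    pooled$band_low <- band[1]
    pooled$band_high <- band[2]
    roles <- classify_temporal_roles(rowMeans(flex), pooled)
    utils::write.table(
      data.frame(region = tensors[[1]]$region_labels,
                 class = as.character(roles)),
      file.path(cfg$out_dir, "temporal_roles.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage(cfg, stage, "band [%0.3f, %0.3f]", band[1], band[2])

    stage <- "corescore"
    cs_cfg <- cfg$corescore
    scores <- sapply(seq_len(ns), function(s) {
      per_layer <- sapply(seq_len(n_layers(tensors[[s]])), function(l)
        core_scores(tensors[[s]]$weights[, , l], cs_cfg$alpha, cs_cfg$beta,
                    n_restarts = cs_cfg$n_restarts,
                    seed = substream_seed(seed, 90L + 17L * s + l))$score)
      core_score_summary(per_layer)$node_mean
    })
    mean_scores <- rowMeans(scores)
    log_stage(cfg, stage, "core scores for %d subjects", ns)

    stage <- "behavior"
    kappa <- fit_cohort_kappa(cohort$trials, loss = cfg$behavior$loss)
    log_stage(cfg, stage, "kappa range [%0.3f, %0.3f]",
              min(kappa), max(kappa))

    stage <- "link"
    # planted flexibility world for the brain-behavior link
    planted_flex <- sapply(cohort$partitions, function(p)
      flexibility(p)$per_node)
    learn_link <- link_flexibility_learning(asplit(planted_flex, 2), kappa)
    geom_link <- link_flexibility_corescore(rowMeans(flex), mean_scores)
    results <- list(
      band = list(low = band[1], high = band[2]),
      roles = table(roles),
      kappa = kappa,
      link_skewness = list(rho = learn_link$skewness$coefficient,
                           p = learn_link$skewness$p_value),
      link_kurtosis = list(rho = learn_link$kurtosis$coefficient,
                           p = learn_link$kurtosis$p_value),
      link_corescore = list(r = geom_link$coefficient,
                            p = geom_link$p_value))
    write_results_json(results, file.path(cfg$out_dir, "results.json"))
    results
  }, dyncore_error = function(e) {
    stop(errorCondition(
      sprintf("pipeline failed at stage '%s': %s", stage,
              conditionMessage(e)),
      class = c(class(e)[1], "dyncore_pipeline_error", "dyncore_error")))
  })
  manifest$outputs <- list(
    communities = file.path(cfg$out_dir, "communities.json"),
    temporal_roles = file.path(cfg$out_dir, "temporal_roles.tsv"),
    results = file.path(cfg$out_dir, "results.json"))
  manifest$results <- result
  manifest$finished <- format(Sys.time())
  write_results_json(manifest, file.path(cfg$out_dir, "manifest.json"))
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `build`, `communities`, `nullband`,
#' `corescore`, `behavior`, `link`, `run-all`; each takes
#' `--config <file.json>` plus `--seed <int>` and `--out <dir>`
#' overrides.  Exit codes: 0 success, 2 configuration error, 3 data
#' error, 4 numerical failure.
#'
#' @param args Character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit code, invisibly; wrap as
#'   `quit(status = dyncore_cli())` in an `Rscript` entry point to
#'   propagate it to the shell.
#' @export
dyncore_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: dyncore <simulate|build|communities|nullband|corescore|",
    "behavior|link|run-all> [--config file.json] [--seed N] [--out dir]",
    "[--verbose]")
  code <- tryCatch({
    if (length(args) < 1) stop_config(usage)
    cmd <- args[1]
    opt <- list(config = NULL, seed = NULL, out = NULL, verbose = FALSE)
    i <- 2
    while (i <= length(args)) {
      a <- args[i]
      if (a == "--verbose") {
        opt$verbose <- TRUE
        i <- i + 1
      } else if (a %in% c("--config", "--seed", "--out")) {
        if (i == length(args)) stop_config("missing value for %s", a)
        opt[[sub("^--", "", a)]] <- args[i + 1]
        i <- i + 2
      } else stop_config("unknown argument '%s'\n%s", a, usage)
    }
    cfg <- list()
    if (!is.null(opt$config)) {
      if (!file.exists(opt$config))
        stop_config("config file not found: %s", opt$config)
      cfg <- jsonlite::read_json(opt$config, simplifyVector = TRUE)
    }
    if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
    if (!is.null(opt$out)) cfg$out_dir <- opt$out
    cfg$verbose <- isTRUE(opt$verbose) || isTRUE(cfg$verbose)
    run_stage_cli(cmd, cfg, usage)
    0L
  },
  dyncore_config_error = function(e) { message(conditionMessage(e)); 2L },
  dyncore_data_error = function(e) { message(conditionMessage(e)); 3L },
  dyncore_numeric_error = function(e) { message(conditionMessage(e)); 4L },
  error = function(e) { message(conditionMessage(e)); 4L })
  invisible(code)
}

run_stage_cli <- function(cmd, cfg, usage) {
  known <- c("run-all", "simulate", "build", "communities", "nullband",
             "corescore", "behavior", "link")
  if (!cmd %in% known)
    stop_config("unknown subcommand '%s'\n%s", cmd, usage)
  full <- merge_config(cfg)
  out <- full$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- full$seed
  switch(cmd,
    "run-all" = run_pipeline(cfg),
    "simulate" = {
      scfg <- do.call(synthetic_config, c(
        full$simulate[intersect(names(full$simulate),
                                names(formals(synthetic_config)))],
        list(seed = seed)))
      gen <- generate_timeseries(scfg)
      write_timeseries(gen$ts, file.path(out, "timeseries.tsv"))
      write_results_json(
        list(planted_core = gen$truth$planted_core_nodes,
             planted_periphery = gen$truth$planted_periphery_nodes,
             strata = gen$truth$strata),
        file.path(out, "ground_truth.json"))
    },
    "build" = {
      ts <- read_timeseries(file.path(out, "timeseries.tsv"))
      tensor <- build_tensor(ts, scale = full$netbuild$scale,
                             family = full$netbuild$family,
                             params = full$netbuild$estimator)
      write_tensor(tensor, file.path(out, "tensor"))
    },
    "communities" = {
      tensor <- read_tensor(file.path(out, "tensor"))
      mlp <- modularity_params(full$communities$gamma,
                               full$communities$omega)
      ens <- run_ensemble(tensor, mlp, n_runs = full$communities$n_opts,
                          seed = seed)
      write_partition(ens$runs[[which.max(ens$Q)]]$partition,
                      tensor$region_labels,
                      file.path(out, "partition.tsv"))
      write_results_json(ens$summary, file.path(out, "communities.json"))
    },
    "nullband" = {
      tensor <- read_tensor(file.path(out, "tensor"))
      mlp <- modularity_params(full$communities$gamma,
                               full$communities$omega)
      ens <- run_ensemble(tensor, mlp, n_runs = full$communities$n_opts,
                          seed = seed)
      nul <- null_flexibility_ensemble(
        tensor, mlp, n_rewirings = full$nullband$n_rewirings,
        n_opts = full$nullband$n_opts, seed = seed,
        pooling = full$nullband$pooling)
      roles <- classify_temporal_roles(ens$summary$node_flexibility, nul)
      utils::write.table(
        data.frame(region = tensor$region_labels,
                   class = as.character(roles)),
        file.path(out, "temporal_roles.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
      write_results_json(
        list(n_rewirings = nul$n_rewirings, band_low = nul$band_low,
             band_high = nul$band_high,
             empirical = ens$summary$node_flexibility),
        file.path(out, "nullband.json"))
    },
    "corescore" = {
      tensor <- read_tensor(file.path(out, "tensor"))
      cs <- full$corescore
      per_layer <- sapply(seq_len(n_layers(tensor)), function(l)
        core_scores(tensor$weights[, , l], cs$alpha, cs$beta,
                    n_restarts = cs$n_restarts,
                    seed = substream_seed(seed, l))$score)
      summ <- core_score_summary(per_layer)
      utils::write.table(
        data.frame(region = tensor$region_labels,
                   score = summ$node_mean, alpha_used = cs$alpha,
                   beta_used = cs$beta),
        file.path(out, "core_scores.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    },
    "behavior" = {
      trials <- read_trials(file.path(out, "trials.tsv"))
      fits <- lapply(split(trials, trials$subject), fit_learning_curve,
                     loss = full$behavior$loss)
      write_results_json(
        lapply(fits, function(f) f[c("kappa", "A", "B", "loss",
                                     "converged")]),
        file.path(out, "learning_fits.json"))
    },
    "link" = {
      roles <- utils::read.table(file.path(out, "temporal_roles.tsv"),
                                 sep = "\t", header = TRUE)
      nul <- jsonlite::read_json(file.path(out, "nullband.json"),
                                 simplifyVector = TRUE)
      cs <- utils::read.table(file.path(out, "core_scores.tsv"),
                              sep = "\t", header = TRUE)
      link <- link_flexibility_corescore(nul$empirical, cs$score)
      write_results_json(list(r = link$coefficient, p = link$p_value,
                              n = link$n),
                         file.path(out, "link.json"))
    },
    stop_config("unknown subcommand '%s'\n%s", cmd, usage))
  invisible(NULL)
}
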