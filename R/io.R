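# File formats: TSV for tabular data, JSON for metadata and results,
# per-layer TSV matrices + manifest.json for adjacency tensors.  All
# sample-window indices on disk are 0-based half-open; regions are always
# identified by string labels.

#' Write a time-series set as TSV plus JSON sidecar
#'
#' The TSV holds rows = regions (first column `region`), columns = sample
#' indices; the sidecar `<path>.json` holds
#' `{sampling_interval_s, blocks: [{start, end}], block_types}` with
#' 0-based half-open sample indices.
#'
#' @param ts A [timeseries_set()].
#' @param path Path of the TSV file to create.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "dyncore_timeseries"))
  df <- data.frame(region = ts$region_labels, ts$values, check.names = FALSE)
  names(df) <- c("region", seq_len(ncol(ts$values)) - 1L)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sidecar <- list(
    sampling_interval_s = ts$sampling_interval,
    blocks = lapply(ts$blocks, function(b) list(start = b[1], end = b[2])),
    block_types = ts$block_types)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a time-series set written by [write_timeseries()]
#'
#' @param path Path of the TSV file (the sidecar `<path>.json` must
#'   exist).
#' @return A `dyncore_timeseries`.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop_data("no such file: %s", path)
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path))
    stop_data("missing JSON sidecar: %s", sidecar_path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "region")
    stop_data("%s: first column must be 'region'", path)
  values <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(values) || any(!is.finite(values)))
    stop_data("%s: non-numeric or non-finite sample values", path)
  side <- jsonlite::read_json(sidecar_path, simplifyVector = FALSE)
  blocks <- lapply(side$blocks, function(b) c(b$start, b$end))
  bt <- side$block_types
  if (!is.null(bt)) bt <- unlist(bt)
  timeseries_set(unname(values), df$region, side$sampling_interval_s,
                 blocks, bt)
}

#' Write an adjacency tensor as a directory of per-layer TSV matrices
#'
#' Creates `layer_001.tsv`, ... (square matrices with region-label header
#' and row names) plus `manifest.json` listing region labels, layer order
#' and construction metadata.
#'
#' @param tensor A `dyncore_tensor`.
#' @param dir Directory to create.
#' @return `dir`, invisibly.
#' @export
write_tensor <- function(tensor, dir) {
  stopifnot(inherits(tensor, "dyncore_tensor"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- n_layers(tensor)
  files <- sprintf("layer_%03d.tsv", seq_len(L))
  for (l in seq_len(L)) {
    m <- tensor$weights[, , l]
    dimnames(m) <- list(tensor$region_labels, tensor$region_labels)
    utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                       file.path(dir, files[l]),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  manifest <- list(region_labels = tensor$region_labels,
                   layers = as.list(files),
                   layer_labels = tensor$layer_labels,
                   meta = tensor$meta)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read an adjacency tensor written by [write_tensor()]
#'
#' @param dir Directory containing `manifest.json` and layer files.
#' @return A `dyncore_tensor`.
#' @export
read_tensor <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop_data("missing manifest: %s", mpath)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  files <- man$layers
  n <- length(man$region_labels)
  weights <- array(0, c(n, n, length(files)))
  for (l in seq_along(files)) {
    fp <- file.path(dir, files[l])
    if (!file.exists(fp)) stop_data("missing layer file: %s", fp)
    m <- as.matrix(utils::read.table(fp, sep = "\t", header = TRUE,
                                     row.names = 1, check.names = FALSE))
    if (nrow(m) != n || ncol(m) != n)
      stop_data("%s: expected a %d x %d matrix", fp, n, n)
    asym <- which(abs(m - t(m)) > 1e-10, arr.ind = TRUE)
    if (nrow(asym) > 0)
      stop_data("%s: asymmetric entry at (%s, %s)", fp,
                rownames(m)[asym[1, 1]], colnames(m)[asym[1, 2]])
    if (any(is.na(m)))
      stop_data("%s: NaN/NA cells present", fp)
    weights[, , l] <- (m + t(m)) / 2
  }
  meta <- man$meta
  adjacency_tensor(weights, region_labels = man$region_labels,
                   layer_labels = man$layer_labels,
                   meta = if (is.null(meta)) list() else as.list(meta))
}

#' Write a multilayer partition as TSV
#'
#' Rows = regions (first column `region`), one integer-label column per
#' layer.
#'
#' @param partition Integer matrix, nodes x layers.
#' @param region_labels Character region names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, region_labels, path) {
  g <- as.matrix(partition)
  df <- data.frame(region = region_labels, g, check.names = FALSE)
  names(df) <- c("region", sprintf("layer_%03d", seq_len(ncol(g))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a multilayer partition written by [write_partition()]
#' @param path TSV path.
#' @return A list with `partition` (integer matrix) and `region_labels`.
#' @export
read_partition <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  list(partition = as.matrix(df[, -1, drop = FALSE]),
       region_labels = df[[1]])
}

#' Write / read a trial table (subject, sequence, type, trial, MT_s)
#' @param trials TrialTable `data.frame`.
#' @param path TSV path.
#' @return `path` / the `data.frame`.
#' @export
write_trials <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("subject", "sequence", "type", "trial", "MT_s")
  if (!all(need %in% names(df)))
    stop_data("%s: missing columns %s", path,
              paste(setdiff(need, names(df)), collapse = ", "))
  if (any(df$MT_s <= 0)) stop_data("%s: movement times must be > 0", path)
  df
}

write_results_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}
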