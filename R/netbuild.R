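# Network construction: windowed multichannel series -> multilayer weighted
# functional network, via maximal-overlap discrete wavelet decomposition and
# band-averaged magnitude-squared coherence.

#' Windowed multichannel time-series container
#'
#' @param values Numeric matrix, regions x samples; all finite.
#' @param region_labels Character vector of region names.
#' @param sampling_interval Sampling interval in seconds.
#' @param blocks List of `c(start, end)` 0-based half-open sample windows,
#'   ordered, non-overlapping, within range.
#' @param block_types Optional character labels (e.g. EXT/MOD/MIN).
#' @return An object of class `dyncore_timeseries`.
#' @export
timeseries_set <- function(values, region_labels, sampling_interval,
                           blocks, block_types = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_data("values must be a numeric matrix (regions x samples)")
  if (any(!is.finite(values)))
    stop_data("time-series values contain non-finite entries")
  if (length(region_labels) != nrow(values))
    stop_data("region_labels length (%d) != number of rows (%d)",
              length(region_labels), nrow(values))
  if (!is.numeric(sampling_interval) || sampling_interval <= 0)
    stop_data("sampling_interval must be positive")
  if (!is.list(blocks) || length(blocks) < 1)
    stop_data("blocks must be a non-empty list of c(start, end)")
  bm <- do.call(rbind, lapply(blocks, as.numeric))
  if (ncol(bm) != 2 || any(bm[, 1] >= bm[, 2]))
    stop_data("each block must be c(start, end) with start < end")
  if (any(bm < 0) || any(bm > ncol(values)))
    stop_data("block boundaries outside sample range [0, %d]", ncol(values))
  if (nrow(bm) > 1 && any(bm[-1, 1] < bm[-nrow(bm), 2]))
    stop_data("blocks overlap or are out of order")
  if (!is.null(block_types) && length(block_types) != length(blocks))
    stop_data("block_types length must match blocks")
  structure(list(values = values, region_labels = as.character(region_labels),
                 sampling_interval = sampling_interval,
                 blocks = lapply(seq_len(nrow(bm)),
                                 function(i) as.integer(bm[i, ])),
                 block_types = block_types),
            class = "dyncore_timeseries")
}

#' Multilayer weighted adjacency tensor container
#'
#' @param weights Numeric array `n_regions x n_regions x n_layers`; each
#'   layer symmetric with zero diagonal, weights in `[0, 1]`.
#' @param region_labels Character region names.
#' @param layer_labels Optional layer (block) labels.
#' @param meta Optional list of construction metadata (estimator
#'   parameters, wavelet family, scale, band).
#' @return An object of class `dyncore_tensor`.
#' @export
adjacency_tensor <- function(weights, region_labels = NULL,
                             layer_labels = NULL, meta = list()) {
  if (!is.array(weights) || length(dim(weights)) != 3)
    stop_data("weights must be a 3-d array (regions x regions x layers)")
  d <- dim(weights)
  if (d[1] != d[2]) stop_data("layers must be square (got %d x %d)",
                              d[1], d[2])
  if (any(!is.finite(weights)))
    stop_data("tensor contains non-finite weights")
  if (min(weights) < 0 || max(weights) > 1)
    stop_data("weights must lie in [0, 1]")
  for (l in seq_len(d[3])) {
    check_square_symmetric(weights[, , l], sprintf("layer %d", l))
    if (any(diag(weights[, , l]) != 0))
      stop_data("layer %d has a nonzero diagonal", l)
  }
  if (is.null(region_labels)) region_labels <- region_names(d[1])
  if (length(region_labels) != d[1])
    stop_data("region_labels length mismatch")
  if (is.null(layer_labels)) layer_labels <- sprintf("layer_%03d",
                                                     seq_len(d[3]))
  structure(list(weights = weights,
                 region_labels = as.character(region_labels),
                 layer_labels = as.character(layer_labels), meta = meta),
            class = "dyncore_tensor")
}

n_layers <- function(tensor) dim(tensor$weights)[3]
n_regions_of <- function(tensor) dim(tensor$weights)[1]

# --- MODWT -----------------------------------------------------------------

# Daubechies scaling filters (orthonormal, sum = sqrt(2)).
dwt_filters <- function(family) {
  g <- switch(family,
    haar = c(1, 1) / sqrt(2),
    d4 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    stop_config("unknown wavelet family '%s' (available: haar, d4)", family))
  L <- length(g)
  h <- rev(g) * (-1)^(seq_len(L) - 1)  # quadrature mirror filter
  list(g = g, h = h)
}

# Circular MODWT pyramid; returns list(W = wavelet coeffs at `scale`,
# V = scaling coeffs).  Filters are the DWT filters divided by sqrt(2),
# upsampled by 2^(j-1) at level j (a trous).
modwt_circular <- function(x, scale, family) {
  f <- dwt_filters(family)
  gt <- f$g / sqrt(2)
  ht <- f$h / sqrt(2)
  n <- length(x)
  v <- x
  w <- NULL
  for (j in seq_len(scale)) {
    step <- 2^(j - 1)
    wj <- numeric(n)
    vj <- numeric(n)
    idx <- seq_len(n)
    for (l in seq_along(gt)) {
      src <- ((idx - 1 - (l - 1) * step) %% n) + 1
      wj <- wj + ht[l] * v[src]
      vj <- vj + gt[l] * v[src]
    }
    w <- wj
    v <- vj
  }
  list(W = w, V = v)
}

#' Undecimated wavelet coefficients of one series at one scale
#'
#' Maximal-overlap discrete wavelet transform (MODWT) coefficients,
#' length-preserving, with reflection boundary handling: the series is
#' extended to twice its length by reflection, transformed circularly, and
#' the first half of the coefficients is returned.
#'
#' @param series Numeric vector of finite values.
#' @param scale Wavelet scale index `j >= 1`; at sampling interval `dt`
#'   scale `j` isolates the dyadic band
#'   `[1/(2^(j+1) dt), 1/(2^j dt)]` Hz.
#' @param family Wavelet family: `"d4"` (4-tap Daubechies, default) or
#'   `"haar"`.
#' @return Numeric vector of wavelet coefficients, same length as input.
#' @export
modwt_scale <- function(series, scale = 2L, family = "d4") {
  scale <- assert_count(scale, "scale", 1L)
  if (any(!is.finite(series)))
    stop_data("series contains non-finite values")
  f <- dwt_filters(family)
  support <- (2^scale - 1) * (length(f$g) - 1) + 1
  if (length(series) < support)
    stop_data("series length %d below the scale-%d filter support %d",
              length(series), scale, support)
  ext <- c(series, rev(series))
  modwt_circular(ext, scale, family)$W[seq_along(series)]
}

#' Nominal frequency band of a wavelet scale
#'
#' @param scale Scale index `j`.
#' @param sampling_interval Sampling interval in seconds.
#' @return `c(f_low, f_high)` in Hz: `[Nyquist/2^j, Nyquist/2^(j-1)]`.
#' @export
wavelet_band <- function(scale, sampling_interval) {
  scale <- assert_count(scale, "scale", 1L)
  nyq <- 1 / (2 * sampling_interval)
  c(nyq / 2^scale, nyq / 2^(scale - 1))
}

# --- Welch coherence -------------------------------------------------------

default_estimator <- function() {
  list(segment_length = 32L, overlap = 0.5, window = "hann")
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

# Per-segment FFTs of a matrix of series (rows = series).  Returns a list
# with the complex array (series x freq x segment) and the frequency grid.
welch_segments <- function(x, dt, params) {
  seg <- assert_count(params$segment_length %||% 32L, "segment_length", 4L)
  ov <- params$overlap %||% 0.5
  assert_prob(ov, "overlap")
  if (ov >= 1) stop_config("overlap must be < 1")
  n <- ncol(x)
  if (n < seg)
    stop_data("window of %d samples is shorter than segment_length %d",
              n, seg)
  step <- max(1L, as.integer(round(seg * (1 - ov))))
  starts <- seq(1L, n - seg + 1L, by = step)
  if (length(starts) < 2)
    stop_data(
      "window of %d samples gives %d Welch segment(s); at least 2 required",
      n, length(starts))
  w <- switch(params$window %||% "hann",
              hann = hann_window(seg),
              rectangular = rep(1, seg),
              stop_config("unknown window '%s'", params$window))
  nf <- seg %/% 2 + 1
  S <- array(0i, c(nrow(x), nf, length(starts)))
  for (k in seq_along(starts)) {
    segm <- x[, starts[k] + seq_len(seg) - 1L, drop = FALSE]
    segm <- segm - rowMeans(segm)
    segm <- sweep(segm, 2, w, "*")
    F <- t(apply(segm, 1, fft))[, seq_len(nf), drop = FALSE]
    S[, , k] <- F
  }
  list(fft = S, freqs = (seq_len(nf) - 1) / (seg * dt))
}

#' Band-averaged magnitude-squared coherence of two series
#'
#' Welch estimator: both series are cut into tapered, overlapping segments;
#' auto- and cross-spectra are averaged over segments; the magnitude-squared
#' coherence `|Sxy|^2 / (Sxx Syy)` is then averaged over the frequency bins
#' inside `band`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param band `c(f_low, f_high)` in Hz.
#' @param sampling_interval Sampling interval in seconds.
#' @param params Estimator parameters: `segment_length` (samples, default
#'   32), `overlap` (fraction in `[0, 1)`, default 0.5), `window`
#'   (`"hann"` or `"rectangular"`).
#' @return Coherence value in `[0, 1]`.
#' @export
band_coherence <- function(x, y, band, sampling_interval = 2,
                           params = default_estimator()) {
  if (length(x) != length(y))
    stop_data("series lengths differ (%d vs %d)", length(x), length(y))
  ws <- welch_segments(rbind(x, y), sampling_interval, params)
  X <- ws$fft[1, , , drop = FALSE]
  Y <- ws$fft[2, , , drop = FALSE]
  sxx <- apply(abs(X)^2, 2, sum)
  syy <- apply(abs(Y)^2, 2, sum)
  sxy <- apply(X * Conj(Y), 2, sum)
  coh <- Mod(sxy)^2 / (sxx * syy)
  sel <- ws$freqs >= band[1] & ws$freqs <= band[2]
  if (!any(sel))
    stop_data("no frequency bins inside band [%g, %g] Hz", band[1], band[2])
  mean(coh[sel])
}

#' Build a multilayer functional network from windowed time series
#'
#' For each block, every region's series is wavelet-transformed at `scale`;
#' layer `l`'s entry `(i, j)` is the band-averaged magnitude-squared
#' coherence of the scale coefficients of regions `i` and `j` within block
#' `l`.  Layers are symmetric with zero diagonal.
#'
#' @param ts A [timeseries_set()].
#' @param scale Wavelet scale (default 2; at 2 s sampling this is the
#'   0.0625-0.125 Hz band).
#' @param family Wavelet family passed to [modwt_scale()].
#' @param params Welch estimator parameters, see [band_coherence()].
#' @return A `dyncore_tensor` with construction metadata in `$meta`.
#' @export
build_tensor <- function(ts, scale = 2L, family = "d4",
                         params = default_estimator()) {
  stopifnot(inherits(ts, "dyncore_timeseries"))
  if (length(ts$blocks) < 2)
    stop_data("at least 2 blocks are required (got %d)", length(ts$blocks))
  n <- nrow(ts$values)
  L <- length(ts$blocks)
  dt <- ts$sampling_interval
  band <- wavelet_band(scale, dt)
  weights <- array(0, c(n, n, L))
  for (l in seq_len(L)) {
    b <- ts$blocks[[l]]
    block <- ts$values[, (b[1] + 1):b[2], drop = FALSE]
    wc <- t(apply(block, 1, modwt_scale, scale = scale, family = family))
    ws <- welch_segments(wc, dt, params)
    sel <- ws$freqs >= band[1] & ws$freqs <= band[2]
    F <- ws$fft[, sel, , drop = FALSE]
    auto <- apply(abs(F)^2, c(1, 2), sum)  # region x freq
    nb <- sum(sel)
    lay <- matrix(0, n, n)
    for (f in seq_len(nb)) {
      Cf <- matrix(F[, f, ], nrow = n)        # region x segment
      S <- Cf %*% Conj(t(Cf))                 # cross-spectra, segment-summed
      lay <- lay + Mod(S)^2 / outer(auto[, f], auto[, f])
    }
    lay <- lay / nb
    diag(lay) <- 0
    if (any(!is.finite(lay))) {
      bad <- which(!is.finite(lay), arr.ind = TRUE)[1, ]
      stop_numeric("non-finite coherence for regions %s and %s in block %d",
                   ts$region_labels[bad[1]], ts$region_labels[bad[2]], l)
    }
    # clip tiny numerical overshoot above 1
    weights[, , l] <- pmin(pmax(lay, 0), 1)
  }
  adjacency_tensor(weights, region_labels = ts$region_labels,
                   layer_labels = ts$block_types %||%
                     sprintf("block_%03d", seq_len(L)),
                   meta = list(scale = scale, family = family, band = band,
                               estimator = params,
                               sampling_interval = dt))
}
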