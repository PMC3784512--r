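#' @useDynLib dyncore, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim quantile rnorm runif rbeta rexp sd var fft
#'   nextn pt qnorm median coef lm
NULL

# Internal error helpers: classed conditions so callers (and the CLI) can
# distinguish configuration, data and numerical failures.
stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("dyncore_config_error", "dyncore_error")))
}
stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("dyncore_data_error", "dyncore_error")))
}
stop_numeric <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("dyncore_numeric_error", "dyncore_error")))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_config("'%s' must lie in [0, 1] (got %s)", name,
                paste(format(x), collapse = ", "))
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min)
    stop_config("'%s' must be an integer >= %d", name, min)
  as.integer(x)
}

#' Derive a reproducible substream seed
#'
#' Expands one global integer seed into per-component substream seeds by a
#' fixed affine map modulo a Mersenne prime, so that components draw from
#' effectively independent streams while the whole run stays reproducible
#' from a single integer.
#'
#' @param seed Global integer seed.
#' @param offset Integer component offset (each component uses its own).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, offset = 0L) {
  seed <- as.double(assert_count(seed, "seed", min = 0L))
  offset <- as.double(assert_count(offset, "offset", min = 0L))
  # 48271 is a classic MINSTD multiplier; arithmetic stays exact in doubles
  as.integer((seed * 48271 + offset * 16807 + 12345) %% 2147483647)
}

check_square_symmetric <- function(A, name = "layer", tol = 1e-12) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop_data("'%s' must be a square matrix", name)
  if (any(!is.finite(A)))
    stop_data("'%s' contains non-finite entries", name)
  d <- max(abs(A - t(A)))
  if (d > tol)
    stop_data("'%s' is not symmetric (max |A - t(A)| = %g)", name, d)
  invisible(A)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items.
#' Used to score recovery of planted community structure.
#'
#' @param a,b Integer (or factor-like) label vectors of equal length.
#' @return Adjusted Rand index in `[-1, 1]`; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop_data("label vectors differ in length (%d vs %d)",
              length(a), length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}
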