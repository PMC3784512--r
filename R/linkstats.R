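# Flexibility-distribution moments, correlation machinery, and the
# linking analyses (flexibility moments vs. learning parameter;
# flexibility vs. geometrical core score).

#' Skewness and kurtosis of a sample
#'
#' Third and fourth standardized central moments.  Kurtosis is reported
#' non-excess, so a Gaussian sample tends to 3.  Population (1/n) central
#' moments are the default.
#'
#' @param values Numeric vector with at least 3 distinct values.
#' @param type `"population"` (1/n moments, default) or `"sample"`
#'   (bias-corrected skewness and kurtosis).
#' @return A list with `skewness` and `kurtosis`.
#' @export
moments <- function(values, type = c("population", "sample")) {
  type <- match.arg(type)
  x <- values[is.finite(values)]
  n <- length(x)
  if (length(unique(x)) < 3)
    stop_data("at least 3 distinct values are required")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop_data("degenerate distribution: zero variance")
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2
  if (type == "sample") {
    g1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
    g2 <- (n - 1) / ((n - 2) * (n - 3)) * ((n + 1) * (g2 - 3) + 6) + 3
  }
  list(skewness = g1, kurtosis = g2)
}

cor_result <- function(method, coefficient, p_value, n) {
  structure(list(method = method, coefficient = coefficient,
                 p_value = p_value, n = n), class = "dyncore_cor")
}

rank_avg <- function(x) rank(x, ties.method = "average")

# All permutations of 1..n by Heap's algorithm (n <= 9).
all_permutations <- function(n) {
  v <- seq_len(n)
  out <- vector("list", factorial(n))
  i <- 0L
  heap <- function(k) {
    if (k == 1L) {
      i <<- i + 1L
      out[[i]] <<- v
      return(invisible())
    }
    for (j in seq_len(k - 1L)) {
      heap(k - 1L)
      if (k %% 2L == 0L) {
        tmp <- v[j]; v[j] <<- v[k]; v[k] <<- tmp
      } else {
        tmp <- v[1L]; v[1L] <<- v[k]; v[k] <<- tmp
      }
    }
    heap(k - 1L)
  }
  heap(n)
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties.  The p-value is two-sided,
#' either by the t approximation (`p_method = "asymptotic"`) or by exact
#' enumeration over all `n!` orderings (`p_method = "exact"`, `n <= 9`).
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param p_method `"asymptotic"` or `"exact"`.
#' @return A `dyncore_cor` with `method`, `coefficient`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y, p_method = c("asymptotic", "exact")) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y))
    stop_data("x and y differ in length")
  n <- length(x)
  if (n < 4) stop_data("at least 4 pairs are required")
  if (sd(x) == 0 || sd(y) == 0)
    stop_data("correlation undefined for a constant vector")
  rx <- rank_avg(x)
  ry <- rank_avg(y)
  rho <- stats::cor(rx, ry)
  if (p_method == "exact") {
    if (n > 9) stop_config("exact permutation p is limited to n <= 9")
    perms <- all_permutations(n)
    null_rho <- vapply(perms, function(p) stats::cor(rx[p], ry),
                       numeric(1))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * pt(-abs(tstat), df = n - 2))
  }
  cor_result("spearman", rho, p, n)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return A `dyncore_cor` with the coefficient and a two-sided t-test
#'   p-value.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop_data("x and y differ in length")
  n <- length(x)
  if (n < 3) stop_data("at least 3 pairs are required")
  if (sd(x) == 0 || sd(y) == 0)
    stop_data("correlation undefined for a constant vector")
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- min(1, 2 * pt(-abs(tstat), df = n - 2))
  cor_result("pearson", r, p, n)
}

#' Correlate flexibility-distribution moments with learning rate
#'
#' Computes per-subject skewness and kurtosis of the subject's nodal
#' flexibility values over regions and rank-correlates each moment with
#' the per-subject learning parameter `kappa`.  In the designed use the
#' flexibility comes from session-1-equivalent data and `kappa` from
#' subsequent training, so the correlations are predictive.
#'
#' @param flexibility_by_subject List (one numeric vector of per-region
#'   flexibilities per subject) or a regions x subjects matrix.
#' @param kappa Numeric vector of per-subject learning parameters.
#' @param p_method Passed to [spearman_cor()].
#' @return A list with `skewness` and `kurtosis` (each a `dyncore_cor`
#'   against `kappa`) and `moments` (per-subject data frame).
#' @export
link_flexibility_learning <- function(flexibility_by_subject, kappa,
                                      p_method = "asymptotic") {
  if (is.matrix(flexibility_by_subject))
    flexibility_by_subject <- asplit(flexibility_by_subject, 2)
  if (length(flexibility_by_subject) != length(kappa))
    stop_data("subject counts differ (%d flexibility vectors, %d kappas)",
              length(flexibility_by_subject), length(kappa))
  if (length(kappa) < 4) stop_data("at least 4 subjects are required")
  mom <- lapply(seq_along(kappa), function(s)
    tryCatch(moments(flexibility_by_subject[[s]]),
             error = function(e) stop_data(
               "moment computation failed for subject %d: %s", s,
               conditionMessage(e))))
  sk <- vapply(mom, `[[`, numeric(1), "skewness")
  ku <- vapply(mom, `[[`, numeric(1), "kurtosis")
  list(skewness = spearman_cor(sk, kappa, p_method),
       kurtosis = spearman_cor(ku, kappa, p_method),
       moments = data.frame(subject = seq_along(kappa), skewness = sk,
                            kurtosis = ku, kappa = kappa))
}

#' Correlate nodal flexibility with geometrical core score
#'
#' Pearson correlation across regions between mean nodal flexibility and
#' mean geometrical core score.  A negative coefficient indicates that
#' temporally stiff regions are also densely connected core regions.
#'
#' @param flexibility_per_region,core_score_per_region Numeric vectors on
#'   the same region set.
#' @return A `dyncore_cor`.
#' @export
link_flexibility_corescore <- function(flexibility_per_region,
                                       core_score_per_region) {
  if (length(flexibility_per_region) != length(core_score_per_region))
    stop_data("region sets differ in size")
  pearson_cor(flexibility_per_region, core_score_per_region)
}
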