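# Behavioral estimates of learning: movement-time extraction, robust
# exponential learning-curve fitting, and training-design arithmetic.

#' Movement time of one trial
#'
#' @param first_press,last_press Times of the first and last key press in
#'   seconds.
#' @return `last_press - first_press` in seconds.  A zero difference
#'   (single-press artifact) is returned with a warning.
#' @export
movement_time <- function(first_press, last_press) {
  if (any(last_press < first_press))
    stop_data("last_press precedes first_press")
  mt <- last_press - first_press
  if (any(mt == 0))
    warning("zero movement time: degenerate single-press trial")
  mt
}

#' Cumulative practiced trials by sequence type and scanning session
#'
#' Design arithmetic of the training protocol: each scanning session
#' contributes `scan_trials` trials per sequence, and each of the
#' `home_sessions` home-training sessions between scans contributes the
#' per-session trial counts by type (extensively / moderately / minimally
#' trained).  The entry for session `s` is the number of trials of that
#' type completed after scanning session `s`.
#'
#' @param n_sessions Number of scanning sessions.
#' @param scan_trials Trials per sequence in each scanning session.
#' @param home_trials Named per-home-session trials:
#'   `c(EXT = 64, MOD = 10, MIN = 1)`.
#' @param home_sessions Home sessions between consecutive scans.
#' @return Integer matrix, rows = sequence types, columns = sessions.
#' @export
cumulative_trials <- function(n_sessions = 4L, scan_trials = 50L,
                              home_trials = c(EXT = 64L, MOD = 10L,
                                              MIN = 1L),
                              home_sessions = 10L) {
  n_sessions <- assert_count(n_sessions, "n_sessions", 1L)
  out <- sapply(seq_len(n_sessions), function(s)
    s * scan_trials + (s - 1) * home_sessions * home_trials)
  dimnames(out) <- list(names(home_trials),
                        sprintf("Session %d", seq_len(n_sessions)))
  out
}

exp_curve <- function(par, t) {
  # par = (log A, kappa, log B); positivity of A and B by construction
  exp(par[1]) * exp(par[2] * t) + exp(par[3])
}

fit_loss <- function(par, t, mt, loss) {
  r <- mt - exp_curve(par, t)
  if (loss == "lar") sum(abs(r)) else sum(r^2)
}

# Deterministic multi-start grid on kappa around a log-linear initial
# estimate: B0 just below the late-trial floor, A0 from the early trials,
# kappa0 from a linear fit of log(MT - B0).
fit_starts <- function(t, mt) {
  b0 <- max(min(mt) * 0.9, 1e-3)
  pos <- pmax(mt - b0, 1e-6)
  k0 <- unname(coef(lm(log(pos) ~ t))[2])
  if (!is.finite(k0)) k0 <- -0.01
  a0 <- max(mean(mt[seq_len(max(3, length(mt) %/% 10))]) - b0, 1e-3)
  kgrid <- unique(c(k0, k0 * c(0.25, 0.5, 2, 4), -0.001, -0.05, -0.2))
  kgrid <- kgrid[seq_len(min(8, length(kgrid)))]
  lapply(kgrid, function(k) c(log(a0), k, log(b0)))
}

#' Fit an exponential learning curve to movement times
#'
#' Fits `MT(t) = A exp(kappa t) + B` with `A, B > 0` by minimizing either
#' the sum of absolute residuals (`loss = "lar"`, the robust default) or
#' the sum of squared residuals (`loss = "ls"`), using derivative-free
#' Nelder-Mead local search from 8 deterministic starts seeded by a
#' log-linear initial estimate.  A negative fitted `kappa` indicates
#' decreasing movement time, i.e. learning.
#'
#' @param trials A TrialTable `data.frame` with columns `trial` and `MT_s`
#'   (or a numeric vector of movement times, taken at trials `1..n`).
#' @param loss `"lar"` (least absolute residuals) or `"ls"`.
#' @param time_axis `"trial"` fits against the trial index (default);
#'   `"clock"` fits against a `time_s` column if present.
#' @param maxit Iteration cap per local search.
#' @return An object of class `dyncore_fit`: `kappa`, `A`, `B`, `loss`
#'   (the achieved objective), `loss_type`, `converged`, `degenerate`
#'   (flag for near-constant data).
#' @export
fit_learning_curve <- function(trials, loss = c("lar", "ls"),
                               time_axis = c("trial", "clock"),
                               maxit = 800L) {
  loss <- match.arg(loss)
  time_axis <- match.arg(time_axis)
  if (is.numeric(trials))
    trials <- data.frame(trial = seq_along(trials), MT_s = trials)
  if (!all(c("trial", "MT_s") %in% names(trials)))
    stop_data("trials must have columns 'trial' and 'MT_s'")
  mt <- trials$MT_s
  if (any(mt <= 0)) stop_data("movement times must be positive")
  if (length(mt) < 4)
    stop_data("at least 4 trials are required (got %d)", length(mt))
  t <- if (time_axis == "clock" && !is.null(trials$time_s))
    trials$time_s else trials$trial
  if (any(diff(order(t)) < 0)) t <- sort(t)
  best <- NULL
  any_conv <- FALSE
  for (p0 in fit_starts(t, mt)) {
    res <- tryCatch(
      optim(p0, fit_loss, t = t, mt = mt, loss = loss,
            method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop_numeric("learning-curve fit failed from every start")
  A <- exp(best$par[1])
  B <- exp(best$par[3])
  kappa <- best$par[2]
  degenerate <- sd(mt) < 1e-8 || A < 1e-6 * B || abs(kappa) < 1e-8
  structure(list(kappa = kappa, A = A, B = B, loss = best$value,
                 loss_type = loss, converged = any_conv,
                 degenerate = degenerate, n_trials = length(mt)),
            class = "dyncore_fit")
}

#' Per-subject learning parameters for a cohort
#'
#' Fits each subject's trial table (per sequence, then averages `kappa`
#' over sequences) and returns the per-subject learning parameters.
#'
#' @param trial_tables List of TrialTable `data.frame`s, one per subject.
#' @param ... Passed to [fit_learning_curve()].
#' @return Numeric vector of per-subject `kappa` values.
#' @export
fit_cohort_kappa <- function(trial_tables, ...) {
  vapply(trial_tables, function(tab) {
    ks <- vapply(split(tab, tab$sequence), function(seq_tab)
      fit_learning_curve(seq_tab, ...)$kappa, numeric(1))
    mean(ks)
  }, numeric(1))
}
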