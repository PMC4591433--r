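# Discriminating statistics and rejection rules for surrogate-data
# nonlinearity testing.

#' Time reversal asymmetry statistic
#'
#' The cubed-increment ratio
#' \deqn{\lambda = \frac{\langle (x_i - x_{i-\tau})^3 \rangle}
#'                      {\langle (x_i - x_{i-\tau})^2 \rangle}}
#' averaged over all valid `i`. A reversible (e.g. linear Gaussian) process
#' has increments with a symmetric distribution, so the statistic is near
#' zero; time irreversibility is a strong signature of nonlinearity.
#'
#' @param series An [lfp_ts()] or numeric vector.
#' @param delay Increment delay in samples (default 1).
#' @return A single real number.
#' @export
time_reversal_asymmetry <- function(series, delay = 1) {
  x <- ts_values(series)
  delay <- as.integer(delay)
  if (delay < 1L) stop("`delay` must be >= 1")
  n <- length(x)
  if (n <= delay) stop("series shorter than the delay")
  d <- x[(1L + delay):n] - x[1:(n - delay)]
  denom <- mean(d^2)
  if (denom == 0) stop("constant series: statistic undefined")
  mean(d^3) / denom
}

#' Average-discrepancy score for a surrogate test
#'
#' `gamma = |mean(lambdas) / lambda0 - 1|`: the relative discrepancy
#' between the surrogate mean and the original statistic. A score above 1
#' indicates that the original and the surrogates differ significantly.
#'
#' @param lambda0 Statistic of the original series (nonzero).
#' @param lambdas Statistics of the surrogates.
#' @return A non-negative number.
#' @export
gamma_avg <- function(lambda0, lambdas) {
  if (lambda0 == 0) stop("`lambda0` must be nonzero for the average score")
  abs(mean(lambdas) / lambda0 - 1)
}

#' Coefficient-of-variation score (Z-score) for a surrogate test
#'
#' `gamma = |mean(lambdas) - lambda0| / sd(lambdas)`. When the surrogate
#' statistics are roughly normal, the null hypothesis is rejected at the
#' 95% level for a score above 1.96.
#'
#' @param lambda0 Statistic of the original series.
#' @param lambdas Statistics of the surrogates (at least 2, with positive
#'   spread).
#' @return A non-negative number.
#' @export
gamma_cv <- function(lambda0, lambdas) {
  if (length(lambdas) < 2L) stop("need at least 2 surrogate statistics")
  s <- sd(lambdas)
  if (!is.finite(s) || s == 0)
    stop("zero spread of the surrogate statistics")
  abs(mean(lambdas) - lambda0) / s
}

#' Rank-ordering test
#'
#' Position of the original statistic in the ascending sort of the pooled
#' values; the null hypothesis is rejected only when the original is a
#' strict extreme (strictly below all surrogates or strictly above all of
#' them). When the original ties one or more surrogates, its rank is the
#' nearer extreme of the tie block, but a tie at an extreme does not count
#' as a rejection (the conservative reading).
#'
#' @param lambda0 Statistic of the original series.
#' @param lambdas Surrogate statistics (at least 1).
#' @return List with `rank` (in `1..n+1`) and `reject` (logical).
#' @export
rank_test <- function(lambda0, lambdas) {
  n <- length(lambdas)
  if (n < 1L) stop("need at least 1 surrogate statistic")
  rank_low <- 1L + sum(lambdas < lambda0)
  rank_high <- 1L + sum(lambdas <= lambda0)
  rank <- if ((rank_low - 1L) <= (n + 1L - rank_high)) rank_low else rank_high
  list(rank = as.integer(rank),
       reject = all(lambdas > lambda0) || all(lambdas < lambda0))
}

#' Surrogate-data nonlinearity test with a scalar statistic
#'
#' Runs the full test for one trial: generates (or reuses) a surrogate set,
#' evaluates the time-reversal asymmetry statistic on the original and on
#' every surrogate, and applies all three rejection rules (average score,
#' coefficient-of-variation score at `threshold`, rank ordering).
#'
#' @param series An [lfp_ts()] or numeric vector.
#' @param n Number of surrogates (ignored when `surrogates` is given).
#' @param method Surrogate method, see [make_surrogates()].
#' @param delay Delay of [time_reversal_asymmetry()].
#' @param threshold Rejection threshold for the CV score (default 1.96, the
#'   two-sided 95% normal critical value).
#' @param seed Optional RNG seed for the surrogate generation.
#' @param surrogates Optional pre-built [make_surrogates()] result.
#' @return Object of class `discrimination_result`: `lambda0`, `lambdas`,
#'   `gamma_avg`, `gamma_cv`, `rank`, `reject_cv`, `reject_rank`,
#'   `threshold`, `method`.
#' @export
surrogate_test <- function(series, n = 100, method = c("iaaft", "ft", "aaft"),
                           delay = 1, threshold = 1.96, seed = NULL,
                           surrogates = NULL) {
  if (is.null(surrogates)) {
    method <- match.arg(method)
    surrogates <- make_surrogates(series, n = n, method = method, seed = seed)
  } else {
    stopifnot(inherits(surrogates, "surrogate_set"))
    method <- surrogates$method
  }
  lambda0 <- time_reversal_asymmetry(series, delay = delay)
  lambdas <- vapply(surrogates$surrogates, time_reversal_asymmetry,
                    numeric(1), delay = delay)
  g_avg <- if (lambda0 != 0) gamma_avg(lambda0, lambdas) else NA_real_
  g_cv <- gamma_cv(lambda0, lambdas)
  rt <- rank_test(lambda0, lambdas)
  structure(list(lambda0 = lambda0, lambdas = lambdas,
                 gamma_avg = g_avg, gamma_cv = g_cv,
                 rank = rt$rank, reject_cv = g_cv > threshold,
                 reject_rank = rt$reject, threshold = threshold,
                 method = method, delay = delay),
            class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf(
    "<discrimination_result> lambda0 = %.4g vs %d %s surrogates\n",
    x$lambda0, length(x$lambdas), x$method))
  cat(sprintf("  gamma_avg = %.4g, gamma_cv = %.4g (threshold %.3g)\n",
              x$gamma_avg, x$gamma_cv, x$threshold))
  cat(sprintf("  rank %d/%d; reject (cv) = %s; reject (rank) = %s\n",
              x$rank, length(x$lambdas) + 1L,
              x$reject_cv, x$reject_rank))
  invisible(x)
}

#' FNN-based surrogate discrimination
#'
#' Uses the false-nearest-neighbour fraction as the discriminating
#' statistic: the FNN percentage is computed per embedding dimension for
#' the original series and for every surrogate, and the null hypothesis is
#' rejected when the original's fraction lies strictly below the surrogate
#' minimum at every tested dimension. Deterministic structure unfolds at a
#' low dimension while its phase-randomized surrogates do not, so the
#' original curve separates from the surrogate envelope.
#'
#' @param series An [lfp_ts()] or numeric vector.
#' @param surrogates A [make_surrogates()] result for the same series.
#' @param lag,dims,f_ratio,theiler,... Passed to [fnn_fraction()].
#' @return List of class `fnn_discrimination`: `dims`, `original`
#'   (fractions per dimension), `surrogate` (matrix, one row per
#'   surrogate), `reject`.
#' @export
fnn_discrimination <- function(series, surrogates, lag, dims = 1:5,
                               f_ratio = 10, theiler = 0, ...) {
  stopifnot(inherits(surrogates, "surrogate_set"))
  orig <- fnn_fraction(series, lag = lag, dims = dims, f_ratio = f_ratio,
                       theiler = theiler, ...)$fraction
  surr <- t(vapply(surrogates$surrogates, function(s) {
    fnn_fraction(s, lag = lag, dims = dims, f_ratio = f_ratio,
                 theiler = theiler, ...)$fraction
  }, numeric(length(dims))))
  env_min <- apply(surr, 2, min, na.rm = TRUE)
  reject <- all(!is.na(orig) & orig < env_min)
  structure(list(dims = sort(as.integer(dims)), original = orig,
                 surrogate = surr, envelope_min = env_min,
                 reject = reject),
            class = "fnn_discrimination")
}

#' @export
print.fnn_discrimination <- function(x, ...) {
  cat(sprintf("<fnn_discrimination> %d surrogates, dims %s\n",
              nrow(x$surrogate), paste(x$dims, collapse = ",")))
  cat("  original: ", paste(sprintf("%.4f", x$original), collapse = " "), "\n")
  cat("  envelope: ", paste(sprintf("%.4f", x$envelope_min), collapse = " "),
      "\n")
  cat(sprintf("  reject = %s\n", x$reject))
  invisible(x)
}

#' Group-level nonlinearity verdicts
#'
#' Averages per-trial CV scores within dendrogram groups and applies the
#' rejection threshold to the group mean, mirroring group-aggregated
#' testing of trial ensembles.
#'
#' @param gamma_values Per-trial [gamma_cv()] scores.
#' @param labels Integer group label per trial.
#' @param threshold Rejection threshold (default 1.96).
#' @return Data frame with `group`, `n_trials`, `mean_gamma`, `reject`.
#' @export
group_gamma <- function(gamma_values, labels, threshold = 1.96) {
  stopifnot(length(gamma_values) == length(labels))
  groups <- sort(unique(labels))
  mg <- vapply(groups, function(g) mean(gamma_values[labels == g]),
               numeric(1))
  data.frame(group = groups,
             n_trials = as.integer(table(factor(labels, levels = groups))),
             mean_gamma = mg, reject = mg > threshold)
}
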