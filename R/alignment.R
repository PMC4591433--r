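# Correction of stimulus-induced phase resetting by circular shifting.

#' Circularly shift a series
#'
#' Sample `i` (0-based) of the output is sample `(i - k) mod N` of the
#' input, so a positive `k` moves the waveform to the right. The multiset
#' of values is preserved and shifts compose additively.
#'
#' @param series An [lfp_ts()] or numeric vector.
#' @param k Integer shift in samples (any sign).
#' @return Same flavour as the input.
#' @export
circular_shift <- function(series, k) {
  x <- ts_values(series)
  n <- length(x)
  k <- as.integer(round(k)) %% n
  if (k == 0L) return(ts_like(x, series))
  idx <- ((seq_len(n) - 1L - k) %% n) + 1L
  ts_like(x[idx], series)
}

# Map a 0-based circular shift to the signed convention (-N/2, N/2].
signed_shift <- function(k, n) {
  k <- k %% n
  ifelse(k > n / 2, k - n, k)
}

#' Optimal circular shift of a trial against a reference
#'
#' Finds the integer circular shift `k*` of `trial` that maximizes the
#' Pearson correlation with `reference` over all `N` possible shifts, via
#' FFT cross-correlation of the mean-centred signals (exactly equivalent to
#' exhaustive search). Ties are broken by the smallest `|k|`, then by the
#' positive `k`. Shifts are reported in `(-N/2, N/2]`, so a recovered shift
#' can be read directly as a signed permanent phase shift.
#'
#' @param trial,reference Equal-length [lfp_ts()] objects or numeric
#'   vectors; both must be non-constant.
#' @return List with `shift` (samples) and `corr` (the maximized Pearson
#'   correlation).
#' @export
best_shift <- function(trial, reference) {
  a <- ts_values(reference)
  b <- ts_values(trial)
  n <- length(a)
  if (length(b) != n) stop("trial and reference must have the same length")
  corr <- shift_correlations(b, a)
  m <- max(corr)
  tol <- 1e-9 * max(1, abs(m))
  cand <- which(corr >= m - tol) - 1L        # 0-based shifts
  ks <- signed_shift(cand, n)
  ord <- order(abs(ks), ks <= 0)             # smallest |k|, positive first
  k_star <- ks[ord[1]]
  list(shift = as.integer(k_star), corr = corr[(k_star %% n) + 1L])
}

# Pearson correlation between `reference` and circular_shift(trial, k) for
# every k = 0..N-1, computed with one FFT cross-correlation.
shift_correlations <- function(trial, reference) {
  a <- reference - mean(reference)
  b <- trial - mean(trial)
  sa <- sqrt(sum(a^2)); sb <- sqrt(sum(b^2))
  if (sa == 0 || sb == 0) stop("constant series: correlation undefined")
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE)) / length(a)
  cc / (sa * sb)
}

#' Root-mean-square error between two traces
#'
#' @param a,b Equal-length [lfp_ts()] objects or numeric vectors.
#' @param normalized If `TRUE` (default) return
#'   `sqrt(mean((a - b)^2))`; if `FALSE`, the plain Euclidean norm
#'   `sqrt(sum((a - b)^2))`.
#' @return A single non-negative number.
#' @export
rms_error <- function(a, b, normalized = TRUE) {
  x <- ts_values(a); y <- ts_values(b)
  if (length(x) != length(y)) stop("series must have the same length")
  ss <- sum((x - y)^2)
  if (normalized) sqrt(ss / length(x)) else sqrt(ss)
}

# First local maximum of the periodic autocorrelation after its first zero
# crossing: a robust estimate of the dominant period in samples.
dominant_period <- function(values) {
  n <- length(values)
  ac <- periodic_acf(values, max_lag = n - 1)
  zero <- which(ac <= 0)[1]
  if (is.na(zero)) return(NA_real_)
  seg <- ac[zero:length(ac)]
  d <- diff(seg)
  up_down <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (length(up_down) == 0L) return(NA_real_)
  (zero - 1L) + up_down[1] - 1L
}

#' Align an ensemble to a reference trial
#'
#' Circularly shifts every trial to maximize its correlation with a
#' reference trial, correcting for the trial-specific permanent phase shift
#' left by the stimulus. Trials are not rescaled or z-scored: amplitude
#' differences between trials are meaningful and are used later for
#' grouping.
#'
#' @param ensemble An [lfp_ensemble()] of steady (transient-free) trials.
#' @param reference `"first"` (default), `"medoid"` (the trial minimizing
#'   the summed rms error to all others), or a trial id.
#' @param normalized_rms Passed to [rms_error()].
#' @return List of class `alignment_result` with
#'   * `ensemble`: the shifted ensemble;
#'   * `result`: per-trial data frame (`trial_id`, `shift_samples`,
#'     `shift_cycles`, `corr_before`, `corr_after`, `rms_before`,
#'     `rms_after`);
#'   * `reference_id`, `period_samples` (dominant period of the reference,
#'     used to express shifts in cycles), and `summary` (mean and sd of
#'     each metric).
#' @export
align_ensemble <- function(ensemble, reference = "first",
                           normalized_rms = TRUE) {
  stopifnot(inherits(ensemble, "lfp_ensemble"))
  n_tr <- length(ensemble$trials)
  if (n_tr < 2L) stop("alignment needs at least 2 trials")
  ref_idx <- switch(reference,
    first = 1L,
    medoid = {
      m <- ensemble_matrix(ensemble)
      dd <- as.matrix(dist(m))
      which.min(rowSums(dd))
    },
    {
      idx <- match(reference, ensemble$trial_ids)
      if (is.na(idx)) stop("reference trial id not found: ", reference)
      idx
    })
  ref <- ensemble$trials[[ref_idx]]
  shifted <- vector("list", n_tr)
  shift_samples <- integer(n_tr)
  corr_before <- corr_after <- rms_before <- rms_after <- numeric(n_tr)
  for (i in seq_len(n_tr)) {
    tr <- ensemble$trials[[i]]
    if (i == ref_idx) {
      bs <- list(shift = 0L, corr = 1)
    } else {
      bs <- best_shift(tr, ref)
    }
    shift_samples[i] <- bs$shift
    shifted[[i]] <- circular_shift(tr, bs$shift)
    corr_before[i] <- cor(tr$values, ref$values)
    corr_after[i] <- bs$corr
    rms_before[i] <- rms_error(tr, ref, normalized = normalized_rms)
    rms_after[i] <- rms_error(shifted[[i]], ref, normalized = normalized_rms)
  }
  period <- dominant_period(ref$values)
  res <- data.frame(trial_id = ensemble$trial_ids,
                    shift_samples = shift_samples,
                    shift_cycles = if (is.na(period) || period <= 0)
                      NA_real_ else shift_samples / period,
                    corr_before = corr_before, corr_after = corr_after,
                    rms_before = rms_before, rms_after = rms_after,
                    stringsAsFactors = FALSE)
  summ <- data.frame(
    metric = c("corr_before", "corr_after", "rms_before", "rms_after"),
    mean = c(mean(corr_before), mean(corr_after),
             mean(rms_before), mean(rms_after)),
    sd = c(sd(corr_before), sd(corr_after), sd(rms_before), sd(rms_after)))
  structure(list(ensemble = lfp_ensemble(shifted, ensemble$trial_ids),
                 result = res, reference_id = ensemble$trial_ids[ref_idx],
                 period_samples = period, summary = summ),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %d trials, reference '%s'\n",
              nrow(x$result), x$reference_id))
  cat(sprintf("  correlation: %.4f +/- %.4f -> %.4f +/- %.4f\n",
              x$summary$mean[1], x$summary$sd[1],
              x$summary$mean[2], x$summary$sd[2]))
  cat(sprintf("  rms error:   %.4f +/- %.4f -> %.4f +/- %.4f\n",
              x$summary$mean[3], x$summary$sd[3],
              x$summary$mean[4], x$summary$sd[4]))
  invisible(x)
}
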