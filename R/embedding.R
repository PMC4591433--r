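# Delay-embedding parameter selection: lag time (autocorrelation first
# zero, AMI first minimum), embedding dimension (false nearest neighbours),
# and delay-vector construction.

# Circular (periodic-continuation) autocorrelation via FFT; exact for a
# sinusoid whose period divides the series length.
periodic_acf <- function(x, max_lag) {
  n <- length(x)
  xc <- x - mean(x)
  if (sum(xc^2) == 0) stop("constant series: autocorrelation undefined")
  r <- Re(fft(fft(xc) * Conj(fft(xc)), inverse = TRUE)) / n
  (r / r[1])[seq_len(max_lag + 1L)]
}

#' Autocorrelation curve of a series
#'
#' @param series An [lfp_ts()] or numeric vector.
#' @param max_lag Largest lag in samples (`< N`).
#' @param mode `"periodic"` treats the series as circular (the convention
#'   used throughout this package, matching periodic continuation of the
#'   data); `"linear"` uses the standard biased estimator.
#' @return Data frame with columns `lag` (0..`max_lag`, samples) and
#'   `value`; `value[lag == 0]` is 1.
#' @export
autocorrelation <- function(series, max_lag,
                            mode = c("periodic", "linear")) {
  mode <- match.arg(mode)
  x <- ts_values(series)
  if (max_lag >= length(x)) stop("`max_lag` must be smaller than the length")
  if (sd(x) == 0) stop("constant series: autocorrelation undefined")
  v <- if (mode == "periodic") {
    periodic_acf(x, max_lag)
  } else {
    as.numeric(acf(x, lag.max = max_lag, type = "correlation",
                   demean = TRUE, plot = FALSE)$acf)
  }
  data.frame(lag = 0:max_lag, value = v)
}

#' First zero crossing of an autocorrelation curve
#'
#' @param curve Data frame `lag`/`value` from [autocorrelation()].
#' @return Integer lag of the first non-positive value. The linearly
#'   interpolated crossing is attached as attribute `interpolated`.
#' @export
first_zero_lag <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("lag", "value") %in% names(curve)))
  if (abs(curve$value[1] - 1) > 1e-8)
    stop("curve must start at 1 (lag 0)")
  # tolerance absorbs rounding when a curve touches zero exactly
  idx <- which(curve$value <= 1e-12)[1]
  if (is.na(idx))
    stop("no zero crossing within max_lag; recompute with a larger max_lag")
  k <- curve$lag[idx]
  interp <- if (idx > 1L) {
    v0 <- curve$value[idx - 1L]; v1 <- curve$value[idx]
    curve$lag[idx - 1L] + v0 / (v0 - v1)
  } else k
  structure(as.integer(k), interpolated = interp)
}

#' Average mutual information curve
#'
#' For each lag `k`, the mutual information (in nats) between `x_t` and
#' `x_(t+k)`, estimated from the equal-width 2-D histogram of the pairs:
#' `I(k) = sum_ij p_ij log(p_ij / (p_i q_j))`. Bin edges span the observed
#' range of the whole series and are shared across lags.
#'
#' @param series An [lfp_ts()] or numeric vector.
#' @param max_lag Largest lag in samples (`< N`).
#' @param n_bins Number of equal-width bins per axis (default 16).
#' @return Data frame with columns `lag` (0..`max_lag`) and `value` (nats,
#'   non-negative). `value[lag == 0]` equals the histogram entropy of the
#'   series.
#' @export
average_mutual_information <- function(series, max_lag, n_bins = 16) {
  x <- ts_values(series)
  n <- length(x)
  if (n_bins < 2) stop("`n_bins` must be >= 2")
  if (max_lag >= n) stop("`max_lag` must be smaller than the length")
  rng <- range(x)
  if (rng[1] == rng[2]) stop("constant series: AMI undefined")
  bin <- pmin(n_bins, floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L)
  vals <- vapply(0:max_lag, function(k) {
    bi <- bin[seq_len(n - k)]
    bj <- bin[(1L + k):n]
    joint <- tabulate(bi + n_bins * (bj - 1L), nbins = n_bins * n_bins)
    npair <- n - k
    p <- joint / npair
    pi_ <- tabulate(bi, nbins = n_bins) / npair
    qj <- tabulate(bj, nbins = n_bins) / npair
    jm <- matrix(p, n_bins, n_bins)
    pos <- which(jm > 0, arr.ind = TRUE)
    sum(jm[pos] * log(jm[pos] / (pi_[pos[, 1]] * qj[pos[, 2]])))
  }, numeric(1))
  data.frame(lag = 0:max_lag, value = pmax(vals, 0))
}

#' First local minimum of a lag curve
#'
#' @param curve Data frame `lag`/`value`, e.g. from
#'   [average_mutual_information()].
#' @return Integer lag of the smallest `k >= 1` with
#'   `value(k) < value(k-1)` and `value(k) <= value(k+1)`.
#' @export
first_min_lag <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("lag", "value") %in% names(curve)))
  v <- curve$value
  if (length(v) < 3L) stop("curve too short to locate a local minimum")
  for (i in 2:(length(v) - 1L)) {
    if (v[i] < v[i - 1L] && v[i] <= v[i + 1L])
      return(as.integer(curve$lag[i]))
  }
  stop("no local minimum within max_lag; recompute with a larger max_lag")
}

#' Estimate the embedding lag of a series
#'
#' Computes both standard lag estimates -- the first zero of the (periodic)
#' autocorrelation and the first local minimum of the average mutual
#' information -- and selects the AMI minimum when it exists, falling back
#' on the autocorrelation zero otherwise.
#'
#' @param series An [lfp_ts()] or numeric vector.
#' @param max_lag Largest lag scanned (default `floor(N/2)`).
#' @param n_bins AMI histogram bins.
#' @return List of class `lag_estimate` with `acf_first_zero`,
#'   `ami_first_min` (either may be `NA` if the feature is absent),
#'   `chosen_lag`, and the two curves.
#' @export
estimate_lag <- function(series, max_lag = NULL, n_bins = 16) {
  x <- ts_values(series)
  if (is.null(max_lag)) max_lag <- floor(length(x) / 2)
  acf_curve <- autocorrelation(x, max_lag, mode = "periodic")
  ami_curve <- average_mutual_information(x, max_lag, n_bins = n_bins)
  acf_zero <- tryCatch(as.integer(first_zero_lag(acf_curve)),
                       error = function(e) NA_integer_)
  ami_min <- tryCatch(first_min_lag(ami_curve),
                      error = function(e) NA_integer_)
  chosen <- if (!is.na(ami_min)) ami_min else acf_zero
  if (is.na(chosen))
    stop("neither an ACF zero nor an AMI minimum found within max_lag")
  structure(list(acf_first_zero = acf_zero, ami_first_min = ami_min,
                 chosen_lag = chosen, acf_curve = acf_curve,
                 ami_curve = ami_curve),
            class = "lag_estimate")
}

#' @export
print.lag_estimate <- function(x, ...) {
  cat(sprintf(
    "<lag_estimate> ACF first zero: %s, AMI first minimum: %s, chosen: %d\n",
    x$acf_first_zero, x$ami_first_min, x$chosen_lag))
  invisible(x)
}

#' Delay-embed a series
#'
#' Point `k` (0-based) of the trajectory is
#' `(x_k, x_(k+lag), ..., x_(k+(dim-1)lag))`; there are
#' `N - (dim - 1) * lag` points.
#'
#' @param series An [lfp_ts()] or numeric vector.
#' @param lag Delay in samples (`>= 1`).
#' @param dim Embedding dimension (`>= 1`).
#' @param source_id Optional label carried in the result.
#' @return Matrix of class `embedded_trajectory` (one row per point) with
#'   attributes `lag`, `embed_dim`, `dt` and `source_id`.
#' @export
embed_delay <- function(series, lag, dim, source_id = NULL) {
  x <- ts_values(series)
  lag <- as.integer(lag); dim <- as.integer(dim)
  if (lag < 1L) stop("`lag` must be >= 1")
  if (dim < 1L) stop("`dim` must be >= 1")
  n <- length(x)
  m <- n - (dim - 1L) * lag
  if (m < 1L) stop("series too short for this lag and dimension")
  pts <- vapply(seq_len(dim) - 1L, function(j) x[(1:m) + j * lag],
                numeric(m))
  if (m == 1L) pts <- matrix(pts, nrow = 1L)
  colnames(pts) <- paste0("x", seq_len(dim))
  structure(pts, class = c("embedded_trajectory", "matrix", "array"),
            lag = lag, embed_dim = dim,
            dt = if (inherits(series, "lfp_ts")) series$dt else NA_real_,
            source_id = source_id)
}

#' @export
print.embedded_trajectory <- function(x, ...) {
  cat(sprintf("<embedded_trajectory> %d points in %d dims (lag %d samples)\n",
              nrow(x), ncol(x), attr(x, "lag")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
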