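# Surrogate-data generation for nonlinearity testing.

# Random-phase (FT) surrogate of a numeric vector. The periodogram is
# preserved exactly: only the phases of the positive-frequency bins are
# randomized, with the DC bin untouched and -- for even length -- the
# (real-valued) Nyquist bin kept as is, so the inverse transform is real.
ft_surrogate_vec <- function(x) {
  n <- length(x)
  X <- fft(x)
  half <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  if (half >= 1) {
    ks <- 2:(half + 1)
    ph <- runif(half, 0, 2 * pi)
    X[ks] <- Mod(X[ks]) * exp(1i * ph)
    X[n + 2 - ks] <- Conj(X[ks])
  }
  Re(fft(X, inverse = TRUE)) / n
}

# Amplitude-adjusted FT surrogate: phase-randomize a Gaussianized copy of
# the series, then restore the original amplitude distribution by rank
# remapping. The sorted values of the surrogate equal the original exactly.
aaft_surrogate_vec <- function(x) {
  n <- length(x)
  g <- sort(rnorm(n))[rank(x, ties.method = "first")]
  gs <- ft_surrogate_vec(g)
  sort(x)[rank(gs, ties.method = "first")]
}

# Iterated AAFT: alternate between imposing the original amplitude spectrum
# and the original value distribution until the rank ordering stabilizes.
# The final step is the value remapping, so the value multiset is exact.
iaaft_surrogate_vec <- function(x, max_iter = 100) {
  n <- length(x)
  amp <- Mod(fft(x))
  s <- sort(x)
  cur <- x[sample.int(n)]
  prev_rank <- NULL
  for (it in seq_len(max_iter)) {
    spec <- fft(cur)
    mod <- Mod(spec)
    phase <- ifelse(mod > 0, spec / mod, 1)
    cur <- Re(fft(amp * phase, inverse = TRUE)) / n
    r <- rank(cur, ties.method = "first")
    cur <- s[r]
    if (!is.null(prev_rank) && identical(r, prev_rank)) break
    prev_rank <- r
  }
  cur
}

#' Generate surrogate series for a nonlinearity test
#'
#' Surrogates preserve the linear properties of the original series while
#' destroying any nonlinear structure, providing the null distribution of a
#' discriminating statistic under the hypothesis that the data are linearly
#' correlated but otherwise random.
#'
#' Methods: `"ft"` randomizes the Fourier phases and preserves the
#' periodogram exactly; `"aaft"` additionally restores the original value
#' distribution (sorted values are exactly those of the original);
#' `"iaaft"` (default) iterates the amplitude-spectrum and value-remapping
#' adjustments until the rank ordering stabilizes (at most `max_iter`
#' iterations), giving surrogates whose value multiset is exact and whose
#' autocorrelation closely matches the original's.
#'
#' @param series An [lfp_ts()] or numeric vector (length >= 8,
#'   non-constant).
#' @param n Number of surrogates (>= 1). Note that a rank test at
#'   significance level `l` needs at least `1/l` surrogates (20 for 5%).
#' @param method One of `"iaaft"`, `"ft"`, `"aaft"`.
#' @param seed Optional RNG seed for reproducibility.
#' @param max_iter IAAFT iteration cap.
#' @return Object of class `surrogate_set`: list with `original` (numeric),
#'   `surrogates` (list of numeric vectors), `method`, `seed`.
#' @export
make_surrogates <- function(series, n, method = c("iaaft", "ft", "aaft"),
                            seed = NULL, max_iter = 100) {
  method <- match.arg(method)
  x <- ts_values(series)
  if (length(x) < 8L) stop("series too short for surrogate generation")
  if (sd(x) == 0)
    stop("constant series: phase randomization is undefined")
  if (n < 1L) stop("`n` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  gen <- switch(method,
                ft = ft_surrogate_vec,
                aaft = aaft_surrogate_vec,
                iaaft = function(v) iaaft_surrogate_vec(v, max_iter))
  surrogates <- lapply(seq_len(n), function(i) gen(x))
  structure(list(original = x, surrogates = surrogates, method = method,
                 seed = seed),
            class = "surrogate_set")
}

#' @export
print.surrogate_set <- function(x, ...) {
  cat(sprintf("<surrogate_set> %d %s surrogates of a %d-sample series\n",
              length(x$surrogates), x$method, length(x$original)))
  invisible(x)
}
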