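# False-nearest-neighbour estimation of the embedding dimension.

#' False nearest neighbour fractions across embedding dimensions
#'
#' For each dimension `d`, the series is embedded at `(d, lag)` and every
#' point's nearest neighbour is found among points separated in time by
#' more than `theiler` samples (so trivially correlated temporal neighbours
#' are never counted as spatial neighbours). With `R_d` the neighbour
#' distance in `d` dimensions and `R_(d+1)` the distance after appending
#' the next delay coordinate, the pair is a false neighbour when
#' \deqn{\sqrt{(R_{d+1}^2 - R_d^2)/R_d^2} > f}
#' or -- with the attractor-size criterion active -- when `R_(d+1)` exceeds
#' `A * sigma`, where `sigma` is the standard deviation of the series (a
#' proxy for the attractor size). The selected embedding dimension `d_E` is
#' the smallest dimension whose false-neighbour fraction falls below
#' `threshold` (default 1%).
#'
#' @param series An [lfp_ts()] or numeric vector.
#' @param lag Embedding delay in samples.
#' @param dims Dimensions to scan (default 1..5).
#' @param f_ratio Distance-ratio threshold `f` (default 10; the decision is
#'   stable over roughly 7..20 on clean deterministic data).
#' @param theiler Theiler window in samples (default 0: only the point
#'   itself is excluded).
#' @param sigma_criterion Toggle for the attractor-size criterion.
#' @param sigma_mult Multiplier `A` of the size criterion (default 2).
#' @param threshold Fraction below which the attractor is considered
#'   unfolded (default 0.01).
#' @param decimate Keep every `decimate`-th sample before embedding, with
#'   `lag` and `theiler` rescaled accordingly; a speed knob for very long
#'   trials (default 1 = off).
#' @return Object of class `fnn_curve`: list with `dims`, `fraction` (per
#'   dimension, in `[0, 1]`, `NA` when no admissible neighbour exists),
#'   `d_E` (`NA` if no dimension passes), and the parameters used.
#' @export
fnn_fraction <- function(series, lag, dims = 1:5, f_ratio = 10, theiler = 0,
                         sigma_criterion = TRUE, sigma_mult = 2,
                         threshold = 0.01, decimate = 1L) {
  x <- ts_values(series)
  lag <- as.integer(lag)
  if (lag < 1L) stop("`lag` must be >= 1")
  if (f_ratio <= 0) stop("`f_ratio` must be > 0")
  decimate <- as.integer(decimate)
  if (decimate > 1L) {
    x <- x[seq(1L, length(x), by = decimate)]
    lag <- max(1L, as.integer(round(lag / decimate)))
    theiler <- as.integer(round(theiler / decimate))
  }
  dims <- sort(as.integer(dims))
  if (length(x) - max(dims) * lag < 2L)
    stop("series too short for the largest requested dimension")
  sig <- sd(x)
  # numerical floor: neighbour pairs closer than this are duplicates up to
  # rounding (e.g. exactly repeated cycles), and their distance ratio is
  # 0/0 noise rather than geometry
  eps <- 1e-8 * sig
  frac <- vapply(dims, function(d) {
    st <- fnn_neighbor_stats(x, lag, d, as.integer(theiler))
    ok <- st$found
    if (!any(ok)) return(NA_real_)
    rd <- st$dist[ok]; dl <- st$delta[ok]
    ratio <- dl / pmax(rd, eps)
    false <- ratio > f_ratio
    if (sigma_criterion)
      false <- false | (sqrt(rd^2 + dl^2) > sigma_mult * sig)
    mean(false)
  }, numeric(1))
  dE <- dims[which(!is.na(frac) & frac < threshold)[1]]
  structure(list(dims = dims, fraction = frac,
                 d_E = if (length(dE) == 0L || is.na(dE)) NA_integer_
                       else as.integer(dE),
                 lag = lag, f_ratio = f_ratio, theiler = theiler,
                 sigma_criterion = sigma_criterion, sigma_mult = sigma_mult,
                 threshold = threshold),
            class = "fnn_curve")
}

#' @export
print.fnn_curve <- function(x, ...) {
  cat(sprintf("<fnn_curve> lag %d, f = %g, Theiler %d\n",
              x$lag, x$f_ratio, x$theiler))
  cat("  dim:      ", paste(sprintf("%6d", x$dims), collapse = " "), "\n")
  cat("  fraction: ", paste(sprintf("%6.4f", x$fraction), collapse = " "),
      "\n")
  cat(sprintf("  selected d_E = %s (threshold %g)\n",
              ifelse(is.na(x$d_E), "none", x$d_E), x$threshold))
  invisible(x)
}
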