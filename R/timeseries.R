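# Core domain types: a uniformly sampled trace and an ensemble of trials.

#' Construct a uniformly sampled time series
#'
#' The basic container for one local field potential (LFP) trace: a vector of
#' real samples with a fixed sampling interval. Sample `i` (0-based) is taken
#' at time `t0 + i * dt`, where `t0` is the time of the first sample relative
#' to stimulus onset. Amplitudes are dimensionless ("arb. units").
#'
#' @param values Numeric vector of samples (length >= 2, all finite).
#' @param dt Sampling interval in seconds (e.g. `1e-4` for 10 kHz).
#' @param t0 Time of the first sample relative to stimulus onset, seconds.
#' @return An object of class `lfp_ts` with fields `values`, `dt`, `t0`.
#' @examples
#' x <- lfp_ts(sin(2 * pi * seq(0, 1, by = 1e-3)), dt = 1e-3)
#' x
#' @export
lfp_ts <- function(values, dt, t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a time series needs at least 2 samples")
  if (!all(is.finite(values)))
    stop("all samples must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number")
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("`t0` must be a single finite number")
  structure(list(values = values, dt = dt, t0 = t0), class = "lfp_ts")
}

#' @export
print.lfp_ts <- function(x, ...) {
  cat(sprintf("<lfp_ts> %d samples, dt = %g s, t0 = %g s, range [%.4g, %.4g]\n",
              length(x$values), x$dt, x$t0,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.lfp_ts <- function(x) length(x$values)

# Accept either an lfp_ts or a bare numeric vector in numeric kernels.
ts_values <- function(x) {
  if (inherits(x, "lfp_ts")) x$values else as.numeric(x)
}

# Rebuild an object of the same flavour as `proto` around new values.
ts_like <- function(values, proto, t0 = NULL) {
  if (inherits(proto, "lfp_ts")) {
    lfp_ts(values, dt = proto$dt, t0 = if (is.null(t0)) proto$t0 else t0)
  } else {
    values
  }
}

#' Sample times of a series
#'
#' @param series An [lfp_ts()].
#' @return Numeric vector `t0 + (0:(N-1)) * dt`, seconds.
#' @export
ts_times <- function(series) {
  stopifnot(inherits(series, "lfp_ts"))
  series$t0 + (seq_along(series$values) - 1) * series$dt
}

#' Read one trial from a single-column text file
#'
#' Trials are stored one per file, one decimal number per line (the storage
#' format of the original recordings). Blank lines and lines starting with
#' `#` are ignored.
#'
#' @param path Path to the file.
#' @param dt Sampling interval in seconds.
#' @param t0 Time of the first sample, seconds.
#' @return An [lfp_ts()].
#' @export
read_trial <- function(path, dt, t0 = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  keep <- nzchar(trimmed) & !startsWith(trimmed, "#")
  if (!any(keep)) stop("no data lines in ", path)
  vals <- suppressWarnings(as.numeric(trimmed[keep]))
  if (anyNA(vals)) {
    bad <- which(keep)[which(is.na(vals))[1L]]
    stop(sprintf("non-numeric value at line %d of %s: '%s'",
                 bad, path, trimmed[bad]))
  }
  lfp_ts(vals, dt = dt, t0 = t0)
}

#' Write one trial to a single-column text file
#'
#' Samples are written one per line at full double precision (17 significant
#' digits), so `write_trial()` followed by [read_trial()] is the identity.
#'
#' @param series An [lfp_ts()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trial <- function(series, path) {
  stopifnot(inherits(series, "lfp_ts"))
  writeLines(sprintf("%.17g", series$values), con = path)
  invisible(path)
}

#' Remove the stimulus-driven transient at the start of a trial
#'
#' Keeps the suffix of the series starting at the first sample at least
#' `t_cut` seconds after the first sample. The convention in the analyses
#' here is to drop the first 0.5 s of each 2 s trial and work with the last
#' 1.5 s of steady activity.
#'
#' @param series An [lfp_ts()].
#' @param t_cut Seconds to drop, measured from the first sample;
#'   `0 <= t_cut < duration`.
#' @return An [lfp_ts()] with `t0` advanced accordingly.
#' @export
drop_transient <- function(series, t_cut) {
  stopifnot(inherits(series, "lfp_ts"))
  n <- length(series$values)
  duration <- n * series$dt
  if (t_cut < 0) stop("`t_cut` must be non-negative")
  if (t_cut >= duration) stop("`t_cut` exceeds the duration of the series")
  # first 0-based index i with i * dt >= t_cut (tolerant to fp rounding)
  i0 <- ceiling(t_cut / series$dt - 1e-9)
  lfp_ts(series$values[(i0 + 1L):n], dt = series$dt,
         t0 = series$t0 + i0 * series$dt)
}

#' Standardize a series to zero mean and unit sample standard deviation
#'
#' @param series An [lfp_ts()] or numeric vector.
#' @return Same flavour as the input.
#' @export
zscore <- function(series) {
  x <- ts_values(series)
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant series")
  ts_like((x - mean(x)) / s, series)
}

#' Construct a trial ensemble
#'
#' An ordered collection of equal-length trials sharing one sampling
#' interval, as produced by repeated stimulation of the same preparation.
#'
#' @param trials List of [lfp_ts()] objects with identical length and `dt`.
#' @param trial_ids Optional character labels (default `trial_001`, ...).
#' @return An object of class `lfp_ensemble`.
#' @export
lfp_ensemble <- function(trials, trial_ids = NULL) {
  if (!is.list(trials) || length(trials) < 1L)
    stop("`trials` must be a non-empty list of lfp_ts objects")
  if (!all(vapply(trials, inherits, logical(1), "lfp_ts")))
    stop("all trials must be lfp_ts objects")
  n <- length(trials[[1]]$values)
  dt <- trials[[1]]$dt
  ok_len <- vapply(trials, function(s) length(s$values) == n, logical(1))
  ok_dt <- vapply(trials, function(s) isTRUE(all.equal(s$dt, dt)), logical(1))
  if (!all(ok_len)) stop("all trials must have the same length")
  if (!all(ok_dt)) stop("all trials must share the same sampling interval")
  if (is.null(trial_ids))
    trial_ids <- sprintf("trial_%03d", seq_along(trials))
  if (length(trial_ids) != length(trials))
    stop("`trial_ids` must match the number of trials")
  trial_ids <- as.character(trial_ids)
  if (anyDuplicated(trial_ids)) stop("trial ids must be unique")
  structure(list(trials = trials, trial_ids = trial_ids, dt = dt),
            class = "lfp_ensemble")
}

#' @export
print.lfp_ensemble <- function(x, ...) {
  cat(sprintf("<lfp_ensemble> %d trials x %d samples, dt = %g s\n",
              length(x$trials), length(x$trials[[1]]$values), x$dt))
  invisible(x)
}

#' @export
length.lfp_ensemble <- function(x) length(x$trials)

#' Trials as a matrix
#'
#' @param ensemble An [lfp_ensemble()].
#' @return Numeric matrix, one row per trial, row names from the trial ids.
#' @export
ensemble_matrix <- function(ensemble) {
  stopifnot(inherits(ensemble, "lfp_ensemble"))
  m <- do.call(rbind, lapply(ensemble$trials, function(s) s$values))
  rownames(m) <- ensemble$trial_ids
  m
}

#' Apply a function to every trial in an ensemble
#'
#' @param ensemble An [lfp_ensemble()].
#' @param f Function mapping an [lfp_ts()] to an [lfp_ts()].
#' @param ... Passed to `f`.
#' @return An [lfp_ensemble()].
#' @export
ensemble_map <- function(ensemble, f, ...) {
  stopifnot(inherits(ensemble, "lfp_ensemble"))
  lfp_ensemble(lapply(ensemble$trials, f, ...), ensemble$trial_ids)
}

#' Write an ensemble as trial files plus a manifest
#'
#' Writes one single-column text file per trial plus `manifest.csv` with
#' columns `trial_id`, `path` (relative to the manifest) and `dt`. An
#' optional ground-truth table is written as `ground_truth.csv`.
#'
#' @param ensemble An [lfp_ensemble()].
#' @param dir Output directory (created if needed).
#' @param truth Optional data frame of per-trial ground truth.
#' @return Invisibly, the manifest path.
#' @export
write_ensemble <- function(ensemble, dir, truth = NULL) {
  stopifnot(inherits(ensemble, "lfp_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- sprintf("%s.txt", ensemble$trial_ids)
  for (i in seq_along(ensemble$trials))
    write_trial(ensemble$trials[[i]], file.path(dir, paths[i]))
  manifest <- data.frame(trial_id = ensemble$trial_ids, path = paths,
                         dt = ensemble$dt, stringsAsFactors = FALSE)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  if (!is.null(truth))
    write.csv(truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(mpath)
}

#' Read an ensemble from a manifest
#'
#' @param manifest Path to a CSV with columns `trial_id`, `path`, and
#'   optionally `dt`; trial paths are resolved relative to the manifest.
#' @param dt Sampling interval; required if the manifest has no `dt` column.
#' @return An [lfp_ensemble()].
#' @export
read_ensemble <- function(manifest, dt = NULL) {
  tab <- read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("trial_id", "path") %in% names(tab)))
    stop("manifest must have columns `trial_id` and `path`")
  if (is.null(dt)) {
    if (!"dt" %in% names(tab))
      stop("manifest has no `dt` column; supply `dt` explicitly")
    dt <- unique(tab$dt)
    if (length(dt) != 1L) stop("manifest lists more than one `dt`")
  }
  base <- dirname(manifest)
  trials <- lapply(tab$path, function(p) {
    full <- if (file.exists(p)) p else file.path(base, p)
    read_trial(full, dt = dt)
  })
  lfp_ensemble(trials, tab$trial_id)
}
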