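# Experiment-shaped synthetic ensembles with known ground truth.

#' Weighted sum of traces (a model LFP)
#'
#' An LFP is modelled as a weighted sum of the activities of nearby neural
#' oscillators; this is the corresponding pointwise operation.
#'
#' @param traces List of [lfp_ts()] objects (or numeric vectors) of equal
#'   length, or a matrix with one trace per row.
#' @param weights Numeric weights, one per trace.
#' @return Same flavour as the first trace.
#' @export
synthesize_lfp <- function(traces, weights) {
  if (is.matrix(traces)) traces <- lapply(seq_len(nrow(traces)),
                                          function(i) traces[i, ])
  if (!is.list(traces) || length(traces) == 0L)
    stop("`traces` must be a non-empty list or matrix")
  if (length(weights) != length(traces))
    stop("`weights` length must match the number of traces")
  vals <- lapply(traces, ts_values)
  n <- length(vals[[1]])
  if (!all(lengths(vals) == n)) stop("all traces must have the same length")
  out <- numeric(n)
  for (i in seq_along(vals)) out <- out + weights[i] * vals[[i]]
  ts_like(out, traces[[1]])
}

#' Specification of a synthetic trial ensemble
#'
#' Describes a full experiment-shaped ensemble: `n_trials` trials of
#' duration `trial_duration`, sampled at `dt`, each consisting of a
#' stimulus-driven transient of length `transient` followed by steady
#' activity. The steady part of every trial is a class template (a
#' Morris-Lecar-derived LFP waveform, scaled by its class amplitude)
#' circularly shifted by a trial-specific number of samples -- the imposed
#' permanent phase shift -- plus i.i.d. Gaussian observation noise.
#'
#' The defaults emulate the recording protocol the package targets: 100
#' trials of 2 s at 10 kHz, a 0.5 s transient, five waveform classes with a
#' majority of high-amplitude trials and a minority low-amplitude class
#' whose peak-to-peak amplitude is 5.5 times smaller (the kind of attenuated
#' trials that intermittent stimulation failures produce).
#'
#' @param n_trials Number of trials.
#' @param trial_duration Trial length, seconds.
#' @param dt Sampling interval, seconds.
#' @param transient Transient length prepended to the steady part, seconds.
#' @param group_weights Per-class proportions (must sum to 1).
#' @param group_amplitudes Per-class peak-to-peak scale factors.
#' @param phase_law `"uniform"` (stimulus phases uniform on `[0,1)`),
#'   `"none"` (all phases 0), or a function `f(n)` returning `n` phases.
#' @param noise_sd Standard deviation of the Gaussian observation noise.
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @param templates Optional list of per-class steady waveforms (numeric
#'   vectors of length `(trial_duration - transient)/dt`), overriding the
#'   Morris-Lecar template. A single vector is recycled across classes.
#' @param n_oscillators Number of noisy oscillators averaged into the
#'   default template.
#' @param ml [ml_params()] used for the default template (noisy by default
#'   so that the template has a unique circular autocorrelation peak).
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_trials = 100, trial_duration = 2, dt = 1e-4,
                          transient = 0.5,
                          group_weights = c(0.30, 0.25, 0.20, 0.15, 0.10),
                          group_amplitudes = c(1, 0.9, 0.8, 0.7, 1 / 5.5),
                          phase_law = "uniform", noise_sd = 0.05, seed = 1,
                          templates = NULL, n_oscillators = 8,
                          ml = ml_params(noise_amp = 30)) {
  if (n_trials < 1) stop("`n_trials` must be >= 1")
  if (abs(sum(group_weights) - 1) > 1e-8)
    stop("`group_weights` must sum to 1")
  if (any(group_weights < 0)) stop("`group_weights` must be non-negative")
  if (length(group_amplitudes) != length(group_weights))
    stop("`group_amplitudes` must match `group_weights` in length")
  if (transient < 0 || transient >= trial_duration)
    stop("`transient` must lie in [0, trial_duration)")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (!(identical(phase_law, "uniform") || identical(phase_law, "none") ||
        is.function(phase_law)))
    stop("`phase_law` must be \"uniform\", \"none\", or a function")
  structure(list(n_trials = as.integer(n_trials),
                 trial_duration = trial_duration, dt = dt,
                 transient = transient, group_weights = group_weights,
                 group_amplitudes = group_amplitudes, phase_law = phase_law,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 templates = templates, n_oscillators = n_oscillators,
                 ml = ml),
            class = "ensemble_spec")
}

#' Fast test preset of the ensemble specification
#'
#' Same structure as the full-scale default but at `dt = 5e-4` s, which
#' keeps end-to-end runs desk-fast while preserving the trial count, class
#' structure and timing of the full-scale design.
#'
#' @param ... Overrides passed on to [ensemble_spec()].
#' @export
ensemble_spec_fast <- function(...) {
  args <- list(...)
  defaults <- list(dt = 5e-4)
  ensemble_spec_args <- modifyList(defaults, args)
  do.call(ensemble_spec, ensemble_spec_args)
}

#' Read an ensemble specification from a YAML or JSON file
#'
#' The file holds any subset of the [ensemble_spec()] fields (as scalars
#' and vectors; `phase_law` as `"uniform"` or `"none"`); omitted fields
#' keep their defaults. Morris-Lecar overrides go under an `ml` mapping.
#'
#' @param path File ending in `.yaml`, `.yml` or `.json`.
#' @return An [ensemble_spec()].
#' @export
read_ensemble_spec <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path,
                                                     simplifyVector = TRUE)
         else stop("unsupported config format: .", ext)
  if (!is.null(raw$ml)) raw$ml <- do.call(ml_params, raw$ml)
  do.call(ensemble_spec, raw)
}

# Build the default steady-state LFP template: the equal-weight sum of
# several noisy Morris-Lecar oscillators with heterogeneous bias currents
# (hence slightly different intrinsic rates) and random initial states,
# settled, centred and scaled to unit peak-to-peak amplitude. The frequency
# heterogeneity makes the summed waveform aperiodic over a trial, which is
# what gives each trial a unique circular-correlation alignment optimum.
ml_lfp_template <- function(spec, n_steady) {
  settle <- 0.5
  dur <- settle + n_steady * spec$dt
  traces <- lapply(seq_len(spec$n_oscillators), function(i) {
    p <- spec$ml
    # +5..15%: rate heterogeneity that also keeps every oscillator above
    # the bistable window near the oscillation onset, where bias noise
    # could otherwise annihilate the rhythm mid-trial
    p$I_bias <- p$I_bias * (1 + runif(1, 0.05, 0.15))
    simulate_ml(p, duration = dur, dt = spec$dt)$values
  })
  avg <- Reduce(`+`, traces) / length(traces)
  n_settle <- round(settle / spec$dt)
  steady <- avg[(n_settle + 1):(n_settle + n_steady)]
  steady <- steady - mean(steady)
  steady / (max(steady) - min(steady))
}

#' Generate a synthetic trial ensemble with known ground truth
#'
#' @param spec An [ensemble_spec()].
#' @return List with elements
#'   * `ensemble`: an [lfp_ensemble()] of full trials (transient + steady);
#'   * `truth`: data frame with one row per trial (`trial_id`, `class`,
#'     `shift_samples`, `phase`, `amplitude`);
#'   * `templates`: the per-class steady templates actually used.
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  set.seed(spec$seed)
  n_total <- round(spec$trial_duration / spec$dt)
  n_trans <- round(spec$transient / spec$dt)
  n_steady <- n_total - n_trans
  k <- length(spec$group_weights)

  templates <- spec$templates
  if (is.null(templates)) {
    base <- ml_lfp_template(spec, n_steady)
    templates <- rep(list(base), k)
  } else {
    if (is.numeric(templates)) templates <- list(templates)
    if (length(templates) == 1L) templates <- rep(templates, k)
    if (length(templates) != k)
      stop("`templates` must have one waveform per class")
    if (!all(lengths(templates) == n_steady))
      stop(sprintf("each template must have %d samples", n_steady))
  }

  # deterministic class counts hitting the proportions as closely as possible
  counts <- diff(c(0L, round(cumsum(spec$group_weights) * spec$n_trials)))
  counts[k] <- spec$n_trials - sum(counts[-k])
  classes <- sample(rep(seq_len(k), counts))

  phases <- switch(
    class(spec$phase_law)[1],
    "function" = spec$phase_law(spec$n_trials),
    if (identical(spec$phase_law, "uniform")) runif(spec$n_trials)
    else rep(0, spec$n_trials)
  )
  if (any(phases < 0 | phases >= 1)) stop("phases must lie in [0, 1)")
  shifts <- as.integer(floor(phases * n_steady))

  env <- exp(-(seq_len(n_trans) - 1) * spec$dt / (spec$transient / 4 + 1e-12))
  trials <- vector("list", spec$n_trials)
  for (i in seq_len(spec$n_trials)) {
    cl <- classes[i]
    amp <- spec$group_amplitudes[cl]
    steady <- circular_shift(amp * templates[[cl]], shifts[i])
    if (n_trans > 0) {
      # stylized evoked response: the template continued backwards under a
      # decaying envelope, so the trace is continuous at the boundary
      lead_idx <- ((-(n_trans:1)) %% n_steady) + 1L
      trans <- (1 + 2 * rev(env)) * steady[lead_idx]
      vals <- c(trans, steady)
    } else {
      vals <- steady
    }
    if (spec$noise_sd > 0) vals <- vals + rnorm(n_total, 0, spec$noise_sd)
    trials[[i]] <- lfp_ts(vals, dt = spec$dt, t0 = 0)
  }
  ids <- sprintf("trial_%03d", seq_len(spec$n_trials))
  truth <- data.frame(trial_id = ids, class = classes,
                      shift_samples = shifts, phase = phases,
                      amplitude = spec$group_amplitudes[classes],
                      stringsAsFactors = FALSE)
  list(ensemble = lfp_ensemble(trials, ids), truth = truth,
       templates = templates)
}
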