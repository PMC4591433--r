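# Morris-Lecar oscillator: simulation, peak bookkeeping, phase resetting.

#' Morris-Lecar model parameters
#'
#' Parameter set for the two-variable Morris-Lecar conductance model
#' \deqn{C \dot V = I - g_{Ca} m_\infty(V)(V-V_{Ca}) - g_K w (V-V_K) -
#'   g_L (V-V_L)}
#' \deqn{\dot w = \phi \cosh\!\big(\tfrac{V-V_3}{2V_4}\big)
#'   (w_\infty(V) - w)}
#' with \eqn{m_\infty(V) = \frac12[1+\tanh((V-V_1)/V_2)]} and
#' \eqn{w_\infty(V) = \frac12[1+\tanh((V-V_3)/V_4)]}. The defaults are the
#' widely used type-II (Hopf) parameter set, which produces a robust limit
#' cycle at `I_bias = 90` uA/cm^2. `noise_amp` is the half-width of uniform
#' noise added to the bias current at every internal integration step.
#'
#' @param C Membrane capacitance, uF/cm^2.
#' @param gCa,gK,gL Maximal conductances, mS/cm^2.
#' @param VCa,VK,VL Reversal potentials, mV.
#' @param V1,V2,V3,V4 Activation shape parameters, mV.
#' @param phi Recovery-variable rate constant, 1/ms.
#' @param I_bias Applied bias current, uA/cm^2.
#' @param noise_amp Uniform noise half-width on the bias current, uA/cm^2.
#' @return An object of class `ml_params`.
#' @export
ml_params <- function(C = 20, gCa = 4.4, gK = 8, gL = 2,
                      VCa = 120, VK = -84, VL = -60,
                      V1 = -1.2, V2 = 18, V3 = 2, V4 = 30,
                      phi = 0.04, I_bias = 90, noise_amp = 0) {
  p <- list(C = C, gCa = gCa, gK = gK, gL = gL, VCa = VCa, VK = VK, VL = VL,
            V1 = V1, V2 = V2, V3 = V3, V4 = V4, phi = phi, I_bias = I_bias,
            noise_amp = noise_amp)
  if (any(vapply(p, function(v) !is.numeric(v) || length(v) != 1L ||
                   !is.finite(v), logical(1))))
    stop("all Morris-Lecar parameters must be single finite numbers")
  if (gCa < 0 || gK < 0 || gL < 0) stop("conductances must be >= 0")
  if (phi <= 0) stop("`phi` must be > 0")
  if (noise_amp < 0) stop("`noise_amp` must be >= 0")
  structure(p, class = "ml_params")
}

ml_par_vector <- function(params) {
  unlist(params[c("C", "gCa", "gK", "gL", "VCa", "VK", "VL",
                  "V1", "V2", "V3", "V4", "phi", "I_bias")],
         use.names = FALSE)
}

#' Rectangular stimulus specification
#'
#' A brief depolarizing current pulse mimicking a 10 ms light pulse. The
#' pulse onset is placed at a fraction `phase` of the oscillator cycle,
#' measured from the most recent membrane-potential peak.
#'
#' @param amplitude Pulse amplitude, uA/cm^2.
#' @param duration Pulse duration in seconds (default 10 ms).
#' @param phase Onset phase in `[0, 1)` within the perturbed cycle.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(amplitude = 30, duration = 0.01, phase = 0.3) {
  if (!is.numeric(duration) || duration <= 0) stop("`duration` must be > 0")
  if (!is.numeric(phase) || phase < 0 || phase >= 1)
    stop("`phase` must be in [0, 1)")
  structure(list(amplitude = amplitude, duration = duration, phase = phase),
            class = "stimulus_spec")
}

#' Detect membrane-potential peaks
#'
#' Local maxima above the mid-range threshold, with a refractory gap of 20%
#' of the median inter-peak interval so that noise riding on a spike is not
#' double counted.
#'
#' @param series An [lfp_ts()] or numeric vector.
#' @param dt Sampling interval (ignored when `series` is an [lfp_ts()]).
#' @return List with `index` (1-based sample indices) and `time` (seconds,
#'   relative to the first sample).
#' @export
find_peaks <- function(series, dt = NULL) {
  x <- ts_values(series)
  if (inherits(series, "lfp_ts")) dt <- series$dt
  if (is.null(dt)) stop("`dt` required for a bare numeric series")
  thr <- (max(x) + min(x)) / 2
  n <- length(x)
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  cand <- cand[x[cand] > thr]
  if (length(cand) == 0L) return(list(index = integer(0), time = numeric(0)))
  if (length(cand) > 1L) {
    gap <- 0.2 * median(diff(cand))
    keep <- cand[1]
    for (k in cand[-1]) {
      if (k - keep[length(keep)] > gap) {
        keep <- c(keep, k)
      } else if (x[k] > x[keep[length(keep)]]) {
        keep[length(keep)] <- k
      }
    }
    cand <- keep
  }
  list(index = cand, time = (cand - 1) * dt)
}

#' Simulate a Morris-Lecar membrane-potential trace
#'
#' Integrates the model with a fixed-step 4th-order Runge-Kutta scheme at an
#' internal step of `dt / substeps`, subsampled to `dt`. With a stimulus,
#' the pulse is injected starting at the requested phase of the cycle given
#' by `cycle` (counted over the detected peaks of the noise-free,
#' unperturbed trace, so the onset is deterministic even for noisy runs).
#'
#' @param params An [ml_params()].
#' @param duration Trace duration, seconds.
#' @param dt Sampling interval, seconds (default `1e-4`, i.e. 10 kHz).
#' @param stimulus Optional [stimulus_spec()].
#' @param seed Optional RNG seed (only relevant when `noise_amp > 0`).
#' @param cycle Index of the perturbed cycle (onset is measured from the
#'   `cycle`-th detected peak).
#' @param substeps Internal integration substeps per sample.
#' @param init Initial state `c(V, w)`.
#' @return An [lfp_ts()] of the membrane potential (mV). The stimulus onset
#'   time (seconds) and the unperturbed period are attached as attributes
#'   `stim_onset` and `period`.
#' @export
simulate_ml <- function(params = ml_params(), duration = 2, dt = 1e-4,
                        stimulus = NULL, seed = NULL, cycle = 3,
                        substeps = 10, init = c(V = -60, w = 0.015)) {
  stopifnot(inherits(params, "ml_params"))
  if (!is.null(seed)) set.seed(seed)
  dur_ms <- duration * 1000
  dt_ms <- dt * 1000
  pv <- ml_par_vector(params)
  onset_ms <- -1
  stim_dur_ms <- 0
  stim_amp <- 0
  period_s <- NA_real_
  if (!is.null(stimulus)) {
    stopifnot(inherits(stimulus, "stimulus_spec"))
    ref <- ml_integrate(pv, dur_ms, dt_ms, as.integer(substeps),
                        -1, 0, 0, 0, init[["V"]], init[["w"]])
    pk <- find_peaks(ref, dt = dt)
    if (length(pk$time) < cycle + 1L)
      stop("trace too short to place the stimulus in cycle ", cycle)
    ipi <- diff(pk$time)
    period_s <- mean(ipi[-1])  # skip the first, settling interval
    onset_s <- pk$time[cycle] + stimulus$phase * period_s
    h_ms <- dt_ms / substeps
    onset_ms <- round(onset_s * 1000 / h_ms) * h_ms  # align to substep grid
    stim_dur_ms <- stimulus$duration * 1000
    stim_amp <- stimulus$amplitude
  }
  v <- ml_integrate(pv, dur_ms, dt_ms, as.integer(substeps),
                    onset_ms, stim_dur_ms, stim_amp, params$noise_amp,
                    init[["V"]], init[["w"]])
  out <- lfp_ts(v, dt = dt, t0 = 0)
  if (length(find_peaks(out)$index) < 3L)
    stop("non-oscillatory parameters: fewer than 3 peaks detected")
  attr(out, "stim_onset") <- if (onset_ms >= 0) onset_ms / 1000 else NA_real_
  attr(out, "period") <- period_s
  out
}

#' Phase resetting curve of the Morris-Lecar oscillator
#'
#' Perturbs the free-running oscillator at `n_phases` equally spaced phases
#' of the cycle given by `cycle` and measures the relative change of that
#' cycle's length: resetting `(P_i - P_perturbed) / P_i`, positive for an
#' advance of the next peak and negative for a delay.
#'
#' @param params An [ml_params()] (noise is usually left at 0 for a clean
#'   curve).
#' @param stimulus A [stimulus_spec()] template; its `phase` field is
#'   ignored and replaced by each probe phase.
#' @param n_phases Number of equally spaced probe phases (default 100).
#' @param cycle Perturbed cycle index.
#' @param duration Simulation length per probe, seconds.
#' @param dt Sampling interval, seconds.
#' @param seed Optional seed; every probe simulation reuses the same seed,
#'   so a zero-amplitude stimulus gives exactly zero resetting even for a
#'   noisy oscillator.
#' @return Data frame with columns `phase` and `resetting`.
#' @details The resetting at each phase is the paired difference
#'   `(P_ref - P_pert) / P_i`, where `P_pert` is the length of the cycle
#'   containing the pulse in the perturbed run, `P_ref` the length of the
#'   same cycle in an unperturbed run with an identical noise realization,
#'   and `P_i` the intrinsic period of the noise-free skeleton.
#' @export
phase_resetting_curve <- function(params = ml_params(), stimulus = stimulus_spec(),
                                  n_phases = 100, cycle = 3, duration = 1,
                                  dt = 1e-4, seed = NULL) {
  stopifnot(inherits(params, "ml_params"), inherits(stimulus, "stimulus_spec"))
  base_seed <- if (is.null(seed)) 0L else as.integer(seed)
  # noise-free skeleton fixes the intrinsic period and the onset grid
  nf <- params; nf$noise_amp <- 0
  ref0 <- simulate_ml(nf, duration = duration, dt = dt, substeps = 10)
  pk0 <- find_peaks(ref0)
  if (length(pk0$time) < cycle + 2L)
    stop("duration too short to measure the perturbed cycle")
  P <- mean(diff(pk0$time)[-1])
  # unperturbed run with the same noise realization as every probe
  ref <- simulate_ml(params, duration = duration, dt = dt, seed = base_seed,
                     substeps = 10)
  pkr <- find_peaks(ref)
  cycle_length <- function(peaks, onset) {
    before <- peaks[peaks <= onset + 1e-12]
    if (length(before) == 0L) return(NA_real_)
    t_k <- max(before)
    after <- peaks[peaks > t_k]
    if (length(after) == 0L) return(NA_real_)
    min(after) - t_k
  }
  phases <- (seq_len(n_phases) - 1) / n_phases
  resetting <- vapply(phases, function(ph) {
    st <- stimulus_spec(amplitude = stimulus$amplitude,
                        duration = stimulus$duration, phase = ph)
    pert <- simulate_ml(params, duration = duration, dt = dt, stimulus = st,
                        seed = base_seed, cycle = cycle, substeps = 10)
    onset <- attr(pert, "stim_onset")
    P_ref <- cycle_length(pkr$time, onset)
    P_pert <- cycle_length(find_peaks(pert)$time, onset)
    (P_ref - P_pert) / P
  }, numeric(1))
  data.frame(phase = phases, resetting = resetting)
}

#' Simulate the Lorenz-63 system
#'
#' A canonical three-dimensional chaotic system, used as a deterministic
#' fixture with a known attractor dimension for embedding diagnostics.
#'
#' @param n Number of output samples.
#' @param dt Output sampling step (model time units).
#' @param sigma,rho,beta Standard Lorenz parameters.
#' @param init Initial state.
#' @param transient Number of initial samples to discard.
#' @param substeps RK4 substeps per output sample.
#' @return Matrix `n x 3` with columns `x`, `y`, `z`.
#' @export
simulate_lorenz <- function(n, dt = 0.01, sigma = 10, rho = 28, beta = 8 / 3,
                            init = c(-8, 8, 27), transient = 1000,
                            substeps = 10) {
  m <- lorenz_integrate(as.integer(n), dt, sigma, rho, beta,
                        as.numeric(init), as.integer(transient),
                        as.integer(substeps))
  colnames(m) <- c("x", "y", "z")
  attr(m, "dt") <- dt
  m
}
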