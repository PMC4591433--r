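---
title: "Methods: nonlinear analysis of stimulus-evoked LFP ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nonlinear analysis of stimulus-evoked LFP ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpattractor)
```

## The problem

A cortical local network is perturbed every 2 s by a brief (10 ms)
stimulus while the local field potential (LFP) is recorded at 10 kHz, one
trial per stimulus. The questions the package answers for such an
ensemble are:

1. Is the steady LFP activity nonlinear, or indistinguishable from
   linearly filtered noise?
2. How much did the stimulus permanently shift the phase of the ongoing
   rhythm in each trial (phase resetting), and can the trials be brought
   into register?
3. After registration and grouping of similar trials, can the steady
   dynamics be reconstructed in a low-dimensional phase space, and with
   which delay and embedding dimension?

Each trial is split into a transient (first ~0.5 s after the stimulus)
and a steady segment (the last 1.5 s), and all analysis runs on the
steady segment (`drop_transient()`).

## Surrogate-data nonlinearity testing

The null hypothesis is that a trial is a realization of a linear Gaussian
process observed through a static transform: linearly correlated in time,
random otherwise. `make_surrogates()` draws `n` surrogate series that obey
the null while matching the linear properties of the data:

* `ft`: randomize Fourier phases, preserving the periodogram exactly;
* `aaft`: additionally restore the exact amplitude distribution by rank
  remapping;
* `iaaft` (default): iterate the spectral and amplitude adjustments until
  the rank ordering stabilizes (at most 100 iterations), ending on the
  amplitude step so the value multiset is exact.

The discriminating statistic is the time-reversal asymmetry
$\lambda = \langle (x_i - x_{i-\tau})^3 \rangle / \langle (x_i -
x_{i-\tau})^2 \rangle$, a robust signature of nonlinearity: a linear
Gaussian process is statistically reversible, so $\lambda \approx 0$ for
it and for every surrogate. Three rejection rules are computed by
`surrogate_test()`: the average score $\gamma = |\bar\lambda/\lambda_0 -
1|$ (reject above 1), the coefficient-of-variation score $\gamma =
|\bar\lambda - \lambda_0|/\sigma_\lambda$ (reject above 1.96, the
two-sided 95% normal critical value), and rank ordering (reject when
$\lambda_0$ is a strict extreme of the pooled list; at level 5% this
needs at least $1/0.05 = 20$ surrogates). Ties in the rank test count
against rejection. Per-trial CV scores are averaged within dendrogram
groups (`group_gamma()`) and the group verdict uses the same 1.96
threshold.

The increment delay $\tau$ matters: at the raw sampling rate of a smooth
band-limited signal, one-sample increments carry almost no asymmetry. The
delay is configurable (default 1 sample for the elementary statistic); in
the calibration studies below we use a delay of about a fifth of the
dominant oscillation period, which is where the asymmetry of a spiking
waveform lives.

A second discriminating statistic is the percentage of false nearest
neighbours (`fnn_discrimination()`): a deterministic signal unfolds at a
low embedding dimension while its phase-randomized surrogates do not, so
the null is rejected when the original FNN curve lies strictly below the
surrogate envelope at every tested dimension.

### Calibration choices

The acceptance studies check the CV-score test at fixed conditions:

* **Size (type-I error):** 200 realizations of the Gaussian AR(2) process
  $x_t = 1.6 x_{t-1} - 0.8 x_{t-2} + \varepsilon_t$, 4096 samples each,
  100 `ft` surrogates. For a Gaussian linear process the FT surrogate is
  the exact null generator, so this isolates the test's calibration; the
  empirical rejection rate should stay below 0.12.
* **Power:** 50 windows of 4096 samples (about 40 cycles) of the
  noise-free Morris-Lecar membrane potential sampled at 1 kHz, 100
  `iaaft` surrogates. The amplitude distribution of a spiking trace is
  strongly non-Gaussian, so the amplitude-adjusted surrogates are the
  appropriate (and tighter) null; the rejection rate should be at least
  0.9. Window starts are drawn at random to vary the realization, since
  the noise-free trajectory itself is deterministic.

## The synthetic generator

No recordings are distributed with the package, so the generator is a
first-class module that produces experiment-shaped ensembles with known
ground truth.

**Oscillator.** `simulate_ml()` integrates the two-variable Morris-Lecar
conductance model with a fixed-step RK4 scheme at one tenth of the
sampling interval. The default parameters are the widely used type-II
(Hopf) set (`ml_params()`); the model then fires periodically at about
9.7 Hz (period $\approx$ 103 ms), a plausible LFP rhythm at the package's
10 kHz convention. Uniform noise of half-width `noise_amp` can be added
to the bias current at every internal step. A rectangular pulse
(`stimulus_spec()`, default 30 uA/cm^2 for 10 ms) injected at a chosen
phase of the cycle resets the oscillator: at phase 0.3 the next peak is
delayed, at phase 0.5 it is advanced. `phase_resetting_curve()` maps this
out as $(P_{ref} - P_{pert})/P_i$ over equally spaced phases, measured as
a paired difference of the perturbed cycle's length against the same
cycle in an identically seeded unperturbed run (so a zero-amplitude pulse
gives exactly zero). Near the subcritical Hopf point the model is
bistable, and a pulse in a narrow phase window can annihilate the rhythm
altogether; the curve reports `NA` there.

**Ensembles.** `generate_ensemble()` builds each trial as a class
template, scaled by the class amplitude, circularly shifted by a
trial-specific number of samples (the imposed permanent phase shift,
drawn from the phase law), plus i.i.d. Gaussian observation noise, with a
stylized decaying transient prepended. The default template is the
equal-weight sum of eight noisy Morris-Lecar oscillators whose bias
currents are jittered upward by up to 10%; the frequency heterogeneity
makes the summed waveform aperiodic over a trial, which is what gives
each trial a unique alignment optimum (a perfectly periodic template
would make the recovered shift ambiguous modulo the period). The default
class structure mirrors the experimental ensembles the package targets:
100 trials of 2 s at 10 kHz, a 0.5 s transient, five classes with
weights (0.30, 0.25, 0.20, 0.15, 0.10) and amplitudes (1, 0.9, 0.8, 0.7,
1/5.5) -- a majority of similar high-amplitude waveforms plus a minority
class attenuated by the factor 5.5, standing in for trials degraded by
intermittent stimulation failures. `ensemble_spec_fast()` keeps the same
design at 2 kHz for desk-fast end-to-end runs; the full-scale preset is
the default `ensemble_spec()`.

**What the generator does not emulate.** Real LFPs are broadband and
nonstationary; the generator's trials are a fixed template plus white
noise, so passing tests demonstrate correctness of the analysis
machinery, not robustness to every pathology of real recordings. One
artifact is specific to the generator: circularly shifting an *aperiodic*
template (e.g. a Lorenz coordinate) cuts its continuity at the wrap
point. True phase resetting moves the system along its attractor and
creates no such seam. Recovery tests that embed a shifted-template
average therefore pin the reference trial's phase to zero, which makes
the aligned frame coincide with the template frame.

## Phase-resetting correction

`best_shift()` maximizes the Pearson correlation between a trial and a
reference over all $N$ circular shifts, computed by FFT cross-correlation
of the mean-centred signals -- identical, shift for shift, to exhaustive
search (this is asserted in the tests). Ties are broken by the smallest
absolute shift, preferring positive; shifts are reported in
$(-N/2, N/2]$ so they read as signed phase shifts, and a derived column
expresses them in cycles of the dominant period (first autocorrelation
peak past the first zero). `align_ensemble()` applies this to every trial
against a reference ("first" by default, as the choice is arbitrary;
"medoid" or an explicit id for robustness), recording correlation and
rms error before and after. Because the identity shift is always a
candidate, alignment can never lower the correlation to the reference.
Trials are deliberately *not* z-scored first: amplitude differences are
information used by the grouping stage.

## Dendrogram grouping

Aligned trials are compared by plain Euclidean waveform distance
(`pairwise_distances()`) and clustered agglomeratively
(`build_dendrogram()`, average linkage by default -- monotone and
standard for waveform similarity; single, complete and Ward are
selectable). `cut_dendrogram()` cuts by height or by group count; the
default operating point is five groups, matching the protocol the
package emulates, where the low-amplitude minority separates from three
or four similar high-amplitude groups. Group averages (`group_average()`)
then serve as denoised per-group waveforms; on separable ensembles each
trial sits closer (in rms) to its own group average than to the global
alignment reference.

## Delay embedding

For a steady trial $x_i$, delay vectors are $(x_i, x_{i+n}, \ldots,
x_{i+(d-1)n})$ (`embed_delay()`), leaving $N - (d-1)n$ points.

**Lag.** `estimate_lag()` reports both standard estimates: the first zero
of the autocorrelation (`autocorrelation()`, periodic continuation by
default; a small positive tolerance absorbs curves that touch zero
exactly) and the first local minimum of the average mutual information
(`average_mutual_information()`, 16 equal-width bins over the observed
range, natural log). The AMI minimum is preferred when it exists, the
autocorrelation zero is the fallback. A caveat found while validating:
for a *noise-free* sinusoid the binned AMI curve carries deterministic
ripples of a few hundredths of a nat, so the strict first-local-minimum
rule can stop at a small lag even though the curve's global minimum over
the first half-cycle sits at the quarter period as expected. On
broadband or noisy signals (every practical input) the rule behaves as
intended; the limitation is documented rather than patched with
smoothing, because any smoothing window would be as arbitrary as the
ripple it removes.

**Dimension.** `fnn_fraction()` implements the false-nearest-neighbour
count: embed at $(d, n)$, find each point's nearest neighbour at least
`theiler` samples away in time (excluding trivially correlated temporal
neighbours), and flag the pair as false when
$\sqrt{(R_{d+1}^2 - R_d^2)/R_d^2} > f$ or when $R_{d+1} > A\sigma$ with
$\sigma$ the series' standard deviation (a proxy for the attractor size;
$A = 2$ by default, toggleable). The selected $d_E$ is the smallest
dimension with under 1% false neighbours. The ratio threshold defaults to
$f = 10$; on clean deterministic data the decision is stable over
roughly $f \in [7, 20]$ (asserted on a Lorenz-63 trajectory, which
selects $d_E = 3$ across that range). Numerical choices: neighbour ties
go to the smallest index; neighbour distances below $10^{-8}\sigma$ are
treated as exact duplicates (their distance ratio is rounding noise, not
geometry -- this matters for exactly repeating cycles); points with no
admissible neighbour are excluded from the count. The production scan is
compiled; tests pin it to an all-pairs brute-force oracle in R.

## The pipeline

`run_pipeline()` executes the stages in their scientific order --
transient removal, alignment, grouping, group-aggregated nonlinearity
testing, lag estimation per trial and per group average, FNN on the
group averages, and embedding of the group averages -- because averaging
or comparing trials before phase correction mixes incompatible phases
and destroys both phase and amplitude information. Reports are written
as JSON plus CSV tables, trajectories as one CSV per group; reruns with
the same config and seed are bit-identical. Grouping first also reduces
the work of comparing reconstructed trajectories: all-pairs comparison
of $N$ trials would cost $N(N+1)/2$ pairings
(`pair_comparison_budget()`), 5050 for $N = 100$, whereas within-group
checks suffice.

## Problem sizes used in the checks

The packaged studies run at sizes chosen to exercise the full design
while staying desk-fast: the fast ensemble preset (100 trials of 2 s at
2 kHz) for alignment and grouping recovery; 4096-sample windows for the
surrogate calibration; 3000-10000-point Lorenz trajectories for the
embedding diagnostics; brute-force oracle comparisons at up to 2048
samples (shifts), 500 points (FNN) and 8 leaves (linkage). The
full-scale 10 kHz preset is available through `ensemble_spec()` and the
bundled scripts.

## Known limitations

* The Morris-Lecar parameters, stimulus strength and noise levels are
  standard modelling choices, not fits to any recording; the generator
  reproduces the *shape* of the experiment, not particular traces.
* Sub-sample (interpolated) shifts and dynamic time warping are out of
  scope; alignment is integer-shift only.
* Lag estimation on noise-free periodic signals inherits the AMI ripple
  caveat above.
* FNN on short, noisy group averages may legitimately select no
  dimension (reported as `NA`) when the residual noise floor keeps the
  false-neighbour fraction above the 1% threshold; embedding of that
  group is then skipped rather than forced.
* Automated topological classification of the reconstructed attractors
  (e.g. recognizing a figure-eight) is not attempted; trajectories are
  exported as coordinates for inspection.
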