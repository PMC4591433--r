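# lfpattractor

Nonlinear time-series analysis of stimulus-evoked local field potentials
(LFPs), for electrophysiologists and computational neuroscientists who
record trial ensembles of rhythmic network activity around a brief
periodic stimulus and want to know (i) whether the steady activity is
genuinely nonlinear, (ii) how much the stimulus permanently reset the
phase of the ongoing rhythm in each trial, and (iii) whether the steady
dynamics live on a low-dimensional attractor.

The package implements the full analysis chain plus a synthetic generator
with known ground truth:

* **Surrogate-data nonlinearity testing** — FT, AAFT and IAAFT surrogates
  (`make_surrogates()`); the time-reversal asymmetry statistic
  $\lambda = \langle (x_i - x_{i-\tau})^3\rangle / \langle (x_i -
  x_{i-\tau})^2\rangle$; the average score
  $\gamma = |\bar\lambda/\lambda_0 - 1|$, the coefficient-of-variation
  score $\gamma = |\bar\lambda - \lambda_0| / \sigma_\lambda$ (reject at
  1.96) and rank ordering (`surrogate_test()`); a false-nearest-neighbour
  envelope test (`fnn_discrimination()`).
* **Phase-resetting correction** — every trial is circularly shifted to
  maximize its Pearson correlation with a reference trial
  (`best_shift()`, `align_ensemble()`), turning the stimulus-induced
  permanent phase shift into a measured, correctable quantity.
* **Dendrogram grouping** — Euclidean waveform distances, agglomerative
  trees, cutoff- or count-based groups and group averages
  (`build_dendrogram()`, `cut_dendrogram()`, `group_average()`).
* **Delay embedding** — lag from the autocorrelation first zero and the
  average-mutual-information first minimum (`estimate_lag()`); embedding
  dimension by false nearest neighbours with a Theiler window and an
  attractor-size criterion (`fnn_fraction()`); delay vectors
  $(x_i, x_{i+n}, \ldots, x_{i+(d-1)n})$ via `embed_delay()`.
* **Synthetic experiments** — a Morris-Lecar oscillator with
  phase-dependent resetting by brief current pulses (`simulate_ml()`,
  `phase_resetting_curve()`), LFPs as weighted oscillator sums
  (`synthesize_lfp()`), and full experiment-shaped ensembles with planted
  classes, shifts and noise (`generate_ensemble()`).
* **Pipeline** — `run_pipeline()` chains transient removal, alignment,
  grouping, group-aggregated testing, lag/dimension estimation and
  trajectory export, reproducibly from one seed.

Trials are exchanged as single-column ASCII text files (one sample per
line) listed in a small manifest CSV; see `read_trial()` /
`read_ensemble()`.

## Worked example

```r
library(lfpattractor)

# 1. simulate an experiment-shaped ensemble (fast preset: 2 kHz)
spec <- ensemble_spec_fast(n_trials = 40, noise_sd = 0.02, seed = 42)
gen <- generate_ensemble(spec)
gen$ensemble
#> <lfp_ensemble> 40 trials x 4000 samples, dt = 0.0005 s

# 2. drop the stimulus transient, correct the phase resetting
steady <- ensemble_map(gen$ensemble, drop_transient, t_cut = 0.5)
al <- align_ensemble(steady)
al
#> <alignment_result> 40 trials, reference 'trial_001'
#>   correlation: 0.0151 +/- 0.2954 -> 0.8579 +/- 0.0376
#>   rms error:   0.1588 +/- 0.0446 -> 0.1228 +/- 0.0396

# 3. group the aligned trials
dend <- build_dendrogram(pairwise_distances(al$ensemble))
groups <- cut_dendrogram(dend, k = 5)
groups
#> <group_assignment> 5 groups over 40 trials (sizes: 4, 6, 8, 10, 12)

# 4. surrogate nonlinearity test on an oscillator membrane potential
v <- simulate_ml(duration = 4.1, dt = 1e-3)
tr <- surrogate_test(lfp_ts(v$values[5:4100], dt = 1e-3), n = 100,
                     method = "iaaft", delay = 20, seed = 1)
tr
#> <discrimination_result> lambda0 = -32.32 vs 100 iaaft surrogates
#>   gamma_avg = 0.9877, gamma_cv = 2.235 (threshold 1.96)
#>   rank 1/101; reject (cv) = TRUE; reject (rank) = TRUE

# 5. lag and embedding dimension of a three-dimensional system
x <- simulate_lorenz(10000, dt = 0.01)[, 1]
lag <- estimate_lag(x, max_lag = 300)
lag
#> <lag_estimate> ACF first zero: NA, AMI first minimum: 17, chosen: 17
fnn <- fnn_fraction(x, lag = lag$chosen_lag, dims = 1:5, theiler = 100)
fnn
#> <fnn_curve> lag 17, f = 10, Theiler 100
#>   dim:            1      2      3      4      5
#>   fraction:  0.9959 0.0676 0.0033 0.0000 0.0000
#>   selected d_E = 3 (threshold 0.01)
```

What the numbers mean: before correction the trials barely correlate with
the reference (0.015 on average) because each stimulus reset the ongoing
rhythm by a different amount; after the optimal circular shifts the mean
pair correlation rises to 0.86 and the rms error drops. Cutting the
dendrogram at five groups isolates the planted amplitude classes,
including the low-amplitude minority. The membrane-potential trace is
flagged as nonlinear by both the CV score (2.24 > 1.96) and the rank test
(its statistic is the extreme of the pooled list), while the
false-nearest-neighbour fraction of the three-variable benchmark system
drops below 1% exactly at embedding dimension 3.

`vignettes/lfp-attractor-methods.Rmd` describes the models, parameter
choices and numerical decisions; `inst/scripts/` holds thin command-line
wrappers (`simulate-ensemble.R`, `run-pipeline.R`).

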