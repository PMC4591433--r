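test_that("the unperturbed oscillator settles on a limit cycle", {
  s <- simulate_ml(duration = 2, dt = 1e-4)
  pk <- find_peaks(s)
  expect_gte(length(pk$index), 10)
  ipi <- diff(pk$time)[-1]  # first interval still settling
  expect_lt((max(ipi) - min(ipi)) / mean(ipi), 0.005)
  # deterministic and seed-independent without noise
  s2 <- simulate_ml(duration = 2, dt = 1e-4, seed = 99)
  expect_identical(s$values, s2$values)
})

test_that("the integrator agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  p <- ml_params()
  rhs <- function(t, y, parms) {
    minf <- 0.5 * (1 + tanh((y[1] - p$V1) / p$V2))
    winf <- 0.5 * (1 + tanh((y[1] - p$V3) / p$V4))
    lam <- p$phi * cosh((y[1] - p$V3) / (2 * p$V4))
    dV <- (p$I_bias - p$gCa * minf * (y[1] - p$VCa) -
             p$gK * y[2] * (y[1] - p$VK) - p$gL * (y[1] - p$VL)) / p$C
    list(c(dV, lam * (winf - y[2])))
  }
  times <- seq(0, 500, by = 0.1)  # ms
  ref <- deSolve::lsoda(c(V = -60, w = 0.015), times, rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  mine <- simulate_ml(duration = 0.5, dt = 1e-4)
  expect_lt(max(abs(mine$values - ref[seq_along(mine$values), "V"])), 0.05)
})

test_that("a pulse delays the next peak at phase 0.3 and advances it at 0.5", {
  unpert <- simulate_ml(duration = 1, dt = 1e-4)
  P <- mean(diff(find_peaks(unpert)$time)[-1])
  cyc <- function(phase) {
    st <- stimulus_spec(amplitude = 30, duration = 0.01, phase = phase)
    pert <- simulate_ml(duration = 1, dt = 1e-4, stimulus = st)
    onset <- attr(pert, "stim_onset")
    pk <- find_peaks(pert)$time
    t_k <- max(pk[pk <= onset])
    min(pk[pk > t_k]) - t_k
  }
  expect_gt(cyc(0.3), P * 1.02)  # delayed
  expect_lt(cyc(0.5), P * 0.98)  # advanced
})

test_that("the resetting curve matches direct cycle-length measurement", {
  prc <- phase_resetting_curve(n_phases = 10, duration = 1)
  expect_equal(prc$phase, (0:9) / 10)
  # null perturbation: identically zero
  prc0 <- phase_resetting_curve(stimulus = stimulus_spec(amplitude = 0),
                                n_phases = 5, duration = 1)
  expect_identical(prc0$resetting, rep(0, 5))
  # independent re-measurement from raw peak times
  unpert <- simulate_ml(duration = 1, dt = 1e-4)
  pk0 <- find_peaks(unpert)$time
  P <- mean(diff(pk0)[-1])
  for (i in c(2, 6, 9)) {
    st <- stimulus_spec(amplitude = 30, duration = 0.01,
                        phase = prc$phase[i])
    pert <- simulate_ml(duration = 1, dt = 1e-4, stimulus = st)
    onset <- attr(pert, "stim_onset")
    measure <- function(times) {
      t_k <- max(times[times <= onset + 1e-12])
      after <- times[times > t_k]
      if (length(after) == 0) return(NA_real_)
      min(after) - t_k
    }
    expected <- (measure(pk0) - measure(find_peaks(pert)$time)) / P
    expect_equal(prc$resetting[i], expected, tolerance = 1e-8)
  }
})

test_that("weighted sums behave arithmetically and average out noise", {
  a <- lfp_ts(rnorm(100), dt = 1e-3)
  b <- lfp_ts(rnorm(100), dt = 1e-3)
  expect_equal(synthesize_lfp(list(a), 1)$values, a$values)
  expect_equal(synthesize_lfp(list(a, b), c(2, -1))$values,
               2 * a$values - b$values)
  expect_error(synthesize_lfp(list(a, lfp_ts(rnorm(99), dt = 1e-3)),
                              c(1, 1)), "length")

  # phase-reset noisy traces: the equal-weight average is smoother than
  # any constituent (less power above 100 Hz)
  set.seed(21)
  p <- ml_params(noise_amp = 400)
  phases <- (0:19) / 20
  traces <- lapply(phases, function(ph) {
    s <- simulate_ml(p, duration = 1, dt = 1e-4,
                     stimulus = stimulus_spec(amplitude = 30, phase = ph),
                     seed = sample.int(1e6, 1))
    s$values[5001:10000]  # steady window after the phase-resetting pulse
  })
  avg <- synthesize_lfp(traces, rep(1 / length(traces), length(traces)))
  hp <- vapply(traces, highfreq_power, numeric(1), dt = 1e-4, f_cut = 100)
  expect_lt(highfreq_power(avg, 1e-4, 100), min(hp))
})

test_that("ensembles are reproducible with exact class structure", {
  spec <- ensemble_spec_fast(n_trials = 12, seed = 31)
  g1 <- generate_ensemble(spec)
  g2 <- generate_ensemble(spec)
  expect_identical(ensemble_matrix(g1$ensemble), ensemble_matrix(g2$ensemble))
  expect_identical(g1$truth, g2$truth)
  expect_equal(sort(unique(g1$truth$class)), 1:5)

  # one class, no noise, no shifts: all trials identical
  spec0 <- ensemble_spec_fast(n_trials = 5, noise_sd = 0,
                              group_weights = 1, group_amplitudes = 1,
                              phase_law = "none", seed = 7)
  g0 <- generate_ensemble(spec0)
  m <- ensemble_matrix(g0$ensemble)
  expect_true(all(apply(m, 2, function(col) all(col == col[1]))))

  # two classes at ratio 5.5: class-wise peak-to-peak ratio exact at zero
  # noise
  spec2 <- ensemble_spec_fast(n_trials = 10, noise_sd = 0,
                              group_weights = c(0.5, 0.5),
                              group_amplitudes = c(1, 1 / 5.5), seed = 13)
  g <- generate_ensemble(spec2)
  steady <- ensemble_map(g$ensemble, drop_transient, t_cut = 0.5)
  ptp <- apply(ensemble_matrix(steady), 1, function(v) max(v) - min(v))
  r <- mean(ptp[g$truth$class == 1]) / mean(ptp[g$truth$class == 2])
  expect_equal(r, 5.5, tolerance = 1e-12)

  # class templates identical across trials up to shift (zero noise)
  un <- lapply(seq_len(10), function(i)
    circular_shift(steady$trials[[i]]$values, -g$truth$shift_samples[i]))
  for (cl in 1:2) {
    rows <- which(g$truth$class == cl)
    for (i in rows[-1])
      expect_equal(un[[i]], un[[rows[1]]], tolerance = 1e-12)
  }
})

test_that("ensemble specifications load from YAML and JSON files", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_trials: 7", "dt: 5.0e-4", "noise_sd: 0.01",
               "group_weights: [0.5, 0.5]", "group_amplitudes: [1.0, 0.4]",
               "phase_law: none", "seed: 12",
               "ml:", "  I_bias: 95", "  noise_amp: 20"), path)
  sp <- read_ensemble_spec(path)
  expect_s3_class(sp, "ensemble_spec")
  expect_equal(sp$n_trials, 7L)
  expect_equal(sp$group_amplitudes, c(1, 0.4))
  expect_equal(sp$ml$I_bias, 95)
  g <- generate_ensemble(sp)
  expect_length(g$ensemble, 7)
  expect_true(all(g$truth$shift_samples == 0))
})

test_that("the Lorenz fixture stays on the familiar attractor", {
  lz <- simulate_lorenz(5000, dt = 0.01)
  expect_equal(dim(lz), c(5000, 3))
  # bounded, non-periodic, visits both wings
  expect_true(all(abs(lz[, 1]) < 25))
  expect_gt(sum(lz[, 1] > 5) / 5000, 0.2)
  expect_gt(sum(lz[, 1] < -5) / 5000, 0.2)
})
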