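test_that("circular shift follows index arithmetic and composes", {
  expect_equal(circular_shift(c(1, 2, 3, 4), 1), c(4, 1, 2, 3))
  x <- rnorm(50)
  expect_equal(circular_shift(x, 0), x)
  expect_equal(circular_shift(x, 50), x)
  expect_equal(circular_shift(x, -3), circular_shift(x, 47))
  expect_equal(circular_shift(circular_shift(x, 7), 12),
               circular_shift(x, 19))
  expect_identical(sort(circular_shift(x, 13)), sort(x))
})

test_that("best_shift equals exhaustive search with the same tie rule", {
  set.seed(71)
  for (n in c(32, 127, 256)) {
    x <- rnorm(n)
    y <- circular_shift(x, sample(0:(n - 1), 1)) + rnorm(n, 0, 0.3)
    got <- best_shift(y, x)
    want <- oracle_best_shift(y, x)
    expect_identical(got$shift, want$shift)
    expect_equal(got$corr, want$corr, tolerance = 1e-10)
  }
})

test_that("best_shift recovers constructed shifts and scale invariance", {
  set.seed(72)
  ref <- lfp_ts(cumsum(rnorm(500)), dt = 1e-3)
  expect_identical(best_shift(ref, ref)$shift, 0L)
  expect_equal(best_shift(ref, ref)$corr, 1)

  trial <- circular_shift(ref, 37)
  bs <- best_shift(trial, ref)
  expect_identical(bs$shift, -37L)
  expect_equal(bs$corr, 1, tolerance = 1e-12)

  # same-frequency sines of different amplitude: perfect correlation at the
  # phase-matching shift
  n <- 400
  a <- sin(2 * pi * (0:(n - 1)) / n)
  b <- 3.7 * sin(2 * pi * ((0:(n - 1)) / n + 0.25))
  bs <- best_shift(b, a)
  expect_equal(bs$corr, 1, tolerance = 1e-9)
  expect_identical(bs$shift, 100L)

  expect_error(best_shift(rep(1, 10), rnorm(10)), "constant")
})

test_that("rms error matches closed forms", {
  x <- rnorm(30)
  expect_equal(rms_error(x, x), 0)
  expect_equal(rms_error(x, x + 2), 2)
  expect_equal(rms_error(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_equal(rms_error(c(0, 0), c(3, 4), normalized = FALSE), 5)
  expect_error(rms_error(1:3, 1:4), "length")
})

test_that("alignment never lowers correlation and recovers known shifts", {
  # identical trials: all shifts 0, all correlations 1
  base <- lfp_ts(cumsum(rnorm(300)), dt = 1e-3)
  ens <- lfp_ensemble(lapply(1:4, function(i) base))
  al <- align_ensemble(ens)
  expect_identical(al$result$shift_samples, rep(0L, 4))
  expect_equal(al$result$corr_after, rep(1, 4))

  # known imposed shifts at zero noise: exact recovery relative to trial 1
  spec <- ensemble_spec_fast(n_trials = 10, noise_sd = 0,
                             group_weights = 1, group_amplitudes = 1,
                             seed = 44)
  g <- generate_ensemble(spec)
  steady <- ensemble_map(g$ensemble, drop_transient, t_cut = 0.5)
  n <- length(steady$trials[[1]]$values)
  al <- align_ensemble(steady)
  expected <- (g$truth$shift_samples[1] - g$truth$shift_samples) %% n
  expect_identical(al$result$shift_samples %% n, expected)
  expect_equal(al$result$corr_after, rep(1, 10), tolerance = 1e-9)

  # noisy ensemble: maximization guarantee
  spec2 <- ensemble_spec_fast(n_trials = 8, noise_sd = 0.1, seed = 45)
  g2 <- generate_ensemble(spec2)
  steady2 <- ensemble_map(g2$ensemble, drop_transient, t_cut = 0.5)
  al2 <- align_ensemble(steady2, reference = "medoid")
  expect_true(all(al2$result$corr_after >= al2$result$corr_before - 1e-12))
  expect_equal(al2$result$shift_samples[
    al2$result$trial_id == al2$reference_id], 0L)
})
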