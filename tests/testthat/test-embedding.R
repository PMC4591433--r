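test_that("autocorrelation matches closed forms and noise bounds", {
  # periodic mode on a commensurate sine: exactly cos(2 pi k / P)
  P <- 200; n <- 4000
  sn <- sin(2 * pi * (0:(n - 1)) / P)
  ac <- autocorrelation(sn, 300, mode = "periodic")
  expect_equal(ac$value, cos(2 * pi * (0:300) / P), tolerance = 1e-10)
  expect_equal(ac$value[1], 1)
  fz <- first_zero_lag(ac)
  expect_identical(as.integer(fz), 50L)
  expect_equal(attr(fz, "interpolated"), 50, tolerance = 0.05)

  set.seed(92)
  wn <- rnorm(20000)
  aw <- autocorrelation(wn, 50, mode = "linear")
  expect_true(all(abs(aw$value[-1]) < 3 / sqrt(20000)))

  expect_error(first_zero_lag(data.frame(lag = 0:3,
                                         value = c(1, 0.9, 0.8, 0.7))),
               "max_lag")
  expect_error(autocorrelation(rep(1, 100), 10), "constant")
})

test_that("AMI equals entropy at lag 0 and shows the iid bias scale", {
  set.seed(92)
  n <- 1e5
  wn <- runif(n)
  am <- average_mutual_information(wn, 5, n_bins = 16)
  # lag 0: the diagonal joint gives the histogram entropy
  bin <- pmin(16, floor((wn - min(wn)) / (max(wn) - min(wn)) * 16) + 1)
  p <- tabulate(bin, 16) / n
  expect_equal(am$value[1], -sum(p * log(p)), tolerance = 1e-10)
  # independent pairs: small positive bias about (n_bins-1)^2 / (2N)
  bias <- (16 - 1)^2 / (2 * n)
  expect_true(all(am$value[-1] > 0))
  expect_true(all(am$value[-1] < 3 * bias))
})

test_that("first_min_lag follows its definition", {
  expect_identical(first_min_lag(data.frame(lag = 0:3,
                                            value = c(3, 2, 1, 2))), 2L)
  expect_error(first_min_lag(data.frame(lag = 0:3,
                                        value = c(4, 3, 2, 1))),
               "no local minimum")
})

test_that("delay embedding has the exact count and is lossless", {
  x <- rnorm(10)
  e <- embed_delay(x, lag = 3, dim = 3)
  expect_equal(nrow(e), 4)
  expect_equal(ncol(e), 3)
  expect_equal(e[2, ], c(x[2], x[5], x[8]), ignore_attr = TRUE)
  e1 <- embed_delay(x, lag = 5, dim = 1)
  expect_equal(as.numeric(e1[, 1]), x)
  # first coordinate reconstructs the series prefix
  e2 <- embed_delay(x, lag = 2, dim = 4)
  expect_equal(as.numeric(e2[, 1]), x[1:nrow(e2)])
  # time span per vector
  s <- lfp_ts(rnorm(100), dt = 1e-3)
  e3 <- embed_delay(s, lag = 7, dim = 4)
  expect_equal((attr(e3, "embed_dim") - 1) * attr(e3, "lag") * attr(e3, "dt"),
               3 * 7 * 1e-3)
  expect_error(embed_delay(x, lag = 5, dim = 3), "too short")
})

test_that("FNN fractions agree with the all-pairs brute-force oracle", {
  set.seed(93)
  cases <- list(
    list(x = rnorm(200), lag = 1, theiler = 0),
    list(x = as.numeric(simulate_lorenz(400, dt = 0.05)[, 1]), lag = 2,
         theiler = 10),
    list(x = sin(2 * pi * (0:399) / 40) + rnorm(400, 0, 0.05), lag = 10,
         theiler = 5))
  for (cs in cases) {
    for (d in 1:3) {
      for (f in c(5, 15)) {
        got <- fnn_fraction(cs$x, lag = cs$lag, dims = d, f_ratio = f,
                            theiler = cs$theiler)$fraction
        want <- oracle_fnn_fraction(cs$x, cs$lag, d, f,
                                    theiler = cs$theiler)
        expect_equal(got, want)
      }
    }
  }
})

test_that("FNN unfolds known systems at the right dimension", {
  # a noise-free sine is a planar loop
  sn <- sin(2 * pi * (0:3999) / 200)
  fc <- fnn_fraction(sn, lag = 50, dims = 1:3, f_ratio = 10, theiler = 10)
  expect_lt(fc$fraction[2], 0.01)
  expect_identical(fc$d_E, 2L)

  # Gaussian noise never unfolds (with the size criterion active)
  set.seed(94)
  fw <- fnn_fraction(rnorm(1000), lag = 1, dims = 1:5, f_ratio = 10)
  expect_true(all(fw$fraction > 0.10))
  expect_true(is.na(fw$d_E))

  # Lorenz embeds at 3 (desk-scale check; full-scale scan elsewhere)
  lz <- simulate_lorenz(4000, dt = 0.01)[, 1]
  lag <- first_min_lag(average_mutual_information(lz, 100))
  fl <- fnn_fraction(lz, lag = lag, dims = 1:5, f_ratio = 10, theiler = 50)
  expect_identical(fl$d_E, 3L)
})

test_that("decimation keeps the FNN decision while halving the lag", {
  sn <- sin(2 * pi * (0:7999) / 200) + 0.01 * sin(2 * pi * (0:7999) / 37)
  full <- fnn_fraction(sn, lag = 50, dims = 1:3, f_ratio = 10, theiler = 10)
  half <- fnn_fraction(sn, lag = 50, dims = 1:3, f_ratio = 10, theiler = 10,
                       decimate = 2)
  expect_equal(half$lag, 25L)
  expect_identical(full$d_E, half$d_E)
})

test_that("a wider Theiler window never lowers FNN on deterministic data", {
  lz <- simulate_lorenz(2000, dt = 0.01)[, 1]
  for (d in 2:3) {
    f0 <- fnn_fraction(lz, lag = 15, dims = d, f_ratio = 10,
                       theiler = 0)$fraction
    f1 <- fnn_fraction(lz, lag = 15, dims = d, f_ratio = 10,
                       theiler = (d - 1) * 15)$fraction
    expect_gte(f1, f0)
  }
})

test_that("estimate_lag reports both estimators and prefers the AMI", {
  lz <- simulate_lorenz(5000, dt = 0.01)[, 1]
  le <- estimate_lag(lz, max_lag = 400)
  expect_s3_class(le, "lag_estimate")
  expect_identical(le$chosen_lag, le$ami_first_min)
  expect_true(is.na(le$acf_first_zero) || le$acf_first_zero >= 1)
})
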