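# Independent brute-force oracles, written without reference to the
# package's production code paths.

# Exhaustive best circular shift: try every k, compute the Pearson
# correlation directly, apply the tie rule (smallest |k|, positive first).
oracle_best_shift <- function(trial, reference) {
  a <- if (inherits(reference, "lfp_ts")) reference$values else reference
  b <- if (inherits(trial, "lfp_ts")) trial$values else trial
  n <- length(a)
  corrs <- vapply(0:(n - 1), function(k) {
    idx <- ((seq_len(n) - 1 - k) %% n) + 1
    cor(a, b[idx])
  }, numeric(1))
  m <- max(corrs)
  cand <- which(corrs >= m - 1e-9 * max(1, abs(m))) - 1
  ks <- ifelse(cand > n / 2, cand - n, cand)
  ks <- ks[order(abs(ks), ks <= 0)]
  list(shift = as.integer(ks[1]), corr = corrs[(ks[1] %% n) + 1])
}

# All-pairs false-nearest-neighbour fraction, built on a full distance
# matrix instead of a scan, with the same neighbour and falseness rules.
oracle_fnn_fraction <- function(x, lag, d, f_ratio, theiler = 0,
                                sigma_criterion = TRUE, sigma_mult = 2) {
  n <- length(x)
  m <- n - d * lag
  emb <- sapply(0:(d - 1), function(j) x[(1:m) + j * lag])
  if (m == 1) emb <- matrix(emb, nrow = 1)
  dm <- as.matrix(dist(emb))
  sep <- abs(outer(seq_len(m), seq_len(m), "-"))
  dm[sep <= theiler] <- Inf
  nxt <- x[(1:m) + d * lag]
  sig <- sd(x)
  eps <- 1e-8 * sig
  n_false <- 0L; n_valid <- 0L
  for (i in seq_len(m)) {
    j <- which.min(dm[i, ])          # ties -> smallest index, as in scan
    if (!is.finite(dm[i, j])) next
    n_valid <- n_valid + 1L
    rd <- dm[i, j]
    dl <- abs(nxt[i] - nxt[j])
    false <- (dl / max(rd, eps)) > f_ratio
    if (sigma_criterion) false <- false || sqrt(rd^2 + dl^2) > sigma_mult * sig
    if (false) n_false <- n_false + 1L
  }
  n_false / n_valid
}

# Brute-force average-linkage (UPGMA) agglomeration on a small distance
# matrix; returns the merge heights in order.
oracle_upgma_heights <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  repeat {
    if (length(active) < 2) break
    best <- c(NA, NA); bh <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      a <- active[ii]; b <- active[jj]
      if (D[a, b] < bh) { bh <- D[a, b]; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    heights <- c(heights, bh)
    # UPGMA update: size-weighted average distance to the merged cluster
    newd <- (sizes[a] * D[a, ] + sizes[b] * D[b, ]) / (sizes[a] + sizes[b])
    D[a, ] <- newd; D[, a] <- newd; D[a, a] <- 0
    sizes[a] <- sizes[a] + sizes[b]
    active <- setdiff(active, b)
  }
  heights
}

# Adjusted Rand index between two labelings.
adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * cc / choose(n, 2)
  maxi <- (b + cc) / 2
  if (maxi == expected) return(1)
  (a - expected) / (maxi - expected)
}

# Stationary Gaussian AR(2) series with the oscillatory coefficients used
# throughout the calibration checks.
ar2_series <- function(n, ar = c(1.6, -0.8)) {
  as.numeric(stats::arima.sim(model = list(ar = ar), n = n))
}

# Power of a series above a frequency cutoff (fraction-free absolute sum),
# used to compare smoothness of traces.
highfreq_power <- function(x, dt, f_cut) {
  n <- length(x)
  sp <- Mod(fft(x - mean(x)))^2 / n
  freqs <- (0:(n - 1)) / (n * dt)
  sum(sp[freqs > f_cut & freqs < 1 / (2 * dt)])
}
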