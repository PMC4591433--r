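mk_ens <- function(m, dt = 1e-3) {
  lfp_ensemble(lapply(seq_len(nrow(m)), function(i) lfp_ts(m[i, ], dt = dt)))
}

test_that("pairwise distances are Euclidean and metric", {
  ens <- mk_ens(rbind(c(0, 0), c(3, 4), c(0, 0)))
  d <- as.matrix(pairwise_distances(ens))
  expect_equal(d[1, 2], 5)
  expect_equal(d[1, 3], 0)
  expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)
  expect_equal(d, t(d))

  set.seed(81)
  dd <- as.matrix(pairwise_distances(mk_ens(matrix(rnorm(60), 6))))
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(dd[i, j], dd[i, k] + dd[k, j] + 1e-12)
})

test_that("dendrogram construction matches a brute-force UPGMA oracle", {
  # two trials: one merge at their distance, any linkage
  ens <- mk_ens(rbind(c(0, 0, 0), c(1, 2, 2)))
  for (lk in c("average", "single", "complete", "ward")) {
    dd <- build_dendrogram(pairwise_distances(ens), linkage = lk)
    expect_equal(nrow(dd$merges), 1)
    expect_equal(dd$merges$height, 3)
  }

  set.seed(82)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    m <- matrix(rnorm(n * 10), n)
    D <- dist(m)
    dd <- build_dendrogram(D, linkage = "average")
    expect_equal(dd$merges$height, oracle_upgma_heights(D),
                 tolerance = 1e-10)
    expect_equal(nrow(dd$merges), n - 1)
    # monotone heights for average linkage
    expect_true(all(diff(dd$merges$height) >= -1e-12))
  }
})

test_that("cutting the tree yields the expected group structure", {
  # two tight blobs far apart
  set.seed(83)
  m <- rbind(matrix(rnorm(5 * 20, 0, 0.1), 5),
             matrix(rnorm(4 * 20, 10, 0.1), 4))
  dd <- build_dendrogram(dist(m))
  expect_gt(max(dd$merges$height),
            10 * sort(dd$merges$height, decreasing = TRUE)[2])

  # cutoff above the root: one group
  one <- cut_dendrogram(dd, cutoff = max(dd$merges$height) + 1)
  expect_equal(unique(one$labels), 1L)
  # cutoff below all merges: all singletons
  sing <- cut_dendrogram(dd, cutoff = min(dd$merges$height) / 2)
  expect_equal(length(unique(sing$labels)), 9)
  # the 2-group cut recovers the blobs
  two <- cut_dendrogram(dd, k = 2)
  expect_equal(adjusted_rand_index(two$labels, rep(1:2, c(5, 4))), 1)

  expect_error(cut_dendrogram(dd, k = 99), "invalid")
  expect_error(cut_dendrogram(dd), "exactly one")
})

test_that("cuts are nested: k-1 groups merge exactly two of the k groups", {
  set.seed(84)
  m <- matrix(rnorm(12 * 30), 12)
  dd <- build_dendrogram(dist(m))
  for (k in 6:2) {
    gk <- cut_dendrogram(dd, k = k)$labels
    gk1 <- cut_dendrogram(dd, k = k - 1)$labels
    # each k-group maps into exactly one (k-1)-group
    expect_true(all(tapply(gk1, gk, function(v) length(unique(v))) == 1))
    # and exactly two of the k groups share a (k-1)-group
    expect_equal(sum(table(tapply(gk1, gk, unique)) == 2), 1)
  }
})

test_that("group averages are pointwise means with expected invariances", {
  ens <- mk_ens(rbind(c(0, 2), c(2, 0), c(5, 5)))
  avg <- group_average(ens, c(1, 1, 2))
  expect_equal(avg$group_1$values, c(1, 1))
  expect_equal(avg$group_2$values, c(5, 5))

  # averaging commutes with a common circular shift
  set.seed(85)
  m <- matrix(rnorm(4 * 40), 4)
  base <- group_average(mk_ens(m), rep(1, 4))$group_1$values
  shifted <- group_average(mk_ens(t(apply(m, 1, circular_shift, k = 11))),
                           rep(1, 4))$group_1$values
  expect_equal(shifted, circular_shift(base, 11))

  expect_error(group_average(mk_ens(m), c(1, 1)), "one label per trial")
})

test_that("the five-class operating point is recovered by cut height or k", {
  spec <- ensemble_spec_fast(n_trials = 50, noise_sd = 0.01, seed = 77)
  g <- generate_ensemble(spec)
  st <- ensemble_map(g$ensemble, drop_transient, t_cut = 0.5)
  al <- align_ensemble(st)
  dd <- build_dendrogram(pairwise_distances(al$ensemble))
  cut5 <- cut_dendrogram(dd, k = 5)
  expect_equal(adjusted_rand_index(cut5$labels, g$truth$class), 1)
  # a height cutoff inside the 5-group window gives the same partition
  h <- sort(dd$merges$height, decreasing = TRUE)
  cutoff <- (h[4] + h[5]) / 2
  cut_h <- cut_dendrogram(dd, cutoff = cutoff)
  expect_equal(adjusted_rand_index(cut_h$labels, cut5$labels), 1)
  expect_equal(length(cut_h$group_sizes), 5)
})

test_that("grouping moves each trial closer to its own template", {
  # separable two-class ensemble: rms to own group mean beats rms to the
  # global reference used for alignment
  spec <- ensemble_spec_fast(n_trials = 16, noise_sd = 0.03,
                             group_weights = c(0.5, 0.5),
                             group_amplitudes = c(1, 0.3), seed = 86)
  g <- generate_ensemble(spec)
  steady <- ensemble_map(g$ensemble, drop_transient, t_cut = 0.5)
  al <- align_ensemble(steady)
  cut <- cut_dendrogram(build_dendrogram(pairwise_distances(al$ensemble)),
                        k = 2)
  expect_equal(adjusted_rand_index(cut$labels, g$truth$class), 1)
  avg <- group_average(al$ensemble, cut)
  ref <- al$ensemble$trials[[1]]
  for (i in 2:16) {  # the reference trial is trivially at rms 0 to itself
    own <- avg[[cut$labels[i]]]
    expect_lte(rms_error(al$ensemble$trials[[i]], own),
               rms_error(al$ensemble$trials[[i]], ref) + 1e-9)
  }
})
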