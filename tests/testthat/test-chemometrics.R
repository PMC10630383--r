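# Standardization, varimax PCA, Ward clustering and the Sneath cut, checked
# against brute-force oracles.

test_that("z-scores have mean 0, sd 1 and are affine invariant", {
  tab <- generate_samples(synthetic_config(seed = 23))
  z <- zscore(tab)
  expect_true(all(abs(colMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-12))
  expect_equal(unname(zscore(data.frame(x = c(1, 2, 3)))[, 1]), c(-1, 0, 1))
  # an affine transform of a column leaves its z-scores unchanged
  df <- as.data.frame(tab)
  df$Ca <- 3.2 * df$Ca + 17
  expect_equal(zscore(sample_table(df))[, "Ca"], z[, "Ca"], tolerance = 1e-12)
  df$Ca <- 5
  expect_error(zscore(sample_table(df)), "Ca")
})

test_that("PCA eigenvalues match the power-iteration oracle", {
  set.seed(41)
  for (i in 1:5) {
    X <- matrix(rnorm(200), 50, 4)
    R <- cor(X)
    p <- pca_varimax(scale(X), retain = 2)
    expect_equal(p$eigenvalues, power_eigen_oracle(R), tolerance = 1e-8)
  }
})

test_that("correlation PCA conserves trace and handles rank-1 structure", {
  tab <- generate_samples(synthetic_config(seed = 25))
  p <- pca_varimax(zscore(tab))
  expect_equal(sum(p$eigenvalues), 13, tolerance = 1e-9)
  expect_true(all(p$communalities >= 0 & p$communalities <= 1 + 1e-9))
  expect_equal(p$percent_variance,
               100 * p$eigenvalues / 13, tolerance = 1e-12)
  # two perfectly correlated variables: eigenvalues {2, 0}
  x <- rnorm(30)
  p2 <- pca_varimax(scale(cbind(a = x, b = 2 * x + 1)), retain = 1)
  expect_equal(p2$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_true(p2$rotation_skipped)
})

test_that("varimax rotation preserves communalities and flips signs positive", {
  tab <- generate_samples(synthetic_config(seed = 26))
  p <- pca_varimax(zscore(tab))
  expect_gte(p$retained, 2)
  before <- rowSums(p$loadings[, seq_len(p$retained), drop = FALSE]^2)
  expect_equal(unname(p$communalities), unname(before), tolerance = 1e-8)
  # each rotated component's largest-magnitude loading is positive
  for (j in seq_len(ncol(p$rotated))) {
    expect_gt(p$rotated[which.max(abs(p$rotated[, j])), j], 0)
  }
})

test_that("Ward merges match exhaustive ESS minimization for small n", {
  set.seed(52)
  for (i in 1:6) {
    n <- sample(4:8, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    wc <- ward_cluster(x, k = 2)
    oracle <- ess_ward_oracle(x)
    expect_equal(wc$heights, oracle$heights, tolerance = 1e-9)
    # the two-group partitions agree (penultimate oracle partition)
    oracle_two <- canonical_partition(oracle$partitions[[n - 2L]])
    ours_two <- canonical_partition(partition_sets(wc$assignments))
    expect_equal(ours_two, oracle_two)
  }
})

test_that("Ward heights are monotone and degenerate merges come first", {
  x <- rbind(c(0, 0), c(0, 0), c(5, 5), c(9, 1))
  wc <- ward_cluster(x, k = 2)
  expect_equal(wc$heights[1], 0)                     # identical pair merges at 0
  expect_true(all(diff(wc$heights) >= -1e-12))       # monotone agglomeration
  expect_equal(sort(unique(wc$assignments[1:2])), unique(wc$assignments[1:2]))
  expect_equal(wc$assignments[1], wc$assignments[2]) # coincident pair together
  tab <- generate_samples(synthetic_config(seed = 27))
  wcz <- ward_cluster(zscore(tab))
  expect_true(all(diff(wcz$heights) >= -1e-9))
  expect_equal(max(wcz$quotient), 100)
})

test_that("Sneath threshold cuts yield the expected cluster counts", {
  set.seed(61)
  # three well-separated blobs
  x <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
             matrix(rnorm(10, 10, 0.1), 5, 2),
             matrix(rnorm(10, c(0, 20), 0.1), 5, 2))
  wc <- ward_cluster(x, k = 3)
  expect_equal(sneath_significance(wc, 100), 1)         # root: one cluster
  expect_equal(sneath_significance(wc, 1e-6), nrow(x))  # below all merges
  expect_equal(sneath_significance(wc, 66.6), 3)        # between the blobs
})

test_that("cluster profiles reduce to means and flag extremes", {
  tab <- generate_samples(synthetic_config(n_samples = 6, seed = 28))
  one <- cluster_profile(tab, rep(1, 6))
  expect_equal(one$means$C1,
               unname(colMeans(as.data.frame(tab)[, canonical_parameters()])))
  two <- cluster_profile(tab[1:2, ], c(1, 2))
  expect_equal(two$means$C1,
               unname(unlist(as.data.frame(tab)[1, canonical_parameters()])))
  wc <- ward_cluster(zscore(tab), k = 3)
  prof <- cluster_profile(tab, wc$assignments)
  # per parameter: exactly one highest and one lowest among 3 clusters
  for (p in rownames(prof$means)) {
    fl <- unlist(prof$flags[p, ])
    expect_equal(sum(fl == "highest"), 1)
    expect_equal(sum(fl == "lowest"), 1)
    expect_equal(unname(prof$means[p, fl == "highest"]),
                 max(unlist(prof$means[p, ])))
  }
})
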