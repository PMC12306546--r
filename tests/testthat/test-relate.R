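test_that("eigenvector features are block-supported with positive sign convention", {
  C <- scv_block_cov(block_spec(list(1:2, 3:4), rho = 0.5, K = 4))
  F <- build_features(list(pop_cov_estimate(C)), d_hat = 2)
  expect_identical(dim(F), c(4L, 2L))
  for (j in 1:2) {
    support <- which(abs(F[, j]) > 1e-10)
    expect_true(identical(support, 1:2) || identical(support, 3:4))
    expect_true(all(F[support, j] > 0))
  }
  expect_equal(colSums(F^2), c(1, 1), tolerance = 1e-12)
  expect_identical(attr(F, "provenance")$rank, c(1L, 2L))
})

test_that("reference design yields thirteen feature columns and row equivariance", {
  des <- scv_design(rho = 0.2, noise_sd = 0)
  covs <- lapply(des$specs[-1], function(s) pop_cov_estimate(scv_block_cov(s)))
  F <- build_features(covs, des$true_d[-1])
  expect_identical(ncol(F), 13L) # 2 + 2 + 2 + 3 + 4
  expect_identical(nrow(F), 10L)

  # equivariance needs a simple spectrum: perturbed block correlations keep
  # eigenvectors unique up to sign, which the sign convention then fixes
  des_n <- scv_design(rho = 0.2, noise_sd = 0.05)
  covs_n <- lapply(seq(2, 6), function(r) {
    pop_cov_estimate(scv_block_cov(des_n$specs[[r]], seed = 50 + r))
  })
  F_n <- build_features(covs_n, des_n$true_d[-1])
  perm <- c(3, 1, 10, 4, 6, 5, 2, 9, 7, 8)
  covs_p <- lapply(covs_n, function(ce) pop_cov_estimate(ce$C[perm, perm]))
  F_p <- build_features(covs_p, des_n$true_d[-1])
  expect_equal(F_p, F_n[perm, ], tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(build_features(list()), "no structured SCVs")
})

test_that("Ward clustering of ground-truth features reproduces the known topology", {
  des <- scv_design(rho = 0.2, noise_sd = 0)
  covs <- lapply(des$specs[-1], function(s) pop_cov_estimate(scv_block_cov(s)))
  F <- build_features(covs, des$true_d[-1])
  rs <- relate_cluster(F, n_clusters = 3, true_labels = des$true_labels)
  expect_identical(rs$labels, c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L))
  expect_equal(rs$ami, 1)
  # merge heights are non-decreasing (Ward monotonicity)
  expect_false(is.unsorted(rs$heights))
  # cutting at two clusters separates datasets 1-4 from 5-10: the groups
  # 5-7 and 8-10 merge with each other before joining 1-4
  two <- extract_labels(rs, 2)
  expect_identical(two, rep(c(1L, 2L), c(4, 6)))
})

test_that("clustering handles tiny and degenerate feature matrices", {
  F2 <- matrix(c(0, 1, 0, 1), 2, 2)
  rs2 <- relate_cluster(F2, n_clusters = 2)
  expect_identical(rs2$labels, c(1L, 2L))
  expect_identical(nrow(rs2$merges), 1L)

  Fd <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0.5, 0.5))
  rsd <- relate_cluster(Fd)
  expect_equal(rsd$heights[1], 0) # duplicated rows merge first at height 0
  expect_error(relate_cluster(matrix(c(1, NA, 0, 1), 2, 2)), "non-finite")

  rs <- relate_cluster(diag(4))
  expect_identical(extract_labels(rs, 4), 1:4)
  expect_identical(extract_labels(rs, 1), rep(1L, 4))
})

test_that("gap heuristic recovers the natural number of clusters", {
  # features from the two- and three-block SCVs partition the datasets into
  # exactly three groups of identical rows
  des <- scv_design(rho = 0.2, noise_sd = 0)
  covs <- lapply(des$specs[c(2, 5)], function(s) pop_cov_estimate(scv_block_cov(s)))
  rs <- relate_cluster(build_features(covs, c(2, 3)))
  labs <- extract_labels(rs)
  expect_identical(labs, c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L))
})

test_that("adjusted mutual information matches an independent reference", {
  truth <- c(1, 1, 1, 1, 2, 2, 2, 3, 3, 3)
  expect_equal(ami(truth, truth), 1)
  expect_equal(ami(truth, c(2, 2, 2, 2, 3, 3, 3, 1, 1, 1)), 1) # relabeling
  # reference values from scikit-learn's AMI (max normalisation)
  expect_equal(ami(truth, c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3)), 0.7191685458,
               tolerance = 1e-9)
  expect_equal(ami(c(1, 1, 2, 2, 3, 3), c(1, 1, 1, 2, 2, 2)), 0.2250422832,
               tolerance = 1e-9)
  expect_equal(ami(c(1, 2, 3, 4), c(1, 1, 2, 2)), 0, tolerance = 1e-12)
  expect_equal(ami(c(1, 1, 1, 2, 2, 2, 3, 3), c(1, 2, 1, 2, 1, 2, 1, 2)),
               -0.1587769248, tolerance = 1e-9)
  expect_error(ami(1:3, 1:4), "equal length")
})

test_that("AMI of independent labelings is near zero", {
  set.seed(5)
  a <- sample(1:3, 1000, replace = TRUE)
  b <- sample(1:4, 1000, replace = TRUE)
  expect_lt(abs(ami(a, b)), 0.05)
})

test_that("recovery metrics count exact hits and averages", {
  rm <- recovery_metrics(matrix(c(2, 2, 2, 3), ncol = 1), d_true = 2)
  expect_equal(rm$p_correct, 0.75)
  expect_equal(rm$mean_d, 2.25)

  runs <- rbind(c(1, 2), c(1, 2), c(1, 3))
  rm2 <- recovery_metrics(runs, c(1, 2))
  expect_equal(rm2$p_correct, c(1, 2 / 3))
  # P equals 1 - normalised Hamming error of the estimate sequence
  expect_equal(rm2$p_correct,
               1 - colMeans(sweep(runs, 2, c(1, 2), `!=`)))
})

test_that("Newick export writes one leaf per dataset", {
  rs <- relate_cluster(diag(4))
  nwk <- export_newick(rs)
  expect_match(nwk, "^\\(")
  expect_identical(length(gregexpr("dataset", nwk)[[1]]), 4L)
})
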