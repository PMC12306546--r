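test_that("block_spec validates its invariants", {
  expect_s3_class(block_spec(list(1:4, 5:7), rho = 0.2, K = 10), "block_spec")
  expect_error(block_spec(list(1:4, 4:6), rho = 0.2, K = 10), "disjoint")
  expect_error(block_spec(list(1:4, 11:12), rho = 0.2, K = 10), "1..K")
  expect_error(block_spec(list(1:4, list(5)[[1]]), rho = 0.2, K = 10), ">= 2")
  expect_error(block_spec(list(1:4), rho = 1.2, K = 10))
  expect_error(block_spec(list(1:4), rho = 0.2, K = 10, noise_sd = -1))
})

test_that("noiseless block covariance has exactly d eigenvalues above one", {
  # equicorrelated (common) case: top eigenvalue 1 + (K-1) rho
  C <- scv_block_cov(block_spec(list(1:10), rho = 0.2, K = 10))
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(max(ev), 1 + 9 * 0.2, tolerance = 1e-12)
  expect_identical(count_above_one(C), 1L)
  expect_true(all(C[upper.tri(C)] == 0.2))

  # three-block case and the full reference design
  C5 <- scv_block_cov(block_spec(list(1:4, 5:7, 8:10), rho = 0.2, K = 10))
  expect_identical(count_above_one(C5), 3L)

  des <- scv_design(rho = 0.2, noise_sd = 0)
  counts <- vapply(des$specs, function(s) count_above_one(scv_block_cov(s)),
                   integer(1))
  expect_identical(counts, c(1L, 2L, 2L, 2L, 3L, 4L))
})

test_that("within-block noise is symmetric, reproducible, and rarely changes the count", {
  spec <- block_spec(list(1:4, 5:7, 8:10), rho = 0.2, K = 10, noise_sd = 0.05)
  C1 <- scv_block_cov(spec, seed = 5)
  C2 <- scv_block_cov(spec, seed = 5)
  expect_identical(C1, C2)
  expect_equal(C1, t(C1))
  expect_equal(diag(C1), rep(1, 10))
  expect_false(identical(C1, scv_block_cov(spec, seed = 6)))
  # off-block entries untouched by noise
  expect_true(all(C1[1:4, 5:10] == 0))

  counts <- vapply(seq_len(1000), function(i) {
    count_above_one(scv_block_cov(spec, seed = i))
  }, integer(1))
  expect_gte(mean(counts == 3L), 0.99)
})

test_that("reference design matches its printed constraints", {
  des <- scv_design(rho = 0.2)
  expect_identical(des$R, 6L)
  expect_identical(des$K, 10L)
  expect_identical(des$V, 1000L)
  expect_identical(des$true_d, c(1L, 2L, 2L, 2L, 3L, 4L))
  expect_identical(des$true_labels, c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L))
  expect_equal(des$noise_sd^2, 0.0025)
  uncorrelated <- vapply(des$specs, scvrelate:::n_uncorrelated, integer(1))
  expect_identical(uncorrelated, c(0L, 0L, 1L, 4L, 0L, 0L))
  # true_d is consistent with the block counts
  expect_identical(des$true_d,
                   vapply(des$specs, function(s) length(s$blocks), integer(1)))
})

test_that("positive-definiteness repair fails loudly when impossible", {
  spec <- block_spec(list(1:8), rho = 0.9, K = 8, noise_sd = 2)
  expect_error(scv_block_cov(spec, seed = 1, max_redraw = 3), "positive-definite")
})
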