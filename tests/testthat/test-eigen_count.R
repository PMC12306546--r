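test_that("absolute sample covariance has unit diagonal and absorbs sign flips", {
  x <- rnorm(200)
  S <- rbind(x, -x)
  ce <- scv_covariance(S)
  expect_equal(ce$C, matrix(1, 2, 2), ignore_attr = TRUE)
  expect_equal(ce$values, c(2, 0), tolerance = 1e-12)

  S6 <- sample_laplacian_scv(diag(6), V = 2000, seed = 1)
  ce6 <- scv_covariance(S6)
  expect_equal(diag(ce6$C), rep(1, 6), tolerance = 1e-12)
  expect_true(all(ce6$C >= 0 & ce6$C <= 1 + 1e-12))
  expect_equal(sum(ce6$values), 6, tolerance = 1e-10) # trace preserved
  expect_false(is.unsorted(rev(ce6$values)))
  expect_error(scv_covariance(rbind(x, 0 * x)), "zero variance")
})

test_that("leading eigenvalue of a sampled equicorrelated block is near closed form", {
  C <- scv_block_cov(block_spec(list(1:4), rho = 0.5, K = 4))
  lead <- vapply(1:5, function(s) {
    scv_covariance(sample_laplacian_scv(C, V = 1000, seed = s))$values[1]
  }, numeric(1))
  expect_lt(max(abs(lead - 2.5)), 0.15) # 1 + 3 * 0.5
})

test_that("test configuration computes eta and rejects impossible settings", {
  cfg <- test_config(B = 1000, Pfa = 0.05)
  expect_identical(cfg$eta, 950L) # floor(1001 * 0.95)
  expect_error(test_config(B = 0), "B >= 1")
  expect_error(test_config(B = 1, Pfa = 0.6), "eta")
})

test_that("bootstrap count recovers block counts on clear structures", {
  C <- scv_block_cov(block_spec(list(1:3, 4:6), rho = 0.6, K = 6))
  S <- sample_laplacian_scv(C, V = 1000, seed = 2)
  ct <- bootstrap_count(S, test_config(B = 500, Pfa = 0.05, seed = 3))
  expect_identical(ct$d_hat, 2L)
  expect_identical(sum(ct$epsilon), ct$d_hat)
  expect_length(ct$threshold, 6)
  # rejection flags follow the tie-rejects comparison exactly
  expect_identical(ct$epsilon, as.integer(ct$T_hat >= ct$threshold))
})

test_that("bootstrap count is reproducible and invariant to signs and column order", {
  C <- scv_block_cov(block_spec(list(1:3, 4:6), rho = 0.4, K = 6))
  S <- sample_laplacian_scv(C, V = 800, seed = 4)
  cfg <- test_config(B = 300, Pfa = 0.05, seed = 11)
  ct1 <- bootstrap_count(S, cfg)
  expect_identical(bootstrap_count(S, cfg)$epsilon, ct1$epsilon)

  S_flip <- S * c(1, -1, 1, -1, -1, 1)
  expect_identical(bootstrap_count(S_flip, cfg)$d_hat, ct1$d_hat)

  set.seed(99)
  S_perm <- S[, sample(ncol(S))]
  expect_identical(bootstrap_count(S_perm, cfg)$d_hat, ct1$d_hat)
})

test_that("direct eigenvalue counting uses a strict boundary and overestimates", {
  fake <- pop_cov_estimate(diag(c(2.8, 1.0, 0.9, 0.3)))
  expect_identical(ev_count(fake), 1L)

  des <- scv_design(rho = 0.2, noise_sd = 0)
  pop_counts <- vapply(des$specs, function(s) {
    ev_count(pop_cov_estimate(scv_block_cov(s)))
  }, integer(1))
  expect_identical(pop_counts, c(1L, 2L, 2L, 2L, 3L, 4L))

  # finite samples push spurious eigenvalues of C4 above one
  des2 <- scv_design(rho = 0.2)
  ev4 <- vapply(1:10, function(s) {
    sim <- simulate_scvs(des2, seed = 200 + s)
    ev_count(scv_covariance(sim$sources[[4]]))
  }, integer(1))
  expect_true(all(ev4 >= 2))
  expect_gt(mean(ev4), 2)
})

test_that("classification splits common and structured SCVs and warns on d = 0", {
  sets <- classify_scvs(c(1, 2, 2, 2, 3, 4))
  expect_identical(sets$common, 1L)
  expect_identical(sets$structured, 2:6)
  expect_length(sets$excluded, 0)

  expect_warning(sets0 <- classify_scvs(c(0, 2)), "d_hat = 0")
  expect_length(sets0$common, 0)
  expect_identical(sets0$structured, 2L)
  expect_identical(sets0$excluded, 1L)
})
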