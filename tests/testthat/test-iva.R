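test_that("joint ISI is zero iff demixing matches up to shared permutation and scale", {
  set.seed(1)
  A <- replicate(4, matrix(rnorm(25), 5, 5), simplify = FALSE)
  expect_equal(joint_isi(lapply(A, solve), A), 0, tolerance = 1e-12)

  P <- diag(5)[c(3, 1, 5, 2, 4), ] * c(2, -1, 0.5, 1, 3)
  W_perm <- lapply(A, function(a) P %*% solve(a))
  expect_equal(joint_isi(W_perm, A), 0, tolerance = 1e-12)

  ones <- replicate(4, matrix(1, 5, 5), simplify = FALSE)
  id <- replicate(4, diag(5), simplify = FALSE)
  expect_equal(joint_isi(ones, id), 1)
})

test_that("objective is invariant to row scaling and SCV permutation", {
  mx <- quick_mixture(V = 300, seed = 2)
  set.seed(3)
  W <- replicate(10, qr.Q(qr(matrix(rnorm(36), 6, 6))), simplify = FALSE)
  J0 <- iva_objective(W, mx$X)
  expect_true(is.finite(J0))

  # scale one demixing row (the profiled SCV covariance absorbs it)
  W_s <- W
  W_s[[4]][2, ] <- 2 * W_s[[4]][2, ]
  expect_equal(iva_objective(W_s, mx$X), J0, tolerance = 1e-8)

  # permute the SCV order identically in every dataset
  W_p <- lapply(W, function(w) w[c(6, 1, 3, 2, 5, 4), ])
  expect_equal(iva_objective(W_p, mx$X), J0, tolerance = 1e-10)
})

test_that("objective prefers the planted demixing over random ones", {
  wins <- vapply(1:20, function(s) {
    mx <- simulate_mixture(scv_design(rho = 0.5, V = 300), seed = 100 + s)
    J_true <- iva_objective(lapply(mx$A, solve), mx$X)
    set.seed(s)
    W_rand <- replicate(10, matrix(rnorm(36), 6, 6), simplify = FALSE)
    J_true <= iva_objective(W_rand, mx$X)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("identity initialisation on unmixed data is a near fixed point", {
  des <- scv_design(rho = 0.8, V = 500)
  sim <- simulate_scvs(des, seed = 7)
  eye <- replicate(10, diag(6), simplify = FALSE)
  mx <- mix_sources(sim$sources, mixing = eye, design = des)
  fit <- iva_l_sos(mx$X, max_iter = 800, tol = 1e-5, W_init = "identity")
  expect_true(fit$converged)
  # total objective decrease from the identity start is marginal
  expect_lt(fit$objective_trajectory[1] - min(fit$objective_trajectory), 0.5)
  # stays within a permutation/scaling of identity: perfect demixing
  expect_lt(joint_isi(fit$W, mx$A), 0.05)
  expect_true(all(diff(fit$objective_trajectory) <= 1e-10))
})

test_that("IVA recovers a planted mixture and normalizes source variances", {
  mx <- quick_mixture(rho = 0.8, V = 500, seed = 5)
  fit <- iva_l_sos(mx$X, max_iter = 600, tol = 1e-6, seed = 2)
  expect_lt(joint_isi(fit$W, mx$A), 0.05)
  # estimated source rows have unit sample variance (1/V convention)
  v <- vapply(fit$S, function(s) range(rowSums(s^2) / ncol(s)), numeric(2))
  expect_equal(as.numeric(v), rep(1, length(v)), tolerance = 1e-8)
  # source-to-SCV reshaping is lossless: SCV r row k equals source k row r
  expect_identical(fit$scvs[[3]][2, ], fit$S[[2]][3, ])
})

test_that("rank-deficient data fail with guidance towards PCA", {
  X <- replicate(3, {
    m <- matrix(rnorm(4 * 100), 4, 100)
    m[4, ] <- m[1, ] + m[2, ]
    m
  }, simplify = FALSE)
  expect_error(iva_l_sos(X, max_iter = 5), "rank-deficient")
})

test_that("ensemble distances vanish for permutation/sign-equivalent runs", {
  mx <- quick_mixture(rho = 0.8, V = 400, seed = 6)
  fit <- iva_l_sos(mx$X, max_iter = 300, tol = 1e-5, seed = 3)
  flip <- c(1, -1, 1, -1, -1, 1)
  perm <- c(4, 2, 6, 1, 3, 5)
  twin <- fit
  twin$S <- lapply(fit$S, function(s) (flip * s)[perm, ])
  expect_equal(scvrelate:::run_distance(fit, twin), 0, tolerance = 1e-10)

  ens1 <- iva_ensemble(mx$X, n_runs = 1, seed = 8, max_iter = 200, tol = 1e-5)
  expect_identical(ens1$selected, 1L)
  expect_identical(ens1$pairwise_distance, matrix(0, 1, 1))
})

test_that("consistency selection picks a run no worse than the median", {
  mx <- quick_mixture(rho = 0.5, V = 500, seed = 9)
  ens <- iva_ensemble(mx$X, n_runs = 5, seed = 10, max_iter = 400, tol = 1e-5)
  isis <- vapply(ens$runs, joint_isi, numeric(1), A = mx$A)
  expect_lte(isis[ens$selected], median(isis) + 1e-9)
})
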