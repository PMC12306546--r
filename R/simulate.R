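#' Sample a multivariate-Laplacian SCV
#'
#' Draws `V` samples of a zero-mean multivariate Laplacian vector with
#' covariance `C` using the Gaussian scale-mixture construction
#' `s = sqrt(w) * z` with `z ~ N(0, C)` and `w ~ Exp(1)`: since `E[w] = 1`
#' the population covariance is exactly `C`, and the marginals are
#' heavier-tailed than Gaussian (excess kurtosis 3).  Rows are centred to
#' exact zero sample mean afterwards; row variances are left stochastic
#' (unit at the population level).
#'
#' @param C symmetric positive-definite `K x K` covariance matrix.
#' @param V number of samples (columns), `V >= K`.
#' @param seed integer seed.
#' @return a `K x V` matrix, one SCV.
#' @examples
#' C <- scv_block_cov(block_spec(list(1:3), rho = 0.5, K = 4))
#' S <- sample_laplacian_scv(C, V = 500, seed = 1)
#' dim(S)
#' @export
sample_laplacian_scv <- function(C, V, seed = NULL) {
  stopifnot(is_square_matrix(C), V >= nrow(C))
  if (max(abs(C - t(C))) > 1e-10) {
    stop("C must be symmetric")
  }
  if (!is_pd(C)) {
    stop("C must be positive definite")
  }
  with_seed(seed, {
    Z <- t(MASS::mvrnorm(n = V, mu = rep(0, nrow(C)), Sigma = C))
    w <- rexp(V, rate = 1)
    S <- sweep(Z, 2, sqrt(w), `*`)
    S - rowMeans(S)
  })
}

#' Generate all SCVs of a design
#'
#' Builds each SCV covariance matrix from its block specification (redrawing
#' the perturbation if positive definiteness fails) and samples a
#' multivariate-Laplacian `K x V` source matrix per SCV.  Per-SCV seeds are
#' derived from `seed` so results do not depend on generation order.
#'
#' @param design an [scv_design()].
#' @param seed master integer seed.
#' @return list with `sources` (list of `R` `K x V` matrices) and `covs`
#'   (list of the realised population covariance matrices).
#' @export
simulate_scvs <- function(design, seed = 1) {
  stopifnot(inherits(design, "scv_design"))
  covs <- lapply(seq_len(design$R), function(r) {
    scv_block_cov(design$specs[[r]], seed = substream_seed(seed, "cov", r))
  })
  sources <- lapply(seq_len(design$R), function(r) {
    sample_laplacian_scv(covs[[r]], design$V,
                         seed = substream_seed(seed, "scv", r))
  })
  list(sources = sources, covs = covs)
}

#' Mix SCV sources into observed datasets
#'
#' Rearranges `R` SCVs (each `K x V`) into per-dataset source matrices
#' `S[k]` (`R x V`, row `r` = row `k` of SCV `r`) and mixes each with a
#' random square matrix `A[k]` of i.i.d. standard-normal entries:
#' `X[k] = A[k] %*% S[k]`.  Mixing matrices with condition number above
#' `cond_cap` are redrawn to avoid numerically unidentifiable mixtures.
#'
#' @param sources list of `R` SCV matrices, all `K x V`.
#' @param seed integer seed for the mixing draw.
#' @param mixing optional list of `K` fixed `R x R` mixing matrices (e.g.
#'   identities as a test hook); skips the random draw.
#' @param cond_cap condition-number cap for redrawing random mixings.
#' @param design optional [scv_design()] carried along for ground truth.
#' @return an object of class `scv_mixture`: list with `X` (K observed
#'   `R x V` matrices), `A` (K mixing matrices), `S` (K per-dataset source
#'   matrices), `sources` (the input SCVs) and `design`.
#' @export
mix_sources <- function(sources, seed = NULL, mixing = NULL,
                        cond_cap = 1e6, design = NULL) {
  K <- nrow(sources[[1]])
  V <- ncol(sources[[1]])
  R <- length(sources)
  stopifnot(all(vapply(sources, nrow, integer(1)) == K),
            all(vapply(sources, ncol, integer(1)) == V))
  # S[k]: row r is the kth component of SCV r
  S <- lapply(seq_len(K), function(k) {
    t(vapply(sources, function(Sr) Sr[k, ], numeric(V)))
  })
  if (is.null(mixing)) {
    A <- with_seed(seed, lapply(seq_len(K), function(k) {
      repeat {
        Ak <- matrix(rnorm(R * R), R, R)
        if (kappa(Ak, exact = TRUE) <= cond_cap) return(Ak)
      }
    }))
  } else {
    stopifnot(length(mixing) == K,
              all(vapply(mixing, is_square_matrix, logical(1))),
              all(vapply(mixing, nrow, integer(1)) == R))
    A <- mixing
  }
  X <- Map(`%*%`, A, S)
  structure(list(X = X, A = A, S = S, sources = sources, design = design),
            class = "scv_mixture")
}

#' Simulate a full ground-truth mixture
#'
#' Convenience wrapper: [simulate_scvs()] then [mix_sources()], with
#' substream seeds derived from one master seed.
#'
#' @inheritParams simulate_scvs
#' @inheritParams mix_sources
#' @return an `scv_mixture` (see [mix_sources()]), with the realised SCV
#'   covariance matrices attached as `$covs`.
#' @examples
#' mx <- simulate_mixture(scv_design(rho = 0.5, V = 200), seed = 7)
#' dim(mx$X[[1]]) # R x V
#' @export
simulate_mixture <- function(design, seed = 1, mixing = NULL, cond_cap = 1e6) {
  sim <- simulate_scvs(design, seed = seed)
  mx <- mix_sources(sim$sources, seed = substream_seed(seed, "mixing"),
                    mixing = mixing, cond_cap = cond_cap, design = design)
  mx$covs <- sim$covs
  mx
}

#' @export
print.scv_mixture <- function(x, ...) {
  K <- length(x$X)
  cat(sprintf("scv_mixture: K = %d datasets, R = %d sources, V = %d samples\n",
              K, nrow(x$X[[1]]), ncol(x$X[[1]])))
  if (!is.null(x$design)) {
    cat(sprintf("  design true d: (%s)\n", paste(x$design$true_d, collapse = ", ")))
  }
  invisible(x)
}
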