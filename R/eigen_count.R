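#' Absolute sample covariance of an SCV and its eigendecomposition
#'
#' Computes `C = abs(S %*% t(S) / V)` for one estimated SCV and its
#' eigendecomposition with eigenvalues sorted in descending order.  The
#' elementwise absolute value (taken before the EVD) absorbs the per-source
#' sign ambiguity of blind source separation.  Rows are defensively centred
#' and scaled to unit sample variance (1/V convention) so that the covariance
#' coincides with the correlation matrix: unit diagonal, entries between 0
#' and 1, trace (= eigenvalue sum) equal to `K`.
#'
#' @param S a `K x V` SCV matrix.
#' @return an object of class `cov_estimate`: list with `C`, `values`
#'   (descending), `vectors` (columns aligned to `values`), `K`, `V`.
#' @export
scv_covariance <- function(S) {
  stopifnot(is.matrix(S), nrow(S) >= 2, ncol(S) >= nrow(S))
  V <- ncol(S)
  S <- S - rowMeans(S)
  rms <- sqrt(rowSums(S^2) / V)
  if (any(rms < .Machine$double.eps * 100)) {
    stop(sprintf("SCV row %d has (near-)zero variance",
                 which(rms < .Machine$double.eps * 100)[1]))
  }
  S <- S / rms
  C <- abs(tcrossprod(S) / V)
  e <- eigen(C, symmetric = TRUE)
  structure(
    list(C = C, values = e$values, vectors = e$vectors,
         K = nrow(S), V = V),
    class = "cov_estimate"
  )
}

#' Directly count eigenvalues greater than one
#'
#' The naive "EV" baseline: `d` is the number of eigenvalues of the absolute
#' sample covariance that strictly exceed 1.  On finite samples this
#' overestimates the block count of structured SCVs because spurious small
#' correlations push trailing eigenvalues above 1; the bootstrap test
#' ([bootstrap_count()]) corrects for this.
#'
#' @param cov a `cov_estimate` from [scv_covariance()], or a `K x V` SCV
#'   matrix (converted internally).
#' @return integer count.
#' @export
ev_count <- function(cov) {
  if (is.matrix(cov)) cov <- scv_covariance(cov)
  stopifnot(inherits(cov, "cov_estimate"))
  sum(cov$values > 1)
}

#' Bootstrap test configuration
#'
#' @param B number of bootstrap resamples (default 1000).
#' @param Pfa per-eigenvalue false-alarm probability (default 0.05); controls
#'   the risk of overestimating the block count.
#' @param seed integer seed for the resampling draws.
#' @return object of class `test_config`.  The threshold rank
#'   `eta = floor((B + 1) (1 - Pfa))` must satisfy `1 <= eta <= B`.
#' @export
test_config <- function(B = 1000, Pfa = 0.05, seed = NULL) {
  stopifnot(is.numeric(B), length(B) == 1L, B >= 1,
            is.numeric(Pfa), length(Pfa) == 1L, Pfa > 0, Pfa < 1)
  eta <- floor((B + 1) * (1 - Pfa))
  if (eta < 1 || eta > B) {
    stop(sprintf(
      "invalid test configuration: eta = floor((B+1)(1-Pfa)) = %d not in [1, %d]; increase B or adjust Pfa",
      eta, as.integer(B)
    ))
  }
  structure(list(B = as.integer(B), Pfa = Pfa, eta = as.integer(eta),
                 seed = seed),
            class = "test_config")
}

#' Bootstrap estimate of the number of eigenvalues greater than one
#'
#' For one SCV, tests each eigenvalue of the absolute sample covariance
#' against the null `H0: lambda[k] <= 1` with a bootstrap approximation of
#' the null distribution of `T = lambda_hat[k] - 1`.  Columns are resampled
#' with replacement `B` times (one shared index draw per replicate for the
#' whole SCV, preserving cross-row dependence); each replicate yields
#' `T*_b = lambda_hat_b[k] - lambda_hat[k]`.  With the `T*` sorted ascending
#' and `eta = floor((B + 1) (1 - Pfa))`, the null is rejected when
#' `T >= T*_eta` (ties reject).  The estimated block count `d_hat` is the
#' number of rejections.
#'
#' @param S a `K x V` SCV matrix (`V >= K`).
#' @param cfg a [test_config()]; its `seed` (or the `seed` argument) makes
#'   the resampling bit-reproducible.
#' @param seed overrides `cfg$seed` when non-`NULL`.
#' @return an object of class `eig_count`: list with `d_hat`, `epsilon`
#'   (0/1 rejection flags per eigenvalue), `T_hat`, `threshold` (the
#'   `T*_eta` per eigenvalue), `cov` (the [scv_covariance()]), `B`, `Pfa`,
#'   `seed`.
#' @examples
#' C <- scv_block_cov(block_spec(list(1:3, 4:6), rho = 0.6, K = 6))
#' S <- sample_laplacian_scv(C, V = 1000, seed = 2)
#' bootstrap_count(S, test_config(B = 200, Pfa = 0.05, seed = 3))$d_hat
#' @export
bootstrap_count <- function(S, cfg = test_config(), seed = NULL) {
  stopifnot(inherits(cfg, "test_config"))
  seed <- seed %||% cfg$seed
  cov <- scv_covariance(S)
  # bootstrap resamples the (normalized) SCV exactly as used for C
  Sn <- S - rowMeans(S)
  Sn <- Sn / sqrt(rowSums(Sn^2) / ncol(Sn))
  boot <- with_seed(seed, boot_eigs_cpp(Sn, cfg$B)) # B x K, rows descending
  Tstar <- sweep(boot, 2, cov$values) # T*_b per eigenvalue rank
  threshold <- apply(Tstar, 2, function(x) sort(x)[cfg$eta])
  T_hat <- cov$values - 1
  epsilon <- as.integer(T_hat >= threshold)
  structure(
    list(d_hat = sum(epsilon), epsilon = epsilon, T_hat = T_hat,
         threshold = threshold, cov = cov, B = cfg$B, Pfa = cfg$Pfa,
         eta = cfg$eta, seed = seed),
    class = "eig_count"
  )
}

#' @export
print.eig_count <- function(x, ...) {
  cat(sprintf("eig_count: d_hat = %d of K = %d (B = %d, Pfa = %g)\n",
              x$d_hat, x$cov$K, x$B, x$Pfa))
  cat("  epsilon:", paste(x$epsilon, collapse = " "), "\n")
  invisible(x)
}

#' Estimate the block count for every SCV
#'
#' Runs [bootstrap_count()] on each SCV with per-SCV seeds derived from the
#' master seed, so results are independent of processing order.
#'
#' @param scvs list of `K x V` SCV matrices.
#' @param cfg a [test_config()].
#' @param seed master integer seed.
#' @return list of `eig_count` objects.
#' @export
estimate_d <- function(scvs, cfg = test_config(), seed = 1) {
  lapply(seq_along(scvs), function(r) {
    bootstrap_count(scvs[[r]], cfg, seed = substream_seed(seed, "bootstrap", r))
  })
}

#' Split SCVs into common and structured sets
#'
#' Common SCVs have exactly one eigenvalue greater than 1 (`d_hat = 1`, all
#' datasets correlated); structured SCVs have `d_hat > 1` (block structure)
#' and carry the relationship information.  SCVs with `d_hat = 0` (identity
#' covariance, completely uncorrelated datasets) belong to neither set and
#' trigger a warning.
#'
#' @param d_hat integer vector of estimated counts (or a list of `eig_count`
#'   objects).
#' @return list with ordered index vectors `common`, `structured`,
#'   `excluded`.
#' @export
classify_scvs <- function(d_hat) {
  if (is.list(d_hat)) {
    d_hat <- vapply(d_hat, function(x) x$d_hat, numeric(1))
  }
  stopifnot(is.numeric(d_hat), all(d_hat >= 0))
  excluded <- which(d_hat == 0)
  if (length(excluded) > 0) {
    warning(sprintf(
      "SCV(s) %s have d_hat = 0 (identity covariance); excluded from both sets",
      paste(excluded, collapse = ", ")
    ))
  }
  list(common = which(d_hat == 1),
       structured = which(d_hat > 1),
       excluded = excluded)
}
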