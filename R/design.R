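#' Block-correlation specification for one SCV covariance matrix
#'
#' Describes the population covariance (= correlation) matrix of one source
#' component vector (SCV) across `K` datasets: disjoint blocks of datasets
#' whose components are correlated at level `rho`, plus an optional symmetric
#' Gaussian perturbation of the within-block entries.  Datasets belonging to
#' no block are uncorrelated components.
#'
#' @param blocks list of integer vectors, pairwise-disjoint 1-based dataset
#'   indices; every block must have at least 2 members (a singleton block is
#'   indistinguishable from an uncorrelated component).
#' @param rho within-block correlation coefficient, in (0, 1).
#' @param K number of datasets.
#' @param noise_sd standard deviation of the symmetric perturbation added to
#'   each within-block off-diagonal entry (units: correlation).
#' @return an object of class `block_spec`.
#' @examples
#' block_spec(list(1:4, 5:7, 8:10), rho = 0.2, K = 10)
#' @export
block_spec <- function(blocks, rho, K, noise_sd = 0) {
  stopifnot(is.list(blocks), length(blocks) >= 1L,
            is.numeric(rho), length(rho) == 1L, rho > 0, rho < 1,
            is.numeric(K), length(K) == 1L, K >= 2,
            is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd >= 0)
  blocks <- lapply(blocks, function(b) sort(as.integer(b)))
  all_idx <- unlist(blocks)
  if (any(all_idx < 1L) || any(all_idx > K)) {
    stop("block indices must lie in 1..K")
  }
  if (anyDuplicated(all_idx)) {
    stop("blocks must be pairwise disjoint")
  }
  if (any(lengths(blocks) < 2L)) {
    stop("each block needs >= 2 datasets; model singletons as uncorrelated components")
  }
  structure(
    list(blocks = blocks, rho = rho, K = as.integer(K), noise_sd = noise_sd),
    class = "block_spec"
  )
}

#' @export
print.block_spec <- function(x, ...) {
  cat(sprintf("block_spec: K = %d, rho = %g, noise_sd = %g\n", x$K, x$rho, x$noise_sd))
  for (i in seq_along(x$blocks)) {
    cat(sprintf("  block %d: {%s}\n", i, paste(x$blocks[[i]], collapse = ", ")))
  }
  un <- n_uncorrelated(x)
  if (un > 0) cat(sprintf("  uncorrelated components: %d\n", un))
  invisible(x)
}

n_uncorrelated <- function(spec) spec$K - length(unlist(spec$blocks))

#' Build an SCV covariance matrix from a block specification
#'
#' Constructs the `K x K` population SCV covariance matrix with unit diagonal,
#' zeros outside the blocks, and `rho + n(k, l)` inside each block, where
#' `n(k, l) = n(l, k) ~ N(0, noise_sd^2)` i.i.d.  Without noise the matrix has
#' exactly `d` eigenvalues greater than 1, where `d` is the number of blocks.
#' If a noise draw breaks positive definiteness, the noise is redrawn (up to
#' `max_redraw` times) before failing.
#'
#' @param spec a [block_spec()].
#' @param seed integer seed for the noise draw (ignored when `noise_sd = 0`).
#' @param max_redraw redraw attempts before giving up on a positive-definite
#'   matrix.
#' @return a symmetric positive-definite `K x K` matrix.
#' @examples
#' C <- scv_block_cov(block_spec(list(1:10), rho = 0.2, K = 10))
#' eigen(C, only.values = TRUE)$values[1] # 1 + 9 * 0.2 = 2.8
#' @export
scv_block_cov <- function(spec, seed = NULL, max_redraw = 100L) {
  stopifnot(inherits(spec, "block_spec"))
  K <- spec$K
  base <- diag(K)
  for (b in spec$blocks) {
    base[b, b] <- spec$rho
  }
  diag(base) <- 1
  if (spec$noise_sd == 0) {
    return(base)
  }
  with_seed(seed, {
    for (attempt in seq_len(max_redraw)) {
      C <- base
      for (b in spec$blocks) {
        nb <- length(b)
        N <- matrix(0, nb, nb)
        N[upper.tri(N)] <- rnorm(nb * (nb - 1) / 2, sd = spec$noise_sd)
        N <- N + t(N)
        C[b, b] <- C[b, b] + N
      }
      if (is_pd(C)) {
        return(C)
      }
    }
    stop(sprintf(
      "no positive-definite covariance after %d noise redraws (K = %d, rho = %g, noise_sd = %g)",
      max_redraw, K, spec$rho, spec$noise_sd
    ))
  })
}

is_pd <- function(C) {
  !inherits(tryCatch(chol(C), error = identity), "error")
}

#' Reference six-SCV simulation design
#'
#' The built-in study design: `R = 6` SCVs over `K = 10` datasets with
#' eigenvalue-above-one counts `d = (1, 2, 2, 2, 3, 4)`.  SCV 1 is common
#' (one block spanning all datasets); SCVs 2-6 are structured, with SCV 3
#' leaving 1 and SCV 4 leaving 4 datasets uncorrelated.  Default block
#' memberships (configurable through `specs`):
#' \itemize{
#'   \item C1: \{1-10\}
#'   \item C2: \{1-4\}, \{5-10\}
#'   \item C3: \{1-4\}, \{5-9\}  (10 uncorrelated)
#'   \item C4: \{1-3\}, \{5-7\}  (4, 8, 9, 10 uncorrelated)
#'   \item C5: \{1-4\}, \{5-7\}, \{8-10\}
#'   \item C6: \{1-2\}, \{3-4\}, \{5-7\}, \{8-10\}
#' }
#' Ground-truth grouping labels are `(1,1,1,1,2,2,2,3,3,3)`.  The within-block
#' perturbation has variance 0.0025 (`noise_sd = 0.05`) so that no two blocks
#' have exactly proportional covariance, which keeps the mixture identifiable
#' for IVA.
#'
#' @param rho within-block correlation, in (0, 1).
#' @param V samples per SCV.
#' @param noise_sd within-block perturbation standard deviation.
#' @param specs optional list of [block_spec()] overriding the default six;
#'   `true_labels` must then be supplied too.
#' @param true_labels integer grouping labels of the `K` datasets.
#' @return an object of class `scv_design` with elements `specs`, `true_d`,
#'   `true_labels`, `K`, `R`, `V`, `rho`, `noise_sd`.
#' @examples
#' des <- scv_design(rho = 0.2)
#' des$true_d # 1 2 2 2 3 4
#' @export
scv_design <- function(rho = 0.2, V = 1000, noise_sd = 0.05,
                       specs = NULL, true_labels = NULL) {
  stopifnot(rho > 0, rho < 1, V >= 1)
  if (is.null(specs)) {
    blocks <- list(
      list(1:10),
      list(1:4, 5:10),
      list(1:4, 5:9),
      list(1:3, 5:7),
      list(1:4, 5:7, 8:10),
      list(1:2, 3:4, 5:7, 8:10)
    )
    specs <- lapply(blocks, block_spec, rho = rho, K = 10L, noise_sd = noise_sd)
    true_labels <- c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L)
  } else {
    stopifnot(all(vapply(specs, inherits, logical(1), "block_spec")))
    if (is.null(true_labels)) {
      stop("true_labels must accompany custom specs")
    }
  }
  K <- specs[[1]]$K
  stopifnot(all(vapply(specs, function(s) s$K, integer(1)) == K),
            length(true_labels) == K, V >= K)
  structure(
    list(
      specs = specs,
      true_d = vapply(specs, function(s) length(s$blocks), integer(1)),
      true_labels = as.integer(true_labels),
      K = K,
      R = length(specs),
      V = as.integer(V),
      rho = rho,
      noise_sd = noise_sd
    ),
    class = "scv_design"
  )
}

#' @export
print.scv_design <- function(x, ...) {
  cat(sprintf("scv_design: R = %d SCVs, K = %d datasets, V = %d samples\n",
              x$R, x$K, x$V))
  cat(sprintf("  rho = %g, noise_sd = %g\n", x$rho, x$noise_sd))
  cat(sprintf("  true d: (%s)\n", paste(x$true_d, collapse = ", ")))
  cat(sprintf("  true labels: (%s)\n", paste(x$true_labels, collapse = ", ")))
  invisible(x)
}
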