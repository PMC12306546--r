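#' Eigenvector feature matrix of the structured SCVs
#'
#' Horizontally concatenates the `d_hat[r]` leading eigenvectors of each
#' structured SCV covariance matrix into a `K x sum(d_hat)` feature matrix.
#' Each eigenvector associated with an eigenvalue greater than 1 is
#' (approximately) supported on one correlated block, so the rows of the
#' feature matrix place datasets that share blocks close together.  Each
#' column is sign-fixed by the sign of its largest-magnitude entry: the
#' absolute covariance is elementwise nonnegative, so block eigenvectors are
#' nonnegative up to a global sign, and the convention restores the
#' "correlated entries positive" property.
#'
#' @param covs list of `cov_estimate` objects (one per structured SCV), or
#'   `eig_count` objects from which both the covariance and `d_hat` are
#'   taken.
#' @param d_hat integer vector of leading-eigenvector counts, one per
#'   element of `covs`; omit when `covs` are `eig_count` objects.
#' @return a `K x sum(d_hat)` matrix with attribute `provenance`, a data
#'   frame mapping each column to its (SCV index within `covs`, eigenvector
#'   rank).
#' @export
build_features <- function(covs, d_hat = NULL) {
  if (length(covs) == 0) {
    stop("no structured SCVs; relationship structure undefined")
  }
  if (is.null(d_hat)) {
    stopifnot(all(vapply(covs, inherits, logical(1), "eig_count")))
    d_hat <- vapply(covs, function(x) x$d_hat, numeric(1))
    covs <- lapply(covs, function(x) x$cov)
  }
  stopifnot(all(vapply(covs, inherits, logical(1), "cov_estimate")),
            length(d_hat) == length(covs), all(d_hat >= 1))
  cols <- list()
  prov <- list()
  for (i in seq_along(covs)) {
    U <- covs[[i]]$vectors[, seq_len(d_hat[i]), drop = FALSE]
    U <- apply(U, 2, function(u) u * sign(u[which.max(abs(u))]))
    cols[[i]] <- U
    prov[[i]] <- data.frame(scv = i, rank = seq_len(d_hat[i]))
  }
  F <- do.call(cbind, cols)
  attr(F, "provenance") <- do.call(rbind, prov)
  F
}

#' Hierarchical clustering of the datasets from eigenvector features
#'
#' Agglomerative clustering of the `K` rows of the feature matrix using
#' Euclidean distance and the Ward criterion (`hclust` method `"ward.D2"`,
#' which operates on unsquared Euclidean distances).  The resulting merge
#' tree (dendrogram) is the estimated relationship structure among the
#' datasets: merge heights express how dissimilar dataset groupings are.
#'
#' @param F feature matrix from [build_features()] (rows = datasets).
#' @param linkage_method linkage criterion passed to [stats::hclust()];
#'   `"ward"` maps to `"ward.D2"`.
#' @param n_clusters optional flat-cluster count; when given, labels are
#'   attached via [extract_labels()].
#' @param true_labels optional ground-truth labels; when given together with
#'   labels, the adjusted mutual information is attached.
#' @return an object of class `relationship_structure`: list with `hclust`
#'   (the [stats::hclust] object), `merges` (a `(K-1) x 4` table: the two
#'   merged children in 'scipy' convention — leaves `0..K-1`, internal nodes
#'   `K..2K-2` — merge height, and merged size), `heights`, `K`, and
#'   optionally `labels`, `n_clusters`, `ami`.
#' @examples
#' des <- scv_design(rho = 0.2, noise_sd = 0)
#' covs <- lapply(seq_len(des$R)[-1], function(r) {
#'   C <- scv_block_cov(des$specs[[r]])
#'   e <- eigen(C, symmetric = TRUE)
#'   structure(list(C = C, values = e$values, vectors = e$vectors,
#'                  K = des$K, V = Inf), class = "cov_estimate")
#' })
#' F <- build_features(covs, des$true_d[-1])
#' rs <- relate_cluster(F, n_clusters = 3)
#' rs$labels
#' @export
relate_cluster <- function(F, linkage_method = "ward", n_clusters = NULL,
                           true_labels = NULL) {
  stopifnot(is.matrix(F), nrow(F) >= 2)
  if (!all(is.finite(F))) {
    stop("feature matrix contains non-finite values")
  }
  method <- if (identical(linkage_method, "ward")) "ward.D2" else linkage_method
  hc <- hclust(dist(F), method = method)
  K <- nrow(F)
  # scipy-style merge table: children < K are leaves, >= K internal nodes
  children <- t(apply(hc$merge, 1, function(m) {
    sort(ifelse(m < 0, -m - 1L, m + K - 1L))
  }))
  sizes <- numeric(K - 1)
  for (i in seq_len(K - 1)) {
    sizes[i] <- sum(ifelse(hc$merge[i, ] < 0, 1, sizes[pmax(hc$merge[i, ], 1)]))
  }
  merges <- cbind(children, height = hc$height, size = sizes)
  rs <- structure(
    list(hclust = hc, merges = merges, heights = hc$height, K = K),
    class = "relationship_structure"
  )
  if (!is.null(n_clusters) || !is.null(true_labels)) {
    rs$labels <- extract_labels(rs, n_clusters)
    rs$n_clusters <- length(unique(rs$labels))
    if (!is.null(true_labels)) {
      rs$ami <- ami(true_labels, rs$labels)
    }
  }
  rs
}

#' @export
print.relationship_structure <- function(x, ...) {
  cat(sprintf("relationship_structure over K = %d datasets\n", x$K))
  if (!is.null(x$labels)) {
    cat(sprintf("  labels (%d clusters): %s\n", x$n_clusters,
                paste(x$labels, collapse = " ")))
  }
  if (!is.null(x$ami)) cat(sprintf("  AMI vs truth: %g\n", x$ami))
  cat("  merge heights:", paste(signif(x$heights, 3), collapse = " "), "\n")
  invisible(x)
}

#' Flat cluster labels from the merge tree
#'
#' Cuts the dendrogram into `n_clusters` flat clusters.  When `n_clusters`
#' is `NULL` the cut is chosen automatically at the largest gap between
#' consecutive merge heights (a documented heuristic going beyond reading
#' the dendrogram by eye).
#'
#' @param rs a `relationship_structure` from [relate_cluster()].
#' @param n_clusters number of clusters in `[1, K]`, or `NULL` for the
#'   gap heuristic.
#' @return integer labels of length `K`, numbered by first appearance.
#' @export
extract_labels <- function(rs, n_clusters = NULL) {
  stopifnot(inherits(rs, "relationship_structure"))
  if (is.null(n_clusters)) {
    h <- sort(rs$heights)
    n_clusters <- if (length(h) < 2) {
      2L
    } else {
      rs$K - which.max(diff(h))
    }
  }
  stopifnot(n_clusters >= 1, n_clusters <= rs$K)
  labs <- cutree(rs$hclust, k = n_clusters)
  # renumber by first appearance for stable output
  as.integer(match(labs, unique(labs)))
}

#' Adjusted mutual information between two labelings
#'
#' Chance-corrected agreement between two flat clusterings:
#' `AMI = (MI - E[MI]) / (norm(H(U), H(V)) - E[MI])`, where the expected
#' mutual information is computed under the permutation (hypergeometric)
#' model and the normalisation is `max(H(U), H(V))` by default.  AMI is
#' invariant to label permutations; it equals 1 for identical clusterings
#' and is about 0 for independent ones.
#'
#' @param labels_true,labels_est equal-length label vectors.
#' @param average_method normalisation: `"max"` (default), `"arithmetic"`,
#'   `"geometric"` or `"min"` of the two entropies.
#' @return a scalar, at most 1.
#' @export
ami <- function(labels_true, labels_est,
                average_method = c("max", "arithmetic", "geometric", "min")) {
  average_method <- match.arg(average_method)
  if (length(labels_true) != length(labels_est)) {
    stop("labelings must have equal length")
  }
  n <- length(labels_true)
  tab <- table(labels_true, labels_est)
  a <- rowSums(tab)
  b <- colSums(tab)
  hu <- entropy_nats(a, n)
  hv <- entropy_nats(b, n)
  if (hu == 0 && hv == 0) {
    return(1) # both labelings are a single cluster: identical by convention
  }
  mi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      nij <- tab[i, j]
      if (nij > 0) {
        mi <- mi + nij / n * log(n * nij / (a[i] * b[j]))
      }
    }
  }
  emi <- expected_mi(a, b, n)
  norm <- switch(average_method,
    max = max(hu, hv),
    min = min(hu, hv),
    arithmetic = (hu + hv) / 2,
    geometric = sqrt(hu * hv)
  )
  denom <- norm - emi
  if (abs(denom) < .Machine$double.eps) {
    denom <- .Machine$double.eps
  }
  unname((mi - emi) / denom)
}

entropy_nats <- function(counts, n) {
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

# Expected mutual information under the hypergeometric permutation model
# (Vinh, Epps & Bailey 2010).  lgamma-based for numerical stability.
expected_mi <- function(a, b, n) {
  lf <- function(x) lgamma(x + 1)
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (lo > hi) next
      for (nij in lo:hi) {
        lp <- lf(ai) + lf(bj) + lf(n - ai) + lf(n - bj) -
          (lf(n) + lf(nij) + lf(ai - nij) + lf(bj - nij) +
             lf(n - ai - bj + nij))
        emi <- emi + nij / n * log(n * nij / (ai * bj)) * exp(lp)
      }
    }
  }
  emi
}

#' Monte-Carlo recovery metrics for the block-count estimator
#'
#' Given estimated counts from repeated runs, computes per SCV the
#' probability of exact recovery `P(d_hat = d)` and the mean estimate
#' `mean(d_hat)`.
#'
#' @param d_hat_runs numeric matrix (runs x SCVs) or vector of estimates.
#' @param d_true true count per SCV (recycled across runs).
#' @return data frame with columns `scv`, `d_true`, `p_correct`, `mean_d`.
#' @export
recovery_metrics <- function(d_hat_runs, d_true) {
  if (!is.matrix(d_hat_runs)) {
    d_hat_runs <- matrix(d_hat_runs, ncol = length(d_true))
  }
  stopifnot(ncol(d_hat_runs) == length(d_true), nrow(d_hat_runs) >= 1)
  data.frame(
    scv = seq_along(d_true),
    d_true = d_true,
    p_correct = colMeans(sweep(d_hat_runs, 2, d_true, `==`)),
    mean_d = colMeans(d_hat_runs)
  )
}

#' Export a relationship structure as a Newick tree
#'
#' Writes the dendrogram in Newick format with merge heights as branch
#' lengths (via the 'ape' package).
#'
#' @param rs a `relationship_structure`.
#' @param file path to write to, or `""` to return the string.
#' @param labels optional tip labels (defaults to `dataset1..K`).
#' @return the Newick string, invisibly when written to a file.
#' @export
export_newick <- function(rs, file = "", labels = NULL) {
  stopifnot(inherits(rs, "relationship_structure"))
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("package 'ape' is required for Newick export")
  }
  hc <- rs$hclust
  hc$labels <- labels %||% paste0("dataset", seq_len(rs$K))
  phy <- ape::as.phylo(hc)
  out <- ape::write.tree(phy, file = file)
  if (nzchar(file)) invisible(out) else out
}
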