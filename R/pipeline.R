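#' Pipeline configuration
#'
#' Collects the tunable parameters of the 3-step pipeline.  Defaults follow
#' the method's standard operating point: 20 IVA restarts, `B = 1000`
#' bootstrap resamples, `Pfa = 0.05`, Ward linkage.
#'
#' @param R target source dimension for PCA reduction; `NULL` when the data
#'   are already reduced (`R x V`).
#' @param n_runs IVA random restarts.
#' @param B,Pfa bootstrap test parameters, see [test_config()].
#' @param linkage_method linkage criterion for [relate_cluster()].
#' @param n_clusters optional flat-cluster count; `NULL` uses the
#'   height-gap heuristic of [extract_labels()].
#' @param seed master seed; every random stage draws from a named substream
#'   derived from it ([substream_seed()]), so stages can be re-run or
#'   parallelised without changing results.
#' @param max_iter,tol IVA convergence controls, see [iva_l_sos()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(R = NULL, n_runs = 20, B = 1000, Pfa = 0.05,
                            linkage_method = "ward", n_clusters = NULL,
                            seed = 1, max_iter = 1024, tol = 1e-6) {
  cfg <- test_config(B = B, Pfa = Pfa) # validates B/Pfa/eta
  structure(
    list(R = R, n_runs = as.integer(n_runs), B = cfg$B, Pfa = cfg$Pfa,
         linkage_method = linkage_method, n_clusters = n_clusters,
         seed = as.integer(seed), max_iter = max_iter, tol = tol),
    class = "pipeline_config"
  )
}

#' PCA dimension reduction, one dataset at a time
#'
#' Reduces each raw dataset `I x J` to `R x J` independently: rows are
#' centred, the top `R` principal directions of the row space are found by
#' SVD, and the data are projected onto them.  Retained-variance fractions
#' are attached as an attribute.
#'
#' @param X list of `K` raw matrices (rows = original dimensions, columns =
#'   samples/voxels).
#' @param R target dimension, at most the rank of each dataset.
#' @return list of `K` reduced `R x J` matrices with attribute
#'   `retained_variance` (per-dataset fraction in `[0, 1]`).
#' @export
pca_reduce <- function(X, R) {
  stopifnot(is.list(X), R >= 1)
  retained <- numeric(length(X))
  out <- vector("list", length(X))
  for (k in seq_along(X)) {
    Xc <- X[[k]] - rowMeans(X[[k]])
    sv <- svd(Xc, nu = min(nrow(Xc), ncol(Xc)), nv = 0)
    rank_k <- sum(sv$d > max(sv$d) * 1e-10)
    if (R > rank_k) {
      stop(sprintf("R = %d exceeds rank %d of dataset %d", R, rank_k, k))
    }
    out[[k]] <- t(sv$u[, seq_len(R), drop = FALSE]) %*% Xc
    retained[k] <- sum(sv$d[seq_len(R)]^2) / sum(sv$d^2)
  }
  attr(out, "retained_variance") <- retained
  out
}

#' Run the full 3-step pipeline
#'
#' Orchestrates: (optional) simulation of ground-truth mixtures, (optional)
#' per-dataset PCA reduction, multi-start IVA with consistency selection,
#' per-SCV bootstrap estimation of the number of eigenvalues greater than
#' one, classification into common/structured SCVs, eigenvector feature
#' construction, Ward clustering, and (when ground truth is available)
#' adjusted mutual information.
#'
#' @param X list of `K` observed matrices; `NULL` when `design` is given.
#' @param design an [scv_design()] to simulate from ([simulate_mixture()]).
#' @param config a [pipeline_config()].
#' @param mixing optional fixed mixing matrices for simulation (test hook).
#' @param true_labels ground-truth labels for AMI; defaults to the design's.
#' @param ... further arguments to [iva_l_sos()] (e.g. `W_init`).
#' @return an object of class `run_report`: list with `d_hat`, `epsilon`
#'   table, `sets` (common/structured/excluded), `structure`
#'   (`relationship_structure`), `labels`, `ami` (or `NULL`), `ensemble`,
#'   `counts` (per-SCV `eig_count`s), `timings` (seconds per stage),
#'   `config`, and for simulations `mixture` and `joint_isi`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(design = scv_design(rho = 0.8, V = 500),
#'                     config = pipeline_config(n_runs = 2, B = 200,
#'                                              n_clusters = 3, seed = 1,
#'                                              max_iter = 300, tol = 1e-5))
#' rep$ami
#' }
#' @export
run_pipeline <- function(X = NULL, design = NULL, config = pipeline_config(),
                         mixing = NULL, true_labels = NULL, ...) {
  stopifnot(inherits(config, "pipeline_config"))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  report <- list(config = config)

  mixture <- NULL
  if (is.null(X)) {
    if (is.null(design)) stop("supply either data X or a simulation design")
    t0 <- tic()
    mixture <- simulate_mixture(design, seed = substream_seed(config$seed, "simgen"),
                                mixing = mixing)
    X <- mixture$X
    true_labels <- true_labels %||% design$true_labels
    timings["simulate"] <- tic() - t0
    report$mixture <- mixture
  }

  if (!is.null(config$R) && config$R < nrow(X[[1]])) {
    t0 <- tic()
    X <- pca_reduce(X, config$R)
    timings["pca"] <- tic() - t0
  }

  t0 <- tic()
  ens <- iva_ensemble(X, n_runs = config$n_runs,
                      seed = substream_seed(config$seed, "iva"),
                      max_iter = config$max_iter, tol = config$tol, ...)
  timings["iva"] <- tic() - t0
  report$ensemble <- ens
  if (!is.null(mixture)) {
    report$joint_isi <- joint_isi(ens$best$W, mixture$A)
  }

  t0 <- tic()
  cfg <- test_config(B = config$B, Pfa = config$Pfa)
  counts <- estimate_d(ens$best$scvs, cfg,
                       seed = substream_seed(config$seed, "bootstrap"))
  d_hat <- vapply(counts, function(x) x$d_hat, integer(1))
  sets <- classify_scvs(d_hat)
  timings["eigen_count"] <- tic() - t0
  report$counts <- counts
  report$d_hat <- d_hat
  report$sets <- sets

  if (length(sets$structured) == 0) {
    stop("no structured SCVs found (all d_hat <= 1); ",
         "the relationship structure is undefined for these data")
  }

  t0 <- tic()
  F <- build_features(counts[sets$structured])
  rs <- relate_cluster(F, linkage_method = config$linkage_method,
                       n_clusters = config$n_clusters %||% NULL,
                       true_labels = true_labels)
  if (is.null(rs$labels)) {
    rs$labels <- extract_labels(rs, config$n_clusters)
    rs$n_clusters <- length(unique(rs$labels))
  }
  timings["relate"] <- tic() - t0

  report$features <- F
  report$structure <- rs
  report$labels <- rs$labels
  report$ami <- rs$ami
  report$timings <- timings
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("3-step relationship-structure pipeline\n")
  cat(sprintf("  d_hat: (%s)\n", paste(x$d_hat, collapse = ", ")))
  cat(sprintf("  common SCVs: {%s}; structured SCVs: {%s}\n",
              paste(x$sets$common, collapse = ", "),
              paste(x$sets$structured, collapse = ", ")))
  cat(sprintf("  labels: (%s)\n", paste(x$labels, collapse = ", ")))
  if (!is.null(x$ami)) cat(sprintf("  AMI vs truth: %g\n", x$ami))
  if (!is.null(x$joint_isi)) {
    cat(sprintf("  joint-ISI vs true mixing: %.4g\n", x$joint_isi))
  }
  cat(sprintf("  timings (s): %s\n",
              paste(sprintf("%s %.2f", names(x$timings), x$timings),
                    collapse = ", ")))
  invisible(x)
}

#' Planning estimate of the pipeline's operation count
#'
#' Evaluates the leading-order complexity `R * K^2 * V * (I * K + B)`:
#' the IVA main loop costs `O(I R K^3 V)` (each iteration multiplies the
#' inverse SCV covariance with the SCV for every dataset) and the bootstrap
#' costs `O(B R K^2 V)`; the final `O(K^3)` clustering is negligible.
#'
#' @param R number of sources, `K` datasets, `V` samples.
#' @param K,V,I_iter,B problem sizes: datasets, samples, IVA iterations,
#'   bootstrap resamples.
#' @return predicted operation count (a planning figure, not a timing).
#' @examples
#' complexity_estimate(R = 6, K = 10, V = 1000, I_iter = 100, B = 1000)
#' @export
complexity_estimate <- function(R, K, V, I_iter, B) {
  R * K^2 * V * (I_iter * K + B)
}
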