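#' Independent vector analysis with a multivariate-Laplacian source model
#'
#' Jointly estimates demixing matrices `W[k]` for `K` datasets so that the
#' source component vectors (SCVs) — the vectors collecting the r-th
#' estimated source across datasets — are maximally independent of each
#' other while dependence within each SCV is preserved.  The SCV density
#' model is a multivariate Laplacian with non-identity covariance,
#' `p(s) ~ exp(-sqrt(s' Sigma^{-1} s))`, so both higher-order statistics
#' (heavy tails) and second-order statistics (the SCV covariance `Sigma`,
#' profiled as the running sample covariance of the estimated SCV) enter the
#' cost.  The cost is the mutual-information objective
#' \preformatted{sum_r ( mean_v sqrt(s_rv' Sigma_r^-1 s_rv)
#'         + 0.5 log det Sigma_r ) - sum_k log |det W_k|}
#' (additive constants dropped), minimised by a relative-gradient descent
#' with an adaptive step that only accepts decreasing updates, after
#' per-dataset pre-whitening.
#'
#' On convergence the demixing rows are rescaled so every estimated source
#' row has unit sample variance (1/V convention), making the SCV covariance
#' a correlation matrix; the returned `W` act on the original (centred)
#' data, with the whitening recorded separately.
#'
#' @param X list of `K` observed matrices, all `R x V` (`V > R`); rows are
#'   centred internally.
#' @param max_iter maximum outer iterations.
#' @param tol convergence tolerance on the maximum normalised Frobenius
#'   change of the `W[k]`.
#' @param seed integer seed for the random orthogonal initialisation.
#' @param W_init `"random"` (default), `"identity"` (start from the
#'   identity demixing of the centred data; test hook), or a list of `K`
#'   starting matrices acting on the centred data.
#' @param ridge ridge added to each SCV covariance before inversion.
#' @return an object of class `iva_result`: list with `W` (total demixing,
#'   `S[k] = W[k] %*% Xc[k]`), `whitening`, `S` (estimated per-dataset
#'   sources), `scvs` (list of `R` `K x V` estimated SCV matrices),
#'   `objective_trajectory`, `n_iter`, `converged`, `seed`.
#' @examples
#' mx <- simulate_mixture(scv_design(rho = 0.8, V = 400), seed = 3)
#' fit <- iva_l_sos(mx$X, max_iter = 200, tol = 1e-5, seed = 1)
#' joint_isi(fit$W, mx$A) # small when recovery succeeded
#' @export
iva_l_sos <- function(X, max_iter = 1024, tol = 1e-6, seed = NULL,
                      W_init = "random", ridge = 1e-8) {
  K <- length(X)
  stopifnot(K >= 2, all(vapply(X, is.matrix, logical(1))))
  R <- nrow(X[[1]])
  V <- ncol(X[[1]])
  stopifnot(all(vapply(X, nrow, integer(1)) == R),
            all(vapply(X, ncol, integer(1)) == V), V > R)

  Xc <- lapply(X, function(x) x - rowMeans(x))
  wh <- lapply(Xc, whitening_matrix)
  Z <- Map(`%*%`, wh, Xc)

  # W_init is expressed on the centred data; convert to whitened coordinates
  W <- if (is.list(W_init)) {
    stopifnot(length(W_init) == K)
    Map(function(w0, wh_k) w0 %*% solve(wh_k), W_init, wh)
  } else if (identical(W_init, "identity")) {
    lapply(wh, solve)
  } else {
    with_seed(seed, replicate(K, random_orthogonal(R), simplify = FALSE))
  }
  W <- lapply(W, function(w) w / sqrt(rowSums(w^2)))

  state <- iva_forward(W, Z, ridge)
  trajectory <- state$J
  mu <- 0.5
  converged <- FALSE
  iter <- 0
  swap_rounds <- 0

  while (iter < max_iter) {
    iter <- iter + 1
    # relative-gradient direction ((1/V) Phi[k] S[k]' - I) W[k], gauge-fixed:
    # the objective is invariant to per-row scaling, so the diagonal of the
    # relative gradient is pure scale drift and is projected out; row norms
    # are pinned to 1 after each accepted update instead.
    Dir <- lapply(seq_len(K), function(k) {
      G <- tcrossprod(state$Phi[[k]], state$S[[k]]) / V
      diag(G) <- 0
      G %*% W[[k]]
    })
    accepted <- FALSE
    for (ls in 1:25) {
      W_new <- lapply(seq_len(K), function(k) {
        w <- W[[k]] - mu * Dir[[k]]
        w / sqrt(rowSums(w^2)) # unit rows in whitened space = unit variance
      })
      cand <- tryCatch(iva_forward(W_new, Z, ridge), error = identity)
      if (!inherits(cand, "error") && is.finite(cand$J) && cand$J < state$J) {
        accepted <- TRUE
        break
      }
      mu <- mu / 2
    }
    stalled <- FALSE
    if (accepted) {
      delta <- max_rel_change(W_new, W)
      W <- W_new
      state <- cand
      trajectory <- c(trajectory, state$J)
      mu <- min(mu * 1.5, 2)
      stalled <- delta < tol
    }
    if (!accepted || stalled) {
      # continuous descent exhausted; try discrete SCV re-alignment.
      # Row assignments across datasets form permutation-type local optima
      # that gradient steps cannot escape (swapping two demixing rows of one
      # dataset moves a component between two SCVs); a greedy swap pass on
      # the same objective resolves them.
      if (swap_rounds < 10) {
        swap_rounds <- swap_rounds + 1
        sw <- swap_scv_rows(W, Z, state, ridge)
        if (sw$n_swaps > 0) {
          W <- sw$W
          state <- sw$state
          trajectory <- c(trajectory, state$J)
          mu <- max(mu, 0.1)
          next
        }
      }
      converged <- TRUE
      break
    }
  }
  if (!is.finite(state$J)) {
    stop(sprintf("non-finite objective at iteration %d", iter))
  }

  # total demixing on the original centred data; unit-variance source rows
  W_tot <- Map(`%*%`, W, wh)
  S_hat <- Map(`%*%`, W_tot, Xc)
  for (k in seq_len(K)) {
    rms <- sqrt(rowSums(S_hat[[k]]^2) / V)
    W_tot[[k]] <- W_tot[[k]] / rms
    S_hat[[k]] <- S_hat[[k]] / rms
  }

  structure(
    list(W = W_tot, whitening = wh, S = S_hat,
         scvs = sources_to_scvs(S_hat),
         objective_trajectory = trajectory, n_iter = iter,
         converged = converged, seed = seed),
    class = "iva_result"
  )
}

#' @export
print.iva_result <- function(x, ...) {
  cat(sprintf("iva_result: K = %d datasets, R = %d sources, %d iterations (%s)\n",
              length(x$W), nrow(x$W[[1]]), x$n_iter,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  objective: %.6g -> %.6g\n",
              x$objective_trajectory[1], tail(x$objective_trajectory, 1)))
  invisible(x)
}

# Per-SCV contribution to the objective: mean sqrt Mahalanobis norm under
# the profiled SCV covariance plus half its log-determinant.
scv_term <- function(Sr, ridge = 1e-8) {
  V <- ncol(Sr)
  Sig <- tcrossprod(Sr) / V + ridge * diag(nrow(Sr))
  ch <- chol(Sig)
  M <- backsolve(ch, forwardsolve(t(ch), Sr))
  q <- pmax(colSums(Sr * M), .Machine$double.eps)
  mean(sqrt(q)) + sum(log(diag(ch)))
}

# Greedy discrete re-alignment between SCV pairs.  Misaligned solutions
# assign the components of a whole correlated block of datasets to the
# wrong SCV; because the swapped configuration is itself block-coherent,
# neither gradient steps nor single-dataset swaps can escape it — the block
# must move as one unit.  For each SCV pair, candidate dataset subsets are
# the connected components of the two estimated (absolute-correlation)
# block graphs, their complements, and singletons; the demixing rows of the
# pair are exchanged over a subset iff that lowers the objective.  The
# |det W[k]| term is invariant under row exchanges, so only the two
# affected SCV terms need re-evaluation.
swap_scv_rows <- function(W, Z, state, ridge = 1e-8, block_tau = 0.1) {
  K <- length(Z)
  R <- nrow(W[[1]])
  V <- ncol(Z[[1]])
  scvs <- state$scvs
  terms <- vapply(scvs, scv_term, numeric(1), ridge = ridge)
  n_swaps <- 0L

  components <- function(Sr) {
    # connected components of the thresholded absolute correlation graph
    Sn <- Sr / sqrt(rowSums(Sr^2) / V)
    adj <- abs(tcrossprod(Sn) / V) >= block_tau
    comp <- integer(K)
    cid <- 0L
    for (k in seq_len(K)) {
      if (comp[k] == 0L) {
        cid <- cid + 1L
        frontier <- k
        comp[k] <- cid
        while (length(frontier) > 0) {
          nb <- which(adj[frontier[1], ] & comp == 0L)
          comp[nb] <- cid
          frontier <- c(frontier[-1], nb)
        }
      }
    }
    unname(split(seq_len(K), comp))
  }

  repeat {
    improved <- FALSE
    for (r in seq_len(R - 1)) {
      for (rp in seq(r + 1, R)) {
        comps <- c(components(scvs[[r]]), components(scvs[[rp]]))
        cands <- c(comps,
                   lapply(comps, function(d) setdiff(seq_len(K), d)),
                   as.list(seq_len(K)))
        cands <- unique(Filter(function(d) length(d) >= 1 && length(d) < K,
                               lapply(cands, sort)))
        for (d in cands) {
          Sr <- scvs[[r]]
          Srp <- scvs[[rp]]
          block <- Sr[d, , drop = FALSE]
          Sr[d, ] <- Srp[d, , drop = FALSE]
          Srp[d, ] <- block
          t_r <- scv_term(Sr, ridge)
          t_rp <- scv_term(Srp, ridge)
          if (t_r + t_rp < terms[r] + terms[rp] - 1e-10) {
            scvs[[r]] <- Sr
            scvs[[rp]] <- Srp
            terms[r] <- t_r
            terms[rp] <- t_rp
            for (k in d) {
              w_row <- W[[k]][r, ]
              W[[k]][r, ] <- W[[k]][rp, ]
              W[[k]][rp, ] <- w_row
            }
            n_swaps <- n_swaps + 1L
            improved <- TRUE
          }
        }
      }
    }
    if (!improved) break
  }
  out <- list(W = W, n_swaps = n_swaps, state = state)
  if (n_swaps > 0) {
    out$state <- iva_forward(W, Z, ridge)
  }
  out
}

# One forward pass: sources, SCV statistics, score matrices and objective
# for demixing W applied to (whitened) data Z.
iva_forward <- function(W, Z, ridge = 1e-8) {
  K <- length(Z)
  R <- nrow(Z[[1]])
  V <- ncol(Z[[1]])
  S <- Map(`%*%`, W, Z)
  # SCV r as K x V matrix
  scvs <- sources_to_scvs(S)
  logdet_w <- sum(vapply(W, function(w) {
    d <- determinant(w, logarithm = TRUE)
    if (d$sign == 0) stop("singular demixing matrix")
    as.numeric(d$modulus)
  }, numeric(1)))
  J_density <- 0
  Phi_scv <- vector("list", R) # K x V score per SCV
  for (r in seq_len(R)) {
    Sr <- scvs[[r]]
    Sig <- tcrossprod(Sr) / V + ridge * diag(K)
    ch <- chol(Sig)
    M <- backsolve(ch, forwardsolve(t(ch), Sr)) # Sigma^{-1} S_r
    q <- colSums(Sr * M)
    sq <- sqrt(pmax(q, .Machine$double.eps))
    J_density <- J_density + mean(sq) + sum(log(diag(ch)))
    Phi_scv[[r]] <- M / rep(sq, each = K)
  }
  # per-dataset score: row r of Phi[[k]] is the k-th row of SCV r's score
  Phi <- lapply(seq_len(K), function(k) {
    t(vapply(Phi_scv, function(p) p[k, ], numeric(V)))
  })
  list(S = S, scvs = scvs, Phi = Phi, J = J_density - logdet_w)
}

#' IVA mutual-information objective
#'
#' Evaluates the cost minimised by [iva_l_sos()] for a given set of demixing
#' matrices applied to data: the multivariate-Laplacian SCV negentropy term
#' with the SCV covariance estimated from the current sources, plus the
#' `- sum_k log |det W[k]|` volume term.  Returns `Inf` for singular `W`.
#'
#' @param W list of `K` demixing matrices (`R x R`).
#' @param X list of `K` data matrices (`R x V`); rows are centred.
#' @param ridge ridge added to each SCV covariance before inversion.
#' @return a finite scalar (or `Inf` for singular `W`).
#' @export
iva_objective <- function(W, X, ridge = 1e-8) {
  stopifnot(length(W) == length(X))
  Xc <- lapply(X, function(x) x - rowMeans(x))
  out <- tryCatch(iva_forward(W, Xc, ridge)$J, error = function(e) Inf)
  out
}

#' Joint inter-symbol-interference of a demixing estimate
#'
#' Normalised cross-talk of the products `G[k] = W[k] %*% A[k]`, summed over
#' datasets before normalisation: 0 if and only if all datasets are demixed
#' up to one shared permutation and per-row scaling; 1 for maximal cross-talk
#' (e.g. all-ones `G`).  Standard validation metric for joint blind source
#' separation on simulated data.
#'
#' @param W list of estimated demixing matrices (or an `iva_result`).
#' @param A list of the true mixing matrices.
#' @return a scalar in `[0, 1]`.
#' @export
joint_isi <- function(W, A) {
  if (inherits(W, "iva_result")) W <- W$W
  stopifnot(length(W) == length(A))
  G <- Reduce(`+`, Map(function(w, a) abs(w %*% a), W, A))
  N <- nrow(G)
  stopifnot(N == ncol(G))
  row_term <- sum(G / apply(G, 1, max)) - N
  col_term <- sum(t(G) / apply(G, 2, max)) - N
  (row_term + col_term) / (2 * N * (N - 1))
}

#' Multi-start IVA with consistency selection
#'
#' Runs [iva_l_sos()] from `n_runs` random initialisations (seeds derived
#' from the master seed) and selects the most consistent run: after greedy
#' permutation-and-sign matching of SCVs between each pair of runs, the
#' cross-run discrepancy is the mean of `1 - |row correlation|` over all
#' source rows, and the selected run minimises the mean discrepancy to all
#' other runs.
#'
#' @param X list of `K` observed matrices (`R x V`).
#' @param n_runs number of random initialisations.
#' @param seed master integer seed.
#' @param ... passed to [iva_l_sos()].
#' @return an object of class `iva_ensemble`: list with `runs`,
#'   `pairwise_distance` (`n_runs x n_runs`, zero diagonal), `selected`
#'   (index), and `best` (the selected `iva_result`).
#' @export
iva_ensemble <- function(X, n_runs = 20, seed = 1, ...) {
  stopifnot(n_runs >= 1)
  runs <- lapply(seq_len(n_runs), function(i) {
    iva_l_sos(X, seed = substream_seed(seed, "iva.run", i), ...)
  })
  if (!any(vapply(runs, function(r) r$converged, logical(1)))) {
    warning("no IVA run converged; selecting the most consistent anyway")
  }
  D <- matrix(0, n_runs, n_runs)
  if (n_runs > 1) {
    for (i in seq_len(n_runs - 1)) {
      for (j in seq(i + 1, n_runs)) {
        D[i, j] <- D[j, i] <- run_distance(runs[[i]], runs[[j]])
      }
    }
  }
  selected <- which.min(rowMeans(D))
  structure(
    list(runs = runs, pairwise_distance = D, selected = selected,
         best = runs[[selected]]),
    class = "iva_ensemble"
  )
}

#' @export
print.iva_ensemble <- function(x, ...) {
  cat(sprintf("iva_ensemble: %d runs, selected run %d (mean cross-run distance %.4g)\n",
              length(x$runs), x$selected, mean(x$pairwise_distance[x$selected, ])))
  invisible(x)
}

# Cross-run discrepancy after greedy SCV matching: SCV similarity is the
# mean over datasets of |cor| between matched source rows; runs estimating
# the same sources up to permutation/sign are at distance 0.
run_distance <- function(ra, rb) {
  K <- length(ra$S)
  R <- nrow(ra$S[[1]])
  sim <- matrix(0, R, R)
  for (k in seq_len(K)) {
    sim <- sim + abs(cor(t(ra$S[[k]]), t(rb$S[[k]])))
  }
  sim <- sim / K
  matched <- numeric(R)
  for (m in seq_len(R)) {
    ij <- arrayInd(which.max(sim), dim(sim))
    matched[m] <- sim[ij[1], ij[2]]
    sim[ij[1], ] <- -Inf
    sim[, ij[2]] <- -Inf
  }
  1 - mean(matched)
}

# Reshape per-dataset sources (K matrices R x V) into SCVs (R matrices K x V).
sources_to_scvs <- function(S) {
  R <- nrow(S[[1]])
  V <- ncol(S[[1]])
  lapply(seq_len(R), function(r) {
    t(vapply(S, function(s) s[r, ], numeric(V)))
  })
}

whitening_matrix <- function(Xc) {
  V <- ncol(Xc)
  C <- tcrossprod(Xc) / V
  e <- eigen(C, symmetric = TRUE)
  tol <- max(e$values) * 1e-10
  if (any(e$values < tol)) {
    stop("rank-deficient dataset: reduce dimension first (see pca_reduce)")
  }
  diag(1 / sqrt(e$values)) %*% t(e$vectors)
}

random_orthogonal <- function(n) {
  qr.Q(qr(matrix(rnorm(n * n), n, n)))
}
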