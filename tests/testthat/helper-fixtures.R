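# cov_estimate wrapper around a population covariance matrix (V = Inf
# marks that no sampling was involved)
pop_cov_estimate <- function(C, V = Inf) {
  e <- eigen(C, symmetric = TRUE)
  structure(list(C = C, values = e$values, vectors = e$vectors,
                 K = nrow(C), V = V),
            class = "cov_estimate")
}

# small two-block mixture that IVA separates quickly
quick_mixture <- function(rho = 0.8, V = 500, seed = 1) {
  simulate_mixture(scv_design(rho = rho, V = V), seed = seed)
}

count_above_one <- function(C) sum(eigen(C, symmetric = TRUE, only.values = TRUE)$values > 1)
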