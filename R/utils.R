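#' @useDynLib scvrelate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cutree dist hclust rexp rnorm runif sd var
#' @importFrom utils read.csv write.csv write.table tail
NULL

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so seeded operations do not perturb the global stream.
#' A `NULL` seed evaluates `code` under the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a reproducible substream seed
#'
#' Maps a master seed plus a named stream (and optional index) to a new
#' 31-bit seed by a small multiplicative hash.  Used so that parallel or
#' reordered stages (per-SCV bootstrap, per-run IVA initialisation) draw
#' from independent, order-insensitive streams.
#'
#' @param seed master integer seed.
#' @param stream character stream label, e.g. `"bootstrap"`.
#' @param index optional non-negative integer (SCV or run index).
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (b in c(utf8ToInt(stream), 257, as.numeric(index))) {
    h <- (h * 69069 + b + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# max_k ||Wa[k] - Wb[k]||_F / ||Wb[k]||_F -- convergence measure
max_rel_change <- function(Wa, Wb) {
  max(mapply(function(a, b) {
    norm(a - b, "F") / max(norm(b, "F"), .Machine$double.eps)
  }, Wa, Wb))
}

is_square_matrix <- function(x) is.matrix(x) && nrow(x) == ncol(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
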