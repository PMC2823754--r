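# Internal numerical helpers shared across modules.

# Row-wise log-sum-exp of a matrix, guarded against -Inf rows.
row_logsumexp <- function(L) {
  m <- apply(L, 1L, max)
  m[!is.finite(m)] <- 0
  m + log(rowSums(exp(L - m)))
}

clip01 <- function(p, eps = 1e-10) pmin(pmax(p, eps), 1 - eps)

sigmoid <- function(eta) 1 / (1 + exp(-eta))

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.  NULL seed leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed below 2^31 from a base seed and a stream index, so that
# independent stages (network, planting, rows, folds, restarts) never share a
# stream.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) {
    return(NULL)
  }
  (as.double(seed) * 7919 + 104729 * as.double(stream)) %% 2147483587
}

`%||%` <- function(a, b) if (is.null(a)) b else a
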