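# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL runs in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Deterministic sub-stream seed for a named pipeline stage. Keeps results of
# one stage reproducible in isolation from the single global seed.
derive_seed <- function(seed, stage, index = 0L) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.double(seed) * 48271 + h * 7919 + as.double(index) * 104729) %%
               2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Column-wise L2 norms of a matrix.
col_norms <- function(m) sqrt(colSums(m^2))

# Remove the per-column (per-sample) channel mean: projection onto the
# average-reference subspace.
center_cols <- function(m) {
  m - rep(colMeans(m), each = nrow(m))
}
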