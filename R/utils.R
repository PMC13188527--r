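# Internal helpers shared across modules.

# Derive independent child seeds from one user-facing seed. Keeps results
# < 2^31 so set.seed() accepts them on all platforms.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  ((abs(seed) + 1) * 48271 + stream * 30269) %% 2147483629
}

# Evaluate expr with a temporarily fixed RNG state, restoring the caller's
# state afterwards (used to keep randomized numerics deterministic without
# disturbing user-level simulations).
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Package-level cache (bridge interpolation grid etc.)
.longisal_cache <- new.env(parent = emptyenv())
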