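# internal helpers

# run code under a fixed RNG seed, restoring the caller's RNG state
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic sub-seed derivation; stays well below .Machine$integer.max
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 599999L) * 3000L + as.integer(offset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
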