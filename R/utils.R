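# Small internal helpers.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Derive a distinct child seed from a parent seed, staying within 32-bit
# integer range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
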