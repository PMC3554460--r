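# Internal helpers.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; restores
# the caller's RNG afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Deterministic child seed, kept inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483587) + 1L
}

# RMS power of a signal after mean removal.
signal_power <- function(x) {
  x <- x - mean(x)
  mean(x^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
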