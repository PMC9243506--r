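# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
# All generator functions route their randomness through this so that they are
# pure functions of (arguments, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = genv)
      } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Leaky rectifier and its derivative (slope applied to the negative part).
# Arithmetic masking instead of ifelse(): these run over ~1e6-element
# activation arrays per minibatch.
leaky_relu <- function(x, slope) {
  x * (slope + (1 - slope) * (x > 0))
}

leaky_relu_grad <- function(x, slope) {
  slope + (1 - slope) * (x > 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
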