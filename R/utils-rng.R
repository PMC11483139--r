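#' @keywords internal
"_PACKAGE"

## RNG discipline: every stochastic entry point takes an explicit integer
## seed and runs inside `with_seed()`, which restores the caller's RNG state
## on exit. Side streams (e.g. the adversary network) get their own saved
## RNG state so their draws never perturb the main training stream.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

## Derive a child seed from a parent seed and a stream index; stays within
## 32-bit signed integer range.
derive_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 1000003) * 2011 + 97 * as.numeric(stream)
  as.integer(s %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
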