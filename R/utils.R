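## Run an expression under a temporary RNG seed, restoring the caller's RNG
## state afterwards. NULL seed means "use the current stream".
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## Deterministic seed derivation: fold integer keys into [1, 2^31 - 2].
## Order-dependent polynomial hash so (scale, treatment, replicate) tuples
## map to well-separated streams while staying 32-bit safe.
deriveSeed <- function(base, ...) {
  keys <- c(base, ...)
  h <- 0
  for (k in keys) h <- (h * 69069 + (as.numeric(k) %% 2147483647)) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

stopifnot2 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

## deterministic round-half-up (base round() goes half-to-even)
roundHalfUp <- function(x) floor(x + 0.5)
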