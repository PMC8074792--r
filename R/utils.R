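# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All generators route their randomness through this
# so that identical configurations are bit-reproducible.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stopf("`seed` must be a single finite number")
  had_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
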