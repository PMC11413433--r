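# Internal RNG plumbing: every randomized operation takes an explicit seed
# and runs in a locally scoped RNG so package calls never disturb the
# caller's random stream.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 31-bit substream seed from a base seed and a stage name,
# so one global seed fans out into independent per-stage streams.
substream <- function(seed, name) {
  h <- 0
  for (b in utf8ToInt(name)) h <- (h * 131 + b) %% 2147483647
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
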