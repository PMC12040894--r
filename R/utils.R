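# Internal helpers shared across modules.

# Deterministic 31-based rolling hash of a string, kept below 2^31 - 1.
stable_hash <- function(name) {
  codes <- utf8ToInt(name)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

# Derive an independent substream seed from a global seed and a stream name,
# so adding a variable to the generator does not shift other variables' draws.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 1e9 + stable_hash(stream)) %% 2147483647)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
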