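# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  code
}

# Deterministic 31-bit string hash (polynomial rolling hash).
hash_string <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  h
}

# Derive a child seed from a parent seed and a string key, so each
# (drug, formula) gets an independent, order-insensitive RNG stream.
child_seed <- function(seed, key) {
  (as.numeric(seed) %% 2147483647 + hash_string(key)) %% 2147483647
}

child_config <- function(config, key) {
  config$seed <- child_seed(config$seed, key)
  config
}
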