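# Run `code` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so library code never perturbs user sessions.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive per-item sub-seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

CLASS_LEVELS <- c("B", "T", "TB")
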