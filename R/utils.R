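# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards: every stochastic generator in the package draws from its own
# explicitly seeded stream and never perturbs the global one.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# deterministic per-purpose sub-seeds derived from one master seed,
# kept below 2^31 - 1
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483647
}
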