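# Seed plumbing. Every stochastic entry point takes an integer seed, draws
# from a private substream, and restores the caller's RNG state on exit, so
# adding one simulated component never perturbs another.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic substream seed: combines the user seed with a string label.
# Arithmetic stays below 2^53 so the modulus is exact in doubles; the result
# fits a 32-bit integer.
substream_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 2147483647
  as.integer(((as.numeric(seed) %% 2147483647) * 2654435 + h) %% 2147483647)
}
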