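# Internal helpers shared across modules: seeded RNG hygiene, deterministic
# seed derivation for ensembles/restarts, and canonical block keys used for
# total-order tie-breaking.

# Run `code` under `seed` without disturbing the caller's RNG state.
local_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) {
    abort("a seed is required for stochastic operations", class = "pbbr_seed_error")
  }
  withr::with_seed(as.integer(seed), code)
}

# Deterministic per-member seed from (base_seed, index); a fixed multiplicative
# hash keeps results below 2^31 and reproducible across platforms.
derive_seed <- function(base_seed, index) {
  s <- (abs(as.numeric(base_seed)) %% 2147483647) + 1
  as.integer((s * 48271 + as.numeric(index) * 16807) %% 2147483647)
}

# Canonical key of a block given as a character vector of element ids.
block_key <- function(members) paste(sort(members), collapse = "\x1f")

# Canonical key of a list of blocks (order-free).
solution_key <- function(blocks) paste(sort(vapply(blocks, block_key, "")), collapse = "\x1e")

`%||%` <- function(a, b) if (is.null(a)) b else a
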