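## Internal helpers: deterministic seed sub-streams and small checks.

# Derive a reproducible sub-stream seed from one master seed. Keeps the
# result a valid 32-bit R integer.
deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %%
               .Machine$integer.max)
}

withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

assertCount <- function(x, name, allow_zero = TRUE) {
  if (length(x) != 1L || is.na(x) || x < if (allow_zero) 0 else 1 ||
      x != as.integer(x))
    stop(name, " must be a single non-negative integer")
  as.integer(x)
}

assertPositive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop(name, " must be finite and positive")
  x
}
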