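# Internal helpers shared across modules.

# Round half away from zero (printed-percentage convention: 19/24 -> 79).
.roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic 32-bit sub-seed for replicate r of a stream seeded by `seed`.
.deriveSeed <- function(seed, r) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + r * 104729) %%
               2147483629)
}

# Coerce TraitSpace or matrix-like input to a numeric matrix.
.asTraitMatrix <- function(x) {
  if (is(x, "TraitSpace")) return(x@values)
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}

.checkFiniteMatrix <- function(m, what) {
  if (any(!is.finite(m))) stop(what, " contains non-finite values")
  invisible(m)
}
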