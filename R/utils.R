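# Internal helpers.

# Deterministic sub-seed derivation: a single pipeline seed spawns
# per-subject / per-stage seeds through a small LCG (modulus 2^31 - 1), so
# subjects can be processed in any order (or in parallel) with identical
# results. All intermediate products stay below 2^53, hence exact in doubles.
.derive_seed <- function(seed, ...) {
  x <- as.numeric(seed) %% 2147483647
  for (salt in c(...)) {
    x <- (x * 48271 + as.numeric(salt)) %% 2147483647
  }
  as.integer(max(1, x))
}

# assortativity coefficient from an edge list (endpoint strengths), used by
# the rewiring inner loop; algebraically identical to the matrix form in
# assort.R but O(m) per call.
.assort_from_endpoints <- function(x, y) {
  n2 <- 2 * length(x)
  mu <- sum(x + y) / n2
  num <- 2 * sum((x - mu) * (y - mu)) / n2
  den <- sum((x - mu)^2 + (y - mu)^2) / n2
  if (den <= 1e-12 * max(1, sum(x^2 + y^2) / n2)) return(NA_real_)
  num / den
}
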