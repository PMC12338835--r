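# Deterministic sub-stream seeds derived from a master seed.
#
# Each stochastic stage of a simulation (composition draw, per-species
# timeline, detection, false-positive placement, classification, threshold
# thinning) is seeded independently so that, e.g., changing the set of
# threshold levels never perturbs the detection draws of any grid cell.

# Fold an arbitrary tag (seed + labels + numeric levels) into [0, 2^31).
# Plain polynomial string hash mod a prime; exact in double arithmetic
# (intermediate values stay below 2^36 << 2^53).
derive_seed <- function(...) {
  parts <- vapply(list(...), function(x) {
    if (is.numeric(x)) {
      format(x, digits = 15, scientific = FALSE, trim = TRUE)
    } else {
      as.character(x)
    }
  }, character(1))
  h <- 0
  for (b in utf8ToInt(paste(parts, collapse = "/"))) {
    h <- (h * 31 + b) %% 2147483629
  }
  as.integer(h)
}
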