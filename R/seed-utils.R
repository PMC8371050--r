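#' Derive a component seed from a master seed
#'
#' All random components (item memories, permutation sets, tie-breakers,
#' channel noise, synthetic data) draw from streams derived deterministically
#' from one master seed, so that experiments are reproducible piecewise:
#' regenerating one component never perturbs another.
#'
#' @param seed Master seed (integer).
#' @param tag Character tag naming the component stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps seeds in integer range
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(tag)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# a NULL seed leaves the ambient RNG untouched.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
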