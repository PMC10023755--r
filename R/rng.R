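#' Derive a named random substream seed
#'
#' All randomness in the package flows from one user seed. Each stage draws
#' from its own substream whose seed is a deterministic hash of
#' `(seed, stage, index)`, so a stage can be re-run in isolation and still
#' reproduce the numbers it produced inside a full pipeline run. The hash is
#' a 31-bit multiplicative fold (exact in double arithmetic), so derived
#' seeds always fit a 32-bit R integer.
#'
#' @param seed Integer master seed.
#' @param stage Character stage name (e.g. `"phantom"`, `"compose"`).
#' @param index Integer index within the stage (e.g. slice number).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(as.character(stage))) h <- (h * 31 + b) %% m
  h <- (h * 31 + (as.numeric(index) %% m)) %% m
  as.integer(h)
}

# Evaluate `code` under a local RNG state seeded with `seed`;
# the caller's .Random.seed is untouched.
with_substream <- function(seed, code) {
  withr::with_seed(seed, code)
}
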