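#' Derive a child seed from the root seed
#'
#' All randomness in the simulator flows from one root seed. Each stage uses
#' its own stream index so that, e.g., regenerating the cohort does not
#' perturb the genotype draw. The map is a fixed affine congruence modulo
#' 2^31 - 1, so every derived seed is a valid 32-bit integer seed.
#'
#' @param seed Root seed (integer-valued scalar).
#' @param stream Non-negative stream index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed),
            is.numeric(stream), length(stream) == 1, stream >= 0)
  m <- 2147483647
  s <- ((abs(seed) %% m) * 48271 + (stream %% m) * 1299709 + 12345) %% m
  as.integer(s)
}
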