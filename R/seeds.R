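#' Derive a reproducible child seed from a parent seed
#'
#' All randomness in the package flows from one user-visible integer seed.
#' Child streams (per repetition, per cross-validation fold, per site, per
#' tree) are spawned deterministically by mixing the parent seed with one or
#' more small integer indices, so results do not depend on the order in
#' which components are trained. Arithmetic is done in doubles (exact below
#' 2^53) and reduced modulo 2^31 - 1 so the result is always a valid
#' 32-bit seed.
#'
#' @param seed Parent seed (non-negative integer).
#' @param ... One or more non-negative integer indices identifying the
#'   child stream.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(42, 1)
#' derive_seed(42, 1, 3) # nested stream
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1 (prime)
  s <- as.numeric(seed) %% m
  for (k in c(...)) {
    # LCG-style mixing; multipliers < 2^16 keep products < 2^47, exact
    s <- (s * 48271 + (as.numeric(k) + 1) * 9973) %% m
    s <- (s * 16807 + 12345) %% m
  }
  as.integer(s)
}
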