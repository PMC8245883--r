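#' Derive a child seed from a master seed
#'
#' Deterministic stable rule used everywhere the package splits one master
#' seed into per-replicate (or per-stage) seeds, so that replicate k of a
#' study is reproducible in isolation without generating replicates 1..k-1.
#' The rule is a Lehmer-style mixed congruential hash of (master, k) modulo
#' the Mersenne prime 2^31 - 1; results are valid `set.seed()` inputs.
#'
#' @param master Master seed (integer-valued).
#' @param k Child index (integer-valued, typically 1, 2, ...).
#' @return A single integer seed in \[1, 2^31 - 2\].
#' @export
child_seed <- function(master, k) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(k), length(k) == 1L, is.finite(k))
  m <- 2147483647  # 2^31 - 1, prime
  # doubles hold the intermediate products exactly (< 2^53)
  h <- (abs(master) %% m) * 48271 %% m
  h <- (h + (abs(k) %% m) * 69621) %% m
  h <- (h * 16807 + 12345) %% m
  as.integer(h %% (m - 1) + 1)
}
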