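#' Derive a per-cell seed from the master seed
#'
#' Every cell cycle is driven by its own RNG stream seeded from a
#' deterministic mix of the master seed and integer keys (replicate, phase,
#' cell id).  Results are therefore invariant to the order in which cells of
#' a lineage tree are simulated.  Mixing uses repeated Lehmer steps modulo
#' the Mersenne prime 2^31 - 1 in double precision (all intermediates stay
#' below 2^53, so the arithmetic is exact).
#'
#' @param master master seed (integer).
#' @param ... integer keys identifying the stream.
#' @return a single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647
  lehmer <- function(x) (x * 48271) %% m
  x <- (abs(master) %% (m - 1)) + 1
  for (k in c(17, ...)) {  # leading constant decorrelates from raw master
    x <- lehmer((x + (abs(k) %% m)) %% m)
    if (x == 0) x <- 1
    x <- lehmer(x)
    if (x == 0) x <- 1
  }
  as.integer(x)
}
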