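# Deterministic seed substreams.  All randomness in a simulated session flows
# from one integer session seed; each component (clock, schedule, playout,
# noise, protocol, ...) draws under a seed derived from (seed, label) so that
# components are individually reproducible and can be tested in isolation.

#' Derive a component seed from a session seed
#'
#' Deterministically maps a `(seed, label)` pair to an integer in
#' `[1, 2^31 - 2]`, used to seed the RNG of one named component of a
#' simulation.
#'
#' @param seed Integer session seed.
#' @param label Character label of the component substream.
#' @return A single integer seed.
#' @keywords internal
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(label) == 1L)
  p <- 2147483647  # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% p
  s <- (abs(as.numeric(seed)) %% p)
  # both terms < 2^31; products stay below 2^53, exact in doubles
  v <- (s * 48271 + h * 69621 + 1) %% p
  as.integer(if (v == 0) 1 else v)
}

# Evaluate `expr` under a derived seed, restoring the caller's RNG state.
with_substream <- function(seed, label, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(derive_seed(seed, label))
  expr
}
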