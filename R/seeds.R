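#' Derive a deterministic stream seed
#'
#' All randomness in the package flows from a single global seed; each
#' consumer (simulation, fold assignment, tuning, bootstrap iteration, ...)
#' derives its own stream seed so that stages can be re-run independently
#' without perturbing one another.
#'
#' @param seed integer global seed.
#' @param stream character label of the consuming stream.
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0)
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483647
  as.integer((seed * 48271 + h) %% 2147483647)
}
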