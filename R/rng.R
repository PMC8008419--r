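#' Reproducible substreams from a single root seed
#'
#' Every stochastic step of a run (each Monte Carlo evaluation, each particle
#' swarm search, each quasi-random scramble) consumes its own numbered
#' substream derived from one root seed. The substream counter is part of the
#' run state, so a checkpointed run resumed mid-way replays exactly the
#' remaining stream and reproduces an uninterrupted run bit-for-bit.
#'
#' @param root_seed Integer root seed for the whole run.
#' @return An `rng_stream` object (mutable environment holding the counter).
#' @export
rng_stream <- function(root_seed) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1, is.finite(root_seed))
  e <- new.env(parent = emptyenv())
  e$root <- as.double(root_seed) %% 2147483647
  e$counter <- 0
  class(e) <- "rng_stream"
  e
}

# deterministic mix of (root, counter) -> seed in [1, 2^31 - 2]; exact in doubles
substream_seed <- function(root, counter) {
  s <- (root * 48271 + counter * 16807 + 12345) %% 2147483647
  s <- (s * 69621) %% 2147483647
  as.integer(s + 1)
}

#' Draw the next substream seed and advance the counter
#' @param stream An [rng_stream()].
#' @return An integer seed; as a side effect the stream counter advances.
#' @export
stream_next_seed <- function(stream) {
  stopifnot(inherits(stream, "rng_stream"))
  s <- substream_seed(stream$root, stream$counter)
  stream$counter <- stream$counter + 1
  s
}

#' @export
print.rng_stream <- function(x, ...) {
  cat(sprintf("<rng_stream> root=%d counter=%d\n", as.integer(x$root), x$counter))
  invisible(x)
}

stream_state <- function(stream) list(root = stream$root, counter = stream$counter)

stream_restore <- function(state) {
  s <- rng_stream(state$root)
  s$counter <- state$counter
  s
}
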