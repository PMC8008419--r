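# Sobol low-discrepancy sequences, direction numbers from the Joe-Kuo
# 6.21201 tables (first 10 dimensions; D <= 10 covers design spaces here).
# 30-bit precision keeps all bit operations inside R's signed integers.

.sobol_dirtab <- list(
  # each entry: list(s = poly degree, a = encoded coefficients, m = initial values)
  list(s = 1, a = 0, m = c(1)),
  list(s = 2, a = 1, m = c(1, 3)),
  list(s = 3, a = 1, m = c(1, 3, 1)),
  list(s = 3, a = 2, m = c(1, 1, 1)),
  list(s = 4, a = 1, m = c(1, 1, 3, 3)),
  list(s = 4, a = 4, m = c(1, 3, 5, 13)),
  list(s = 5, a = 2, m = c(1, 1, 5, 5, 17)),
  list(s = 5, a = 4, m = c(1, 1, 5, 5, 5)),
  list(s = 5, a = 7, m = c(1, 1, 7, 11, 19))
)

.sobol_bits <- 30L

# direction vectors V[1..L] for dimension d (d = 1 is the van der Corput base-2)
.sobol_directions <- function(d, L = .sobol_bits) {
  if (d == 1) return(bitwShiftL(1L, L - seq_len(L)))
  tab <- .sobol_dirtab[[d - 1]]
  s <- tab$s; a <- tab$a
  m <- integer(L)
  m[seq_len(min(s, L))] <- tab$m[seq_len(min(s, L))]
  if (L > s) {
    for (i in (s + 1):L) {
      mi <- bitwXor(m[i - s], bitwShiftL(m[i - s], s))
      if (s > 1) for (k in 1:(s - 1)) {
        ak <- bitwAnd(bitwShiftR(a, s - 1 - k), 1L)
        if (ak == 1L) mi <- bitwXor(mi, bitwShiftL(m[i - k], k))
      }
      m[i] <- mi
    }
  }
  bitwShiftL(m, L - seq_len(L))
}

#' Generate a Sobol quasi-random sequence in the unit hypercube
#'
#' Space-filling low-discrepancy points used for initial designs and the
#' fixed-design comparator. With a seed, each dimension receives a random
#' digital (XOR) shift; this scrambling preserves the dyadic balance property
#' of the sequence while making independent replications possible. Without a
#' seed the raw sequence (whose first point is the origin) is returned.
#'
#' @param n Number of points.
#' @param d Dimension (1 to 10).
#' @param seed Optional integer seed for the digital shift.
#' @param skip Number of initial sequence elements to skip.
#' @return An `n` x `d` matrix with entries in `[0, 1)`.
#' @export
sobol_sequence <- function(n, d, seed = NULL, skip = 0) {
  stopifnot(n >= 1, d >= 1, d <= 10, skip >= 0)
  L <- .sobol_bits
  V <- vapply(seq_len(d), .sobol_directions, integer(L))  # L x d
  # state of point `skip` directly from its Gray code, then step forward
  state <- integer(d)
  g <- bitwXor(skip, bitwShiftR(skip, 1L))
  for (b in seq_len(L)) {
    if (bitwAnd(g, 1L) == 1L) state <- bitwXor(state, V[b, ])
    g <- bitwShiftR(g, 1L)
  }
  X <- matrix(0L, n, d)
  X[1, ] <- state
  if (n > 1) {
    for (i in 2:n) {
      km1 <- skip + i - 2L  # gray-code bit position flipped at this step
      c <- 1L
      while (bitwAnd(km1, 1L) == 1L) { km1 <- bitwShiftR(km1, 1L); c <- c + 1L }
      state <- bitwXor(state, V[c, ])
      X[i, ] <- state
    }
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    shift <- as.integer(floor(stats::runif(d) * 2^L))
    X <- t(apply(X, 1, bitwXor, b = shift))
    if (d == 1) X <- matrix(X, ncol = 1)
  }
  X / 2^L
}

#' Sobol initial design over a solution space
#'
#' Scales a (digitally shifted) Sobol sequence to the design box and rounds
#' integer dimensions half-up. Points that collide after rounding are
#' replaced by subsequent sequence elements so the design always holds
#' `size` distinct design points.
#'
#' @param space A [solution_space()].
#' @param size Number of design points.
#' @param seed Integer seed for the digital shift (or an [rng_stream()]).
#' @return A `size` x D matrix of design points (named columns).
#' @export
sobol_design <- function(space, size, seed = NULL) {
  stopifnot(inherits(space, "solution_space"), size >= 1)
  if (inherits(seed, "rng_stream")) seed <- stream_next_seed(seed)
  d <- space_dim(space)
  if (all(space$integer)) {
    lattice <- prod(floor(space$upper) - ceiling(space$lower) + 1)
    if (size > lattice)
      stop("could not find ", size, " distinct design points after rounding; ",
           "the integer box holds only ", lattice, " points")
  }
  keep <- NULL
  offset <- 0
  chunk <- size
  while (is.null(keep) || nrow(keep) < size) {
    u <- sobol_sequence(chunk, d, seed = seed, skip = offset)
    pts <- space_round(space, space_unscale(space, u))
    keep <- unique(rbind(keep, pts))
    offset <- offset + chunk
    chunk <- max(8, size)
    if (offset > 10000 * size)
      stop("could not find ", size, " distinct design points after rounding; ",
           "the integer box may hold fewer points than requested")
  }
  keep[seq_len(size), , drop = FALSE]
}
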