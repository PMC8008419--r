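#' Define a bounded solution space of trial design parameters
#'
#' A solution space is the box of candidate designs: per-dimension names,
#' lower and upper bounds, and integrality flags. Surrogate models and the
#' inner particle-swarm search operate on the continuous box; integer
#' dimensions are rounded (half-up) only when a design is about to be
#' evaluated or reported.
#'
#' @param names Character vector of design-parameter names.
#' @param lower,upper Numeric vectors of bounds (same length as `names`),
#'   with `lower < upper` elementwise.
#' @param integer Logical vector: is each dimension integer-valued?
#' @return An object of class `solution_space`.
#' @examples
#' solution_space(c("k", "n"), lower = c(10, 100), upper = c(100, 500),
#'                integer = c(TRUE, TRUE))
#' @export
solution_space <- function(names, lower, upper, integer = rep(FALSE, length(names))) {
  stopifnot(is.character(names), length(names) >= 1,
            length(lower) == length(names), length(upper) == length(names),
            length(integer) == length(names))
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("solution space bounds must be finite")
  if (any(upper <= lower))
    stop("invalid solution space: upper bound not above lower bound for ",
         paste(names[upper <= lower], collapse = ", "))
  structure(
    list(names = names, lower = as.numeric(lower), upper = as.numeric(upper),
         integer = as.logical(integer)),
    class = "solution_space"
  )
}

#' @export
print.solution_space <- function(x, ...) {
  cat("<solution_space> ", length(x$names), " dimensions\n", sep = "")
  for (i in seq_along(x$names)) {
    cat(sprintf("  %s: [%g, %g]%s\n", x$names[i], x$lower[i], x$upper[i],
                if (x$integer[i]) " (integer)" else ""))
  }
  invisible(x)
}

space_dim <- function(space) length(space$names)

#' @noRd
as_design_matrix <- function(space, x) {
  if (is.data.frame(x)) x <- as.matrix(x[, space$names, drop = FALSE])
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != space_dim(space))
    stop("design has ", ncol(x), " columns; space has ", space_dim(space))
  colnames(x) <- space$names
  x
}

# affine map raw box -> unit box (GP inputs are always scaled)
space_scale <- function(space, x) {
  x <- as_design_matrix(space, x)
  sweep(sweep(x, 2, space$lower, "-"), 2, space$upper - space$lower, "/")
}

space_unscale <- function(space, u) {
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  x <- sweep(sweep(u, 2, space$upper - space$lower, "*"), 2, space$lower, "+")
  colnames(x) <- space$names
  x
}

# round-half-up on integer dimensions, clamp into the box
space_round <- function(space, x) {
  x <- as_design_matrix(space, x)
  for (d in which(space$integer)) x[, d] <- floor(x[, d] + 0.5)
  for (d in seq_len(ncol(x))) x[, d] <- pmin(pmax(x[, d], space$lower[d]), space$upper[d])
  x
}

space_contains <- function(space, x) {
  x <- as_design_matrix(space, x)
  apply(x, 1, function(row) all(row >= space$lower - 1e-9) && all(row <= space$upper + 1e-9))
}
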