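# Pareto dominance, approximation sets, and exact dominated hypervolume in
# two and three objectives (all objectives minimised).

#' Pareto dominance between two objective vectors
#'
#' `a` dominates `b` when `a` is no worse in every objective and strictly
#' better in at least one (all objectives minimised). The relation is
#' irreflexive: a vector never dominates itself.
#'
#' @param a,b Numeric objective vectors of equal length.
#' @return `TRUE` iff `a` dominates `b`.
#' @examples
#' dominates(c(100, 10), c(120, 10))  # TRUE
#' dominates(c(100, 10), c(80, 13))   # FALSE
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b))
    stop("objective vectors have different lengths: ", length(a), " vs ", length(b))
  all(a <= b) && any(a < b)
}

# logical index of nondominated rows of an objective matrix; weak-dominance
# ties collapse to the first-seen row (keeps approximation sets minimal)
nondominated <- function(Y) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n == 0) return(logical(0))
  if (ncol(Y) == 2) {
    # sort by first objective, then second; sweep a running minimum
    ord <- order(Y[, 1], Y[, 2])
    keep <- logical(n)
    best2 <- Inf
    seen <- matrix(numeric(0), 0, 2)
    for (i in ord) {
      if (Y[i, 2] < best2) {
        dup <- nrow(seen) > 0 && any(seen[, 1] == Y[i, 1] & seen[, 2] == Y[i, 2])
        if (!dup) { keep[i] <- TRUE; seen <- rbind(seen, Y[i, ]) }
        best2 <- Y[i, 2]
      }
    }
    return(keep)
  }
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (j in seq_len(n)) {
      if (i == j || !keep[i]) next
      if (dominates(Y[j, ], Y[i, ]) ||
          (j < i && all(Y[j, ] == Y[i, ]))) keep[i] <- FALSE
    }
  }
  keep
}

#' Filter a set of evaluated designs to its nondominated subset
#'
#' Retains exactly the rows whose objective vectors are not dominated by any
#' other row. Rows with identical objective vectors collapse to the
#' first-evaluated one.
#'
#' @param data Data frame (or matrix) holding the candidate points.
#' @param objectives Character vector naming the objective columns; by
#'   default all columns are treated as objectives.
#' @return A tibble: the nondominated rows, in their original order.
#' @export
pareto_filter <- function(data, objectives = NULL) {
  data <- tibble::as_tibble(as.data.frame(data))
  if (is.null(objectives)) objectives <- names(data)
  Y <- as.matrix(data[, objectives, drop = FALSE])
  data[nondominated(Y), , drop = FALSE]
}

.hv_check <- function(Y, ref) {
  B <- length(ref)
  if (B > 3 || B < 2)
    stop("dominated hypervolume supports 2 or 3 objectives, not ", B)
  if (ncol(Y) != B) stop("objective matrix has ", ncol(Y), " columns; reference has ", B)
  ok <- apply(Y, 1, function(r) all(r < ref))
  if (any(!ok))
    warning(sum(!ok), " point(s) not strictly better than the reference point contribute 0")
  Y[ok, , drop = FALSE]
}

.hv2 <- function(Y, ref) {
  if (nrow(Y) == 0) return(0)
  Y <- Y[nondominated(Y), , drop = FALSE]
  ord <- order(Y[, 1], Y[, 2])
  Y <- Y[ord, , drop = FALSE]
  x <- c(Y[-1, 1], ref[1])
  sum((x - Y[, 1]) * (ref[2] - Y[, 2]))
}

.hv3 <- function(Y, ref) {
  if (nrow(Y) == 0) return(0)
  Y <- Y[nondominated(Y), , drop = FALSE]
  z <- sort(unique(Y[, 3]))
  vol <- 0
  for (i in seq_along(z)) {
    znext <- if (i < length(z)) z[i + 1] else ref[3]
    slice <- Y[Y[, 3] <= z[i], c(1, 2), drop = FALSE]
    vol <- vol + .hv2(slice, ref[1:2]) * (znext - z[i])
  }
  vol
}

#' Exact dominated hypervolume of an approximation set
#'
#' The objective-space volume dominated by the set and bounded above by the
#' reference point: the scalar quality measure of an approximation set.
#' Computed exactly: in two objectives by the sorted staircase sum, in three
#' by sweeping slices of the third objective (each slice a 2-D staircase).
#' Points not strictly better than the reference point in every objective
#' contribute zero (with a warning).
#'
#' @param points Matrix or data frame of objective vectors (rows = set
#'   members, all objectives minimised).
#' @param ref Reference point, worse than every scored vector.
#' @return The dominated hypervolume (0 for an empty set).
#' @examples
#' A <- rbind(c(589, 24), c(705, 20), c(810, 12), c(982, 10))
#' dominated_hypervolume(A, ref = c(1200, 30))  # 9202
#' @export
dominated_hypervolume <- function(points, ref) {
  Y <- as.matrix(points)
  if (length(Y) == 0 || nrow(Y) == 0) return(0)
  Y <- .hv_check(Y, ref)
  if (nrow(Y) == 0) return(0)
  if (length(ref) == 2) .hv2(Y, ref) else .hv3(Y, ref)
}

#' Hypervolume improvement of a candidate objective vector
#'
#' `H(A + candidate) - H(A)`: the gain in dominated hypervolume if the
#' candidate joined the set. Zero when the candidate is dominated by (or
#' equal to) a member; never negative.
#'
#' @param points Current set's objective vectors (matrix/data frame).
#' @param candidate Objective vector of the candidate.
#' @param ref Reference point.
#' @return The nonnegative hypervolume improvement.
#' @export
hypervolume_improvement <- function(points, candidate, ref) {
  Y <- as.matrix(points)
  base <- dominated_hypervolume(Y, ref)
  withcand <- suppressWarnings(dominated_hypervolume(rbind(Y, candidate), ref))
  max(withcand - base, 0)
}

# batch hypervolume improvement: one row per candidate. The 2-D path walks
# the staircase of the (nondominated) current set once per candidate with
# vectorised segment sums; the 3-D path falls back to set recomputation.
.hvi_batch <- function(current_Y, cand_Y, ref) {
  current_Y <- as.matrix(current_Y)
  cand_Y <- as.matrix(cand_Y)
  q <- nrow(cand_Y)
  if (length(ref) != 2) {
    return(vapply(seq_len(q), function(i)
      hypervolume_improvement(current_Y, cand_Y[i, ], ref), numeric(1)))
  }
  if (nrow(current_Y) > 0) {
    S <- current_Y[nondominated(current_Y), , drop = FALSE]
    S <- S[order(S[, 1]), , drop = FALSE]
  } else {
    S <- matrix(numeric(0), 0, 2)
  }
  out <- numeric(q)
  for (i in seq_len(q)) {
    cx <- cand_Y[i, 1]; cy <- cand_Y[i, 2]
    if (cx >= ref[1] || cy >= ref[2]) next
    left <- S[, 1] <= cx
    f0 <- min(c(S[left, 2], ref[2]))
    if (f0 <= cy) next  # dominated by a member
    xs <- c(cx, S[!left, 1], ref[1])
    floors <- cummin(c(f0, S[!left, 2]))
    out[i] <- sum(diff(xs) * pmax(pmin(floors, ref[2]) - cy, 0))
  }
  out
}

#' Default reference point for a problem's objective space
#'
#' Per-objective upper bound of the objectives over the search box, scaled by
#' 1.1. The specific choice is immaterial to the method provided the point is
#' worse than all anticipated objective values.
#'
#' @param problem An [ssd_problem()].
#' @return Numeric reference point of length B.
#' @export
default_reference_point <- function(problem) {
  space <- problem$space
  corners <- as.matrix(expand.grid(lapply(seq_along(space$names), function(d)
    c(space$lower[d], space$upper[d]))))
  colnames(corners) <- space$names
  Y <- problem$objectives(corners)
  unname(apply(as.matrix(Y), 2, max) * 1.1)
}
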