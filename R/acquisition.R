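# Constrained multi-objective expected improvement for Monte-Carlo-estimated
# constraints: hypervolume gain of a candidate times, for each constraint,
# the probability that the candidate will be deemed feasible after its
# planned (noisy) evaluation.

#' Upper feasibility quantile of a constraint prediction
#'
#' A design is deemed feasible when the upper `100*p`% quantile
#' `q = m + qnorm(p) * s` of the surrogate's predictive distribution of the
#' constraint value lies at or below zero.
#'
#' @param mean,sd Predictive mean(s) and standard deviation(s) of the
#'   constraint function (already threshold-shifted, so feasible means <= 0).
#' @param level Quantile level `p` in (0.5, 1); fixed per run.
#' @return The quantile(s) `q`.
#' @examples
#' feasibility_quantile(-0.02, 0.01, 0.9)  # -0.00718..., deemed feasible
#' @export
feasibility_quantile <- function(mean, sd, level = 0.9) {
  stopifnot(all(sd >= 0))
  mean + stats::qnorm(level) * sd
}

#' Predictive distribution of the post-evaluation feasibility quantile
#'
#' Before a planned Monte Carlo evaluation with error standard deviation
#' `omega`, the revised quantile `q+` is itself normally distributed:
#' `m+ = m + qnorm(p) * sqrt(omega^2 s^2 / (omega^2 + s^2))` and
#' `s+^2 = s^4 / (omega^2 + s^2)`. An infinitely noisy evaluation
#' (`omega -> Inf`) leaves the quantile at `q` with no spread; a perfect one
#' (`omega = 0`) makes `q+ ~ N(m, s^2)`.
#'
#' @param mean,sd Current predictive mean(s)/sd(s) of the constraint.
#' @param omega Standard error of the planned Monte Carlo evaluation.
#' @param level Quantile level `p`.
#' @return A tibble with columns `mean_plus`, `sd_plus`.
#' @export
quantile_update <- function(mean, sd, omega, level = 0.9) {
  stopifnot(all(sd >= 0), all(omega >= 0))
  n <- max(length(mean), length(sd), length(omega))
  mean <- rep_len(mean, n); sd <- rep_len(sd, n); omega <- rep_len(omega, n)
  s2 <- sd^2; w2 <- omega^2
  tot <- w2 + s2
  shrink2 <- ifelse(tot > 0, w2 * s2 / tot, 0)   # both zero -> degenerate at m
  sp2 <- ifelse(tot > 0, s2^2 / tot, 0)
  inf <- is.infinite(omega)
  shrink2[inf] <- s2[inf]; sp2[inf] <- 0
  tibble::tibble(mean_plus = mean + stats::qnorm(level) * sqrt(shrink2),
                 sd_plus = sqrt(sp2))
}

#' Probability a design will be deemed feasible after evaluation
#'
#' `Phi(-m+ / s+)`; degenerate (`s+ = 0`) predictions give 1 when `m+ <= 0`
#' and 0 otherwise.
#'
#' @param mean_plus,sd_plus Predictive moments of the post-evaluation
#'   quantile, from [quantile_update()].
#' @return Probability vector.
#' @export
prob_deemed_feasible <- function(mean_plus, sd_plus) {
  ifelse(sd_plus > 0, stats::pnorm(-mean_plus / sd_plus),
         as.numeric(mean_plus <= 0))
}

#' Expected improvement of candidate designs
#'
#' For each candidate: the hypervolume improvement its (deterministic)
#' objective vector would add to the current approximation set, multiplied
#' across constraints by the probability that the candidate will be deemed
#' feasible after a planned evaluation of `planned_n` Monte Carlo samples.
#' The planned evaluation's error is `sqrt(m(1-m)/N)` with `m` the
#' surrogate's mean of the operating characteristic, clipped to
#' `[0.001, 0.999]`.
#'
#' @param X Matrix of candidate design points (raw values; rows =
#'   candidates).
#' @param models List of fitted `gp_model`s, one per constraint (modelling
#'   the operating characteristic itself).
#' @param thresholds Numeric vector of nominal constraint thresholds (the
#'   constraint is `OC - threshold <= 0`).
#' @param current_Y Matrix of objective vectors of the current approximation
#'   set (0 rows allowed).
#' @param ref Reference point.
#' @param objectives Function mapping a design matrix to an objective
#'   matrix.
#' @param level Feasibility quantile level `p`.
#' @param planned_n Monte Carlo sample size of the planned evaluation.
#' @return A tibble with columns `ei`, `hvi`, `p_feasible` (the product over
#'   constraints).
#' @export
expected_improvement <- function(X, models, thresholds, current_Y, ref,
                                 objectives, level = 0.9, planned_n = 100) {
  res <- .ei_core(as.matrix(X), models, thresholds, current_Y, ref,
                  objectives, level, planned_n)
  tibble::tibble(ei = res$ei, hvi = res$hvi, p_feasible = res$p_feasible)
}

# tibble-free core used inside the particle swarm loop
.ei_core <- function(X, models, thresholds, current_Y, ref, objectives,
                     level, planned_n) {
  Y <- as.matrix(objectives(X))
  hvi <- .hvi_batch(current_Y, Y, ref)
  pfeas <- rep(1, nrow(X))
  zp <- stats::qnorm(level)
  for (j in seq_along(models)) {
    pr <- .gp_predict_raw(models[[j]], X)
    m_oc <- pmin(pmax(pr$mean, 0.001), 0.999)
    w2 <- m_oc * (1 - m_oc) / planned_n
    s2 <- pr$var
    tot <- w2 + s2
    m <- pr$mean - thresholds[j]
    mp <- m + zp * sqrt(ifelse(tot > 0, w2 * s2 / tot, 0))
    sp <- sqrt(ifelse(tot > 0, s2^2 / tot, 0))
    pfeas <- pfeas * ifelse(sp > 0, stats::pnorm(-mp / sp), as.numeric(mp <= 0))
  }
  list(ei = hvi * pfeas, hvi = hvi, p_feasible = pfeas)
}

#' Control parameters for the particle swarm inner search
#'
#' @param swarm Swarm size.
#' @param iterations Number of velocity/position updates.
#' @param inertia,cognitive,social Standard PSO weights.
#' @return A list of class `pso_control`.
#' @export
pso_control <- function(swarm = 40, iterations = 200, inertia = 0.7298,
                        cognitive = 1.49618, social = 1.49618) {
  structure(list(swarm = swarm, iterations = iterations, inertia = inertia,
                 cognitive = cognitive, social = social),
            class = "pso_control")
}

# maximise fn_batch (matrix -> numeric) over a box by particle swarm with
# reflecting bounds; deterministic given seed
pso_maximize <- function(fn_batch, lower, upper, control = pso_control(), seed = 1) {
  d <- length(lower)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  ns <- control$swarm
  X <- matrix(stats::runif(ns * d), ns, d)
  X <- sweep(sweep(X, 2, upper - lower, "*"), 2, lower, "+")
  V <- matrix(stats::runif(ns * d, -1, 1), ns, d) *
    matrix(rep(upper - lower, each = ns), ns, d) * 0.1
  f <- fn_batch(X)
  init_best <- max(f)
  pbest <- X; pbestf <- f
  g <- which.max(f)
  gbest <- X[g, ]; gbestf <- f[g]
  for (it in seq_len(control$iterations)) {
    r1 <- matrix(stats::runif(ns * d), ns, d)
    r2 <- matrix(stats::runif(ns * d), ns, d)
    V <- control$inertia * V +
      control$cognitive * r1 * (pbest - X) +
      control$social * r2 * (sweep(-X, 2, gbest, "+"))
    X <- X + V
    # reflect at the box boundary and reverse the velocity component
    for (k in seq_len(d)) {
      lo <- X[, k] < lower[k]; hi <- X[, k] > upper[k]
      X[lo, k] <- pmin(2 * lower[k] - X[lo, k], upper[k])
      X[hi, k] <- pmax(2 * upper[k] - X[hi, k], lower[k])
      V[lo | hi, k] <- -V[lo | hi, k]
    }
    f <- fn_batch(X)
    imp <- f > pbestf
    pbest[imp, ] <- X[imp, ]; pbestf[imp] <- f[imp]
    g <- which.max(pbestf)
    if (pbestf[g] > gbestf) { gbest <- pbest[g, ]; gbestf <- pbestf[g] }
  }
  list(par = gbest, value = gbestf, init_best = init_best)
}

#' Maximise expected improvement over the design box
#'
#' Particle swarm search over the continuous box (integer dimensions are
#' rounded later, at evaluation time). If expected improvement is zero
#' everywhere the swarm visited, falls back to the visited point with the
#' highest product of feasibility probabilities — pure exploration of the
#' feasibility boundary — and flags the fallback.
#'
#' @param problem An [ssd_problem()].
#' @param models List of constraint `gp_model`s.
#' @param current_Y Objective matrix of the current approximation set.
#' @param level Feasibility quantile level.
#' @param planned_n Planned Monte Carlo sample size.
#' @param control A [pso_control()].
#' @param stream An [rng_stream()] or integer seed.
#' @return List with `design` (named numeric, continuous scale), `ei`,
#'   `p_feasible`, `fallback` (logical).
#' @export
maximize_ei <- function(problem, models, current_Y, level = 0.9,
                        planned_n = 100, control = pso_control(), stream = 1) {
  seed <- if (inherits(stream, "rng_stream")) stream_next_seed(stream) else as.integer(stream)
  space <- problem$space
  best_pf <- new.env(parent = emptyenv())
  best_pf$p <- -Inf; best_pf$x <- NULL
  fn <- function(X) {
    colnames(X) <- space$names
    res <- .ei_core(X, models, problem$thresholds, current_Y,
                    problem$ref_point, problem$objectives, level, planned_n)
    i <- which.max(res$p_feasible)
    if (res$p_feasible[i] > best_pf$p) {
      best_pf$p <- res$p_feasible[i]; best_pf$x <- X[i, ]
    }
    res$ei
  }
  out <- pso_maximize(fn, space$lower, space$upper, control, seed)
  fallback <- !(out$value > 0)
  par <- if (fallback && !is.null(best_pf$x)) best_pf$x else out$par
  names(par) <- space$names
  res <- expected_improvement(matrix(par, 1, dimnames = list(NULL, space$names)),
                              models, problem$thresholds, current_Y,
                              problem$ref_point, problem$objectives,
                              level, planned_n)
  list(design = par, ei = unname(res$ei[1]),
       p_feasible = unname(res$p_feasible[1]), fallback = fallback)
}
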