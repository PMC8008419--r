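# The efficient global optimisation loop: Sobol initial design, then iterate
# fit GP per constraint -> maximise expected improvement -> evaluate by
# Monte Carlo -> refresh the approximation set.

#' Control parameters for an EGO run
#'
#' @param iterations Number of EGO iterations after the initial design.
#' @param init_size Initial Sobol design size E; default ten points per
#'   design dimension, capped at `iterations` so the initial phase consumes
#'   at most half of the evaluation budget.
#' @param n_per_eval Monte Carlo samples N per operating-characteristic
#'   evaluation.
#' @param quantile_level Feasibility quantile level p (fixed for the run).
#' @param seed Root seed; every stochastic step derives a numbered substream
#'   from it.
#' @param pso A [pso_control()] for the inner search.
#' @param gp A [gp_control()] for surrogate fitting.
#' @param checkpoint Optional path; run state is written there after every
#'   evaluation.
#' @param verbose Print per-iteration progress?
#' @return A list of class `ego_control`.
#' @export
ego_control <- function(iterations = 30, init_size = NULL, n_per_eval = 100,
                        quantile_level = 0.9, seed = 1,
                        pso = pso_control(), gp = gp_control(),
                        checkpoint = NULL, verbose = FALSE) {
  stopifnot(iterations >= 0, n_per_eval >= 1,
            quantile_level > 0.5, quantile_level < 1)
  structure(list(iterations = iterations, init_size = init_size,
                 n_per_eval = n_per_eval, quantile_level = quantile_level,
                 seed = seed, pso = pso, gp = gp, checkpoint = checkpoint,
                 verbose = verbose),
            class = "ego_control")
}

.default_init_size <- function(space, control) {
  E <- control$init_size
  if (is.null(E)) {
    E <- 10 * space_dim(space)
    if (control$iterations > 0) E <- min(E, control$iterations)
  }
  max(2, E)
}

# evaluate one design (all constraints, N samples each); updates archive
# in place and appends log rows. archive: env with X (matrix), succ, nsamp
# (matrices n_designs x C, operating-characteristic scale)
.evaluate_design <- function(arch, problem, sim, x, n_per_eval, stream,
                             iteration, pred = NULL, ei = NA_real_,
                             p_feasible = NA_real_) {
  C <- length(problem$constraints)
  key <- paste(x, collapse = "|")
  idx <- match(key, arch$keys)
  new_design <- is.na(idx)
  if (new_design) {
    arch$X <- rbind(arch$X, x)
    arch$succ <- rbind(arch$succ, rep(0, C))
    arch$nsamp <- rbind(arch$nsamp, rep(0, C))
    arch$keys <- c(arch$keys, key)
    idx <- length(arch$keys)
  }
  t0 <- proc.time()[["elapsed"]]
  rows <- vector("list", C)
  for (j in seq_len(C)) {
    ct <- problem$constraints[[j]]
    est <- estimate_oc(sim, x, ct$hypothesis, n_per_eval, stream)
    oc_succ <- .oc_successes(ct, est$successes, est$n_samples)
    arch$succ[idx, j] <- arch$succ[idx, j] + oc_succ
    arch$nsamp[idx, j] <- arch$nsamp[idx, j] + est$n_samples
    rows[[j]] <- tibble::tibble(
      iteration = iteration,
      tibble::as_tibble(as.data.frame(matrix(x, 1, dimnames = list(NULL, problem$space$names)))),
      constraint = ct$name, hypothesis = ct$hypothesis,
      n_samples = est$n_samples, successes = oc_succ,
      estimate = oc_succ / est$n_samples,
      std_error = mc_standard_error(oc_succ / est$n_samples, est$n_samples),
      pred_mean = if (is.null(pred)) NA_real_ else pred$mean[j],
      pred_sd = if (is.null(pred)) NA_real_ else pred$sd[j],
      ei = ei, p_feasible = p_feasible, pooled = !new_design,
      elapsed = proc.time()[["elapsed"]] - t0)
  }
  arch$log <- dplyr::bind_rows(arch$log, dplyr::bind_rows(rows))
  invisible(idx)
}

# pooled per-design OC estimates and noise variances for constraint j
.archive_targets <- function(arch, j) {
  est <- arch$succ[, j] / arch$nsamp[, j]
  list(y = est, noise = mc_standard_error(est, arch$nsamp[, j])^2)
}

.fit_constraint_gps <- function(arch, problem, control) {
  lapply(seq_along(problem$constraints), function(j) {
    tg <- .archive_targets(arch, j)
    fit_gp(arch$X, tg$y, tg$noise, space = problem$space, control = control$gp)
  })
}

#' Run the efficient global optimisation algorithm
#'
#' Evaluates a Sobol initial design (each constraint's operating
#' characteristic at each point with N Monte Carlo samples), then iterates:
#' fit one Gaussian process per constraint to all data so far, maximise
#' constrained expected hypervolume improvement by particle swarm over the
#' continuous box, round integer dimensions (half-up), evaluate the
#' proposal, and refresh the approximation set. A proposal that rounds onto
#' an already-evaluated design pools its new replicates with the old ones
#' (successes and N add, so the noise entry shrinks); budget is consumed
#' either way, keeping total simulator draws at exactly
#' `(E + iterations) * N * C`.
#'
#' @param problem An [ssd_problem()].
#' @param sim A [trial_simulator()] honouring the problem's hypothesis
#'   labels.
#' @param control An [ego_control()].
#' @return An object of class `ego_run` with the evaluation log, fitted
#'   models, and final approximation set.
#' @export
run_ego <- function(problem, sim, control = ego_control()) {
  stopifnot(inherits(problem, "ssd_problem"), inherits(sim, "trial_simulator"))
  for (ct in problem$constraints)
    if (!ct$hypothesis %in% sim$hypotheses)
      stop("simulator does not support hypothesis '", ct$hypothesis, "'")
  E <- .default_init_size(problem$space, control)
  C <- length(problem$constraints)
  if (control$verbose)
    message("total budget: ", (E + control$iterations) * control$n_per_eval * C,
            " simulator draws (", E, " initial + ", control$iterations,
            " iterated evaluations, N = ", control$n_per_eval, ", ",
            C, " constraint", if (C > 1) "s" else "", ")")
  stream <- rng_stream(control$seed)
  arch <- new.env(parent = emptyenv())
  arch$X <- NULL; arch$succ <- NULL; arch$nsamp <- NULL; arch$keys <- character(0)
  arch$log <- NULL

  X0 <- sobol_design(problem$space, E, seed = stream)
  for (i in seq_len(E)) {
    .evaluate_design(arch, problem, sim, X0[i, ], control$n_per_eval, stream,
                     iteration = 0L)
    .maybe_checkpoint(arch, problem, control, stream, models = NULL)
  }
  run <- .ego_iterate(arch, problem, sim, control, stream,
                      from_iter = 1L, to_iter = control$iterations)
  run
}

# shared iterative phase (also used by resume)
.ego_iterate <- function(arch, problem, sim, control, stream, from_iter, to_iter) {
  models <- NULL
  if (to_iter >= from_iter) {
    for (t in seq(from_iter, to_iter)) {
      models <- .fit_constraint_gps(arch, problem, control)
      approx <- .approx_from_models(arch, problem, models, control$quantile_level)
      prop <- maximize_ei(problem, models, approx$Y, control$quantile_level,
                          control$n_per_eval, control$pso, stream)
      x <- drop(space_round(problem$space, prop$design))
      pred <- do.call(rbind, lapply(models, function(m)
        predict(m, matrix(x, 1, dimnames = list(NULL, problem$space$names)))))
      .evaluate_design(arch, problem, sim, x, control$n_per_eval, stream,
                       iteration = as.integer(t), pred = pred, ei = prop$ei,
                       p_feasible = prop$p_feasible)
      if (control$verbose)
        message(sprintf("iter %d: design (%s), EI %.4g%s", t,
                        paste(signif(x, 4), collapse = ", "), prop$ei,
                        if (prop$fallback) " [exploration fallback]" else ""))
      .maybe_checkpoint(arch, problem, control, stream, models, iteration = t)
    }
  }
  models <- .fit_constraint_gps(arch, problem, control)
  approx <- .approx_from_models(arch, problem, models, control$quantile_level)
  structure(
    list(problem = problem, sim = sim, control = control,
         log = tibble::as_tibble(arch$log),
         archive = list(X = arch$X, successes = arch$succ, n_samples = arch$nsamp),
         models = models, approx = approx$tbl,
         iterations_done = to_iter, stream = stream_state(stream)),
    class = "ego_run"
  )
}

# feasible nondominated subset of the archive under the current GPs
.approx_from_models <- function(arch, problem, models, level) {
  X <- arch$X
  n <- nrow(X)
  C <- length(models)
  q <- matrix(NA_real_, n, C)
  est <- matrix(NA_real_, n, C)
  for (j in seq_len(C)) {
    pr <- predict(models[[j]], X)
    q[, j] <- feasibility_quantile(pr$mean - problem$thresholds[j], pr$sd, level)
    est[, j] <- arch$succ[, j] / arch$nsamp[, j]
  }
  feasible <- rowSums(q <= 0) == C
  Y <- problem$objectives(X)
  sel <- which(feasible)
  if (length(sel) > 0) sel <- sel[nondominated(Y[sel, , drop = FALSE])]
  cnames <- vapply(problem$constraints, `[[`, character(1), "name")
  tbl <- dplyr::bind_cols(
    tibble::as_tibble(as.data.frame(X[sel, , drop = FALSE])),
    tibble::as_tibble(as.data.frame(Y[sel, , drop = FALSE])),
    tibble::as_tibble(as.data.frame(stats::setNames(
      as.data.frame(est[sel, , drop = FALSE]), paste0("estimate_", cnames)))),
    tibble::as_tibble(as.data.frame(stats::setNames(
      as.data.frame(q[sel, , drop = FALSE]), paste0("q_", cnames))))
  )
  list(tbl = tbl, Y = Y[sel, , drop = FALSE], feasible = feasible, q = q)
}

#' Extract the approximation set from a run under its current surrogates
#'
#' Recomputes the feasibility quantile of every evaluated design under the
#' run's (final) Gaussian processes; designs with every quantile at or below
#' zero form the feasible pool, and the nondominated subset of the pool is
#' returned. New data can therefore evict a design that was previously
#' deemed feasible.
#'
#' @param run An `ego_run`.
#' @param level Feasibility quantile level; default: the run's own.
#' @return A tibble: design columns, objective columns, per-constraint
#'   pooled estimates and feasibility quantiles.
#' @export
extract_approximation_set <- function(run, level = NULL) {
  stopifnot(inherits(run, "ego_run"))
  level <- level %||% run$control$quantile_level
  arch <- list2env(list(X = run$archive$X, succ = run$archive$successes,
                        nsamp = run$archive$n_samples),
                   envir = new.env(parent = emptyenv()))
  .approx_from_models(arch, run$problem, run$models, level)$tbl
}

#' Continue an EGO run for further iterations
#'
#' Restarts the loop from the run's final state; because every stochastic
#' step consumes a numbered substream of the root seed, a run of
#' `a + b` iterations equals a run of `a` iterations resumed for `b`.
#'
#' @param run An `ego_run`.
#' @param iterations Additional iterations.
#' @return A new `ego_run`.
#' @export
resume_ego <- function(run, iterations) {
  stopifnot(inherits(run, "ego_run"), iterations >= 0)
  arch <- new.env(parent = emptyenv())
  arch$X <- run$archive$X
  arch$succ <- run$archive$successes
  arch$nsamp <- run$archive$n_samples
  arch$keys <- apply(run$archive$X, 1, paste, collapse = "|")
  arch$log <- run$log
  stream <- stream_restore(run$stream)
  .ego_iterate(arch, run$problem, run$sim, run$control, stream,
               from_iter = run$iterations_done + 1L,
               to_iter = run$iterations_done + iterations)
}

#' Fixed space-filling comparator
#'
#' Evaluates one Sobol batch of designs, computes for each constraint the
#' Monte Carlo confidence interval `estimate +/- z * omega`, discards any
#' design whose interval is not entirely below the nominal threshold, and
#' returns the nondominated subset of the survivors.
#'
#' @param problem An [ssd_problem()].
#' @param sim A [trial_simulator()].
#' @param n_points Number of designs to evaluate.
#' @param n_per_eval Monte Carlo samples per evaluation.
#' @param conf_level Two-sided confidence level for the interval (default
#'   95%).
#' @param seed Root seed.
#' @return A tibble like [extract_approximation_set()]'s (with upper
#'   confidence limits in place of quantiles), plus attribute `n_evaluated`.
#' @export
run_fixed_design <- function(problem, sim, n_points, n_per_eval = 100,
                             conf_level = 0.95, seed = 1) {
  stopifnot(n_points >= 1)
  stream <- rng_stream(seed)
  X <- sobol_design(problem$space, n_points, seed = stream)
  C <- length(problem$constraints)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- matrix(NA_real_, n_points, C)
  upper <- matrix(NA_real_, n_points, C)
  for (i in seq_len(n_points)) {
    for (j in seq_len(C)) {
      ct <- problem$constraints[[j]]
      e <- estimate_oc(sim, X[i, ], ct$hypothesis, n_per_eval, stream)
      oc <- .oc_successes(ct, e$successes, e$n_samples) / e$n_samples
      est[i, j] <- oc
      upper[i, j] <- oc + z * mc_standard_error(oc, e$n_samples)
    }
  }
  keep <- rowSums(sweep(upper, 2, problem$thresholds, "<=")) == C
  Y <- problem$objectives(X)
  sel <- which(keep)
  if (length(sel) > 0) sel <- sel[nondominated(Y[sel, , drop = FALSE])]
  cnames <- vapply(problem$constraints, `[[`, character(1), "name")
  out <- dplyr::bind_cols(
    tibble::as_tibble(as.data.frame(X[sel, , drop = FALSE])),
    tibble::as_tibble(as.data.frame(Y[sel, , drop = FALSE])),
    tibble::as_tibble(as.data.frame(stats::setNames(
      as.data.frame(est[sel, , drop = FALSE]), paste0("estimate_", cnames)))),
    tibble::as_tibble(as.data.frame(stats::setNames(
      as.data.frame(upper[sel, , drop = FALSE]), paste0("upper_", cnames))))
  )
  attr(out, "n_evaluated") <- n_points
  out
}

#' Surrogate fit diagnostics for an EGO run
#'
#' For each post-initial evaluation, the standardised prediction error
#' `(observed - predicted mean) / sqrt(predicted var + MC error var)` of the
#' surrogate that proposed the point. Values beyond +/- 3 flag a poorly
#' calibrated surrogate.
#'
#' @param run An `ego_run`.
#' @return A tibble with one row per (iteration, constraint): observed,
#'   predicted moments, standardised error `z`, and `flag`.
#' @export
ego_diagnostics <- function(run) {
  stopifnot(inherits(run, "ego_run"))
  log <- run$log
  log <- log[log$iteration > 0 & !is.na(log$pred_mean), , drop = FALSE]
  if (nrow(log) == 0)
    return(tibble::tibble(iteration = integer(0), constraint = character(0),
                          observed = numeric(0), pred_mean = numeric(0),
                          pred_sd = numeric(0), std_error = numeric(0),
                          z = numeric(0), flag = logical(0)))
  z <- (log$estimate - log$pred_mean) / sqrt(log$pred_sd^2 + log$std_error^2)
  tibble::tibble(iteration = log$iteration, constraint = log$constraint,
                 observed = log$estimate, pred_mean = log$pred_mean,
                 pred_sd = log$pred_sd, std_error = log$std_error,
                 z = z, flag = abs(z) > 3)
}

#' @export
print.ego_run <- function(x, ...) {
  C <- length(x$problem$constraints)
  cat("<ego_run> ", x$problem$name, ": ", nrow(x$archive$X),
      " designs evaluated (", x$iterations_done, " iterations + initial design)\n",
      sep = "")
  cat("  simulator draws: ", sum(x$archive$n_samples),
      "; approximation set size: ", nrow(x$approx), "\n", sep = "")
  hv <- dominated_hypervolume(
    as.matrix(x$approx[, colnames(x$problem$objectives(x$archive$X[1, , drop = FALSE])),
                       drop = FALSE]),
    x$problem$ref_point)
  cat("  dominated hypervolume: ", signif(hv, 6), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.ego_run <- function(x, ...) x$approx

#' @export
glance.ego_run <- function(x, ...) {
  objnames <- colnames(x$problem$objectives(x$archive$X[1, , drop = FALSE]))
  hv <- dominated_hypervolume(as.matrix(x$approx[, objnames, drop = FALSE]),
                              x$problem$ref_point)
  tibble::tibble(
    n_designs = nrow(x$archive$X),
    n_draws = sum(x$archive$n_samples),
    iterations = x$iterations_done,
    set_size = nrow(x$approx),
    hypervolume = hv
  )
}
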