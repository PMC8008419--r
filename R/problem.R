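#' Specify an operating-characteristic constraint
#'
#' A constraint requires an operating characteristic (a probability estimated
#' by simulation under one hypothesis) to be at most a nominal threshold:
#' `g(x) = OC(x) - threshold <= 0`. The surrogate models the operating
#' characteristic itself; the threshold is subtracted when feasibility is
#' judged.
#'
#' @param name Constraint label (used in logs and column names).
#' @param hypothesis Hypothesis label passed to the trial simulator.
#' @param threshold Nominal upper bound on the operating characteristic.
#' @param event Which event's probability is the operating characteristic:
#'   `"reject"` (e.g. type I error under a null hypothesis) or `"accept"`
#'   (e.g. type II error under an alternative).
#' @return A list of class `oc_constraint`.
#' @examples
#' oc_constraint("type2", "alternative", 0.1, event = "accept")
#' @export
oc_constraint <- function(name, hypothesis, threshold,
                          event = c("reject", "accept")) {
  event <- match.arg(event)
  stopifnot(threshold > 0, threshold < 1)
  structure(list(name = name, hypothesis = hypothesis,
                 threshold = threshold, event = event),
            class = "oc_constraint")
}

#' Bundle a sample size determination problem
#'
#' A problem couples the design box, cheap deterministic objective functions
#' (all minimised), and simulation-estimated operating-characteristic
#' constraints.
#'
#' @param space A [solution_space()].
#' @param objectives Function mapping a design matrix (rows = designs, named
#'   columns) to a matrix of objective values with named columns.
#' @param constraints List of [oc_constraint()]s (at least one).
#' @param ref_point Reference point for hypervolume scoring; default: the
#'   per-objective maximum over the box corners times 1.1.
#' @param name Problem label.
#' @return An object of class `ssd_problem`.
#' @export
ssd_problem <- function(space, objectives, constraints, ref_point = NULL,
                        name = "problem") {
  stopifnot(inherits(space, "solution_space"), is.function(objectives),
            length(constraints) >= 1)
  for (ct in constraints) stopifnot(inherits(ct, "oc_constraint"))
  obj_wrapped <- function(X) {
    Y <- objectives(as_design_matrix(space, X))
    Y <- as.matrix(Y)
    if (is.null(colnames(Y))) colnames(Y) <- paste0("f", seq_len(ncol(Y)))
    Y
  }
  prob <- structure(
    list(space = space, objectives = obj_wrapped, constraints = constraints,
         thresholds = vapply(constraints, `[[`, numeric(1), "threshold"),
         ref_point = ref_point, name = name),
    class = "ssd_problem"
  )
  if (is.null(ref_point)) prob$ref_point <- default_reference_point(prob)
  n_obj <- ncol(prob$objectives(matrix(space$lower, 1,
                                       dimnames = list(NULL, space$names))))
  if (length(prob$ref_point) != n_obj)
    stop("reference point has length ", length(prob$ref_point),
         "; problem has ", n_obj, " objectives")
  prob$n_objectives <- n_obj
  prob
}

#' @export
print.ssd_problem <- function(x, ...) {
  cat("<ssd_problem> ", x$name, "\n", sep = "")
  print(x$space)
  cat("  objectives: ", x$n_objectives,
      "; reference point: (", paste(signif(x$ref_point, 4), collapse = ", "),
      ")\n", sep = "")
  for (ct in x$constraints)
    cat(sprintf("  constraint %s: P(%s | %s) <= %g\n", ct$name, ct$event,
                ct$hypothesis, ct$threshold))
  invisible(x)
}

# operating-characteristic success count from a reject-indicator estimate
.oc_successes <- function(constraint, successes, n) {
  if (constraint$event == "reject") successes else n - successes
}
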