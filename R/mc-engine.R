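#' Wrap a user trial simulation routine as a trial simulator
#'
#' A trial simulator encapsulates the data-generating process and analysis of
#' one simulated trial: given a design point and a hypothesis label it returns
#' a binary indicator of whether the null hypothesis was rejected. All
#' operating characteristics (power, type I error) are Monte Carlo averages of
#' this indicator.
#'
#' @param simulate_once `function(design, hypothesis)` returning exactly 0 or
#'   1 for a single simulated trial. `design` is a named numeric vector. The
#'   function may use the R random number generator freely; seeding is handled
#'   by the caller.
#' @param hypotheses Character vector of valid hypothesis labels.
#' @param simulate_batch Optional `function(design, hypothesis, n)` returning
#'   a length-`n` 0/1 vector; used when available to vectorise replicates.
#'   Must be distributionally identical to `n` calls of `simulate_once`.
#' @param name Label used in logs.
#' @return An object of class `trial_simulator`.
#' @export
trial_simulator <- function(simulate_once,
                            hypotheses = c("null", "alternative"),
                            simulate_batch = NULL,
                            name = "simulator") {
  stopifnot(is.function(simulate_once), is.character(hypotheses))
  structure(
    list(simulate_once = simulate_once, hypotheses = hypotheses,
         simulate_batch = simulate_batch, name = name),
    class = "trial_simulator"
  )
}

#' @export
print.trial_simulator <- function(x, ...) {
  cat("<trial_simulator> ", x$name, " | hypotheses: ",
      paste(x$hypotheses, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Standard error of a Monte Carlo probability estimate
#'
#' For an estimated probability `p_hat` based on `n_samples` binary
#' replicates, the sampling standard deviation is `sqrt(p(1-p)/N)`. The
#' estimate is clipped to `[0.5/N, 1 - 0.5/N]` before plugging in, so a run
#' with 0 or N successes still yields a strictly positive error: a zero
#' Monte Carlo standard error is an artefact of finite N, not certainty, and
#' the surrogate model requires strictly positive noise variances.
#'
#' @param p_hat Estimated probability (vectorised).
#' @param n_samples Number of Monte Carlo replicates.
#' @return Strictly positive standard error(s).
#' @examples
#' mc_standard_error(0.5, 100)  # 0.05
#' @export
mc_standard_error <- function(p_hat, n_samples) {
  stopifnot(all(n_samples >= 1), all(p_hat >= 0 & p_hat <= 1))
  p <- pmin(pmax(p_hat, 0.5 / n_samples), 1 - 0.5 / n_samples)
  sqrt(p * (1 - p) / n_samples)
}

#' Monte Carlo estimate of an operating characteristic
#'
#' Runs the simulator `n_samples` times under the given hypothesis and
#' returns the rejection proportion with its normal-approximation error
#' model: estimate = true probability + e, e ~ N(0, omega^2).
#'
#' @param sim A [trial_simulator()].
#' @param design Named numeric vector (or 1-row data frame) of design
#'   parameters.
#' @param hypothesis One of `sim$hypotheses`.
#' @param n_samples Number of replicates (>= 1).
#' @param stream An [rng_stream()] (one substream is consumed), or an integer
#'   seed.
#' @return A one-row tibble of class `mc_estimate` with columns `estimate`,
#'   `n_samples`, `successes`, `std_error`.
#' @export
estimate_oc <- function(sim, design, hypothesis, n_samples, stream) {
  stopifnot(inherits(sim, "trial_simulator"), n_samples >= 1)
  if (!hypothesis %in% sim$hypotheses)
    stop("unknown hypothesis '", hypothesis, "'; simulator supports: ",
         paste(sim$hypotheses, collapse = ", "))
  if (is.data.frame(design)) design <- unlist(design[1, , drop = TRUE])
  seed <- if (inherits(stream, "rng_stream")) stream_next_seed(stream) else as.integer(stream)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (!is.null(sim$simulate_batch)) {
    ind <- sim$simulate_batch(design, hypothesis, n_samples)
    bad <- which(!(ind %in% c(0, 1)))
    if (length(bad) > 0)
      stop("simulator '", sim$name, "' returned non-binary value ", ind[bad[1]],
           " at replicate ", bad[1], " for design (",
           paste(names(design), design, sep = "=", collapse = ", "), ")")
  } else {
    ind <- vapply(seq_len(n_samples), function(i) {
      v <- sim$simulate_once(design, hypothesis)
      if (length(v) != 1 || !(v %in% c(0, 1)))
        stop("simulator '", sim$name, "' returned non-binary value at replicate ",
             i, " for design (",
             paste(names(design), design, sep = "=", collapse = ", "), ")")
      as.numeric(v)
    }, numeric(1))
  }
  successes <- sum(ind)
  est <- successes / n_samples
  out <- tibble::tibble(estimate = est, n_samples = as.integer(n_samples),
                        successes = as.integer(successes),
                        std_error = mc_standard_error(est, n_samples))
  class(out) <- c("mc_estimate", class(out))
  out
}
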