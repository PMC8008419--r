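# Reduced-scale benchmark of EGO against the fixed space-filling design on
# the analytic cluster trial, where closed-form power supplies ground truth
# for validity and the exhaustive Pareto set bounds the hypervolume.

#' Benchmark EGO against fixed designs on the analytic cluster problem
#'
#' Repeats the EGO run and fixed designs of the requested sizes under
#' independent seeds; for every resulting approximation set records the
#' dominated hypervolume (common reference point), the set size, and the
#' proportion of its designs whose true analytic type II error is within
#' the nominal bound. Only the cluster problem is accepted: the benchmark
#' needs the truth oracle.
#'
#' @param params A [cluster_params()].
#' @param n_repeats Number of repetitions per method.
#' @param fixed_sizes Sizes of the fixed comparator designs.
#' @param control An [ego_control()]; its seed anchors the whole benchmark.
#' @param conf_level Confidence level of the fixed-design screening
#'   interval.
#' @return A tibble with one row per (method, repeat): `method`,
#'   `n_evaluations`, `rep`, `hypervolume`, `set_size`, `valid_prop`.
#'   Attribute `true_hypervolume` holds the exhaustive Pareto set's value.
#' @export
run_benchmark <- function(params = cluster_params(), n_repeats = 20,
                          fixed_sizes = c(50), control = ego_control(),
                          conf_level = 0.95) {
  stopifnot(inherits(params, "cluster_params"))
  problem <- cluster_problem(params)
  sim <- cluster_simulator(params)
  truth <- cluster_true_pareto(params)
  hv_true <- dominated_hypervolume(as.matrix(truth[, c("total_n", "total_k")]),
                                   problem$ref_point)
  score <- function(tbl) {
    if (nrow(tbl) == 0)
      return(tibble::tibble(hypervolume = 0, set_size = 0L,
                            valid_prop = NA_real_))
    hv <- dominated_hypervolume(as.matrix(tbl[, c("total_n", "total_k")]),
                                problem$ref_point)
    beta_true <- 1 - cluster_power_analytic(tbl$k, tbl$n, params)
    tibble::tibble(hypervolume = hv, set_size = nrow(tbl),
                   valid_prop = mean(beta_true <= params$nominal_type2))
  }
  rows <- list()
  E <- .default_init_size(problem$space, control)
  for (rep in seq_len(n_repeats)) {
    ctl <- control
    ctl$seed <- substream_seed(control$seed, 1000 + rep)
    run <- run_ego(problem, sim, ctl)
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble::tibble(method = "ego",
                     n_evaluations = E + control$iterations, rep = rep),
      score(run$approx))
    for (sz in fixed_sizes) {
      fx <- run_fixed_design(problem, sim, sz, control$n_per_eval, conf_level,
                             seed = substream_seed(control$seed, 2000 + rep * 100 + sz %% 97))
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(method = "fixed", n_evaluations = sz, rep = rep),
        score(fx))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "true_hypervolume") <- hv_true
  out
}

#' Summarise a benchmark by method
#'
#' @param bench Output of [run_benchmark()].
#' @return A tibble per (method, n_evaluations): median and mean
#'   hypervolume, mean set size, mean validity proportion.
#' @export
summarize_benchmark <- function(bench) {
  dplyr::summarise(
    dplyr::group_by(bench, .data$method, .data$n_evaluations),
    median_hypervolume = stats::median(.data$hypervolume),
    mean_hypervolume = mean(.data$hypervolume),
    mean_set_size = mean(.data$set_size),
    mean_valid_prop = mean(.data$valid_prop, na.rm = TRUE),
    n_repeats = dplyr::n(),
    .groups = "drop")
}
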