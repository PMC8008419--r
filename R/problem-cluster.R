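# Built-in problem 1: a two-arm cluster randomised trial with a continuous
# outcome, analysed by a one-sided two-sample t-test on cluster means. Its
# power has a closed form, so it doubles as a truth oracle for the
# optimisation machinery.

#' Parameters of the cluster randomised trial example
#'
#' Outcome model `y_ij = b0 + b1 t_i + u_j + e_i` with cluster effects
#' `u_j ~ N(0, between_var)` and residuals `e_i ~ N(0, within_var)`. With the
#' default variances the total variance is 1, so `effect` is a standardised
#' difference in means. The test is one-sided at level `alpha`.
#'
#' @param within_var Within-cluster residual variance.
#' @param between_var Between-cluster variance.
#' @param effect Difference in means under the alternative (the minimal
#'   clinically important difference).
#' @param alpha One-sided test level.
#' @param nominal_type2 Nominal type II error bound used as the constraint
#'   threshold.
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(within_var = 0.95, between_var = 0.05,
                           effect = 0.3, alpha = 0.025, nominal_type2 = 0.1) {
  stopifnot(within_var > 0, between_var > 0, alpha > 0, alpha < 0.5)
  structure(list(within_var = within_var, between_var = between_var,
                 effect = effect, alpha = alpha,
                 nominal_type2 = nominal_type2),
            class = "cluster_params")
}

#' Closed-form power of the cluster trial
#'
#' The per-arm cluster means have variance `between_var + within_var / m`
#' with `m = n / k` (real-valued), so the one-sided two-sample t-test on `k`
#' cluster means per arm has power
#' `P(T > t_{1-alpha, 2k-2})` for `T` noncentral t with `2k - 2` degrees of
#' freedom and noncentrality `effect / sqrt(2 (between_var + within_var/m) / k)`.
#'
#' @param k Clusters per arm (vectorised).
#' @param n Participants per arm (vectorised).
#' @param params A [cluster_params()].
#' @return Power value(s).
#' @export
cluster_power_analytic <- function(k, n, params = cluster_params()) {
  if (any(k < 2)) stop("need at least 2 clusters per arm")
  m <- n / k
  var_mean <- params$between_var + params$within_var / m
  ncp <- params$effect / sqrt(2 * var_mean / k)
  df <- 2 * k - 2
  crit <- stats::qt(1 - params$alpha, df)
  stats::pt(crit, df, ncp = ncp, lower.tail = FALSE)
}

# one simulated trial: cluster effects + residuals -> cluster means -> t-test.
# sizes are balanced as far as possible when k does not divide n.
.cluster_sim_batch <- function(design, params, hypothesis, n_rep) {
  k <- design[["k"]]; n <- design[["n"]]
  delta <- if (hypothesis == "alternative") params$effect else 0
  sizes <- rep(floor(n / k), k) + (seq_len(k) <= n %% k)
  # cluster mean = arm mean + u_j + mean of size_j residuals
  sd_mean <- sqrt(params$between_var + params$within_var / sizes)
  draw_arm <- function(mu) {
    matrix(stats::rnorm(n_rep * k, mean = mu,
                        sd = rep(sd_mean, each = n_rep)), n_rep, k)
  }
  y1 <- draw_arm(delta); y0 <- draw_arm(0)
  m1 <- rowMeans(y1); m0 <- rowMeans(y0)
  v1 <- apply(y1, 1, stats::var); v0 <- apply(y0, 1, stats::var)
  sp2 <- (v1 + v0) / 2
  tstat <- (m1 - m0) / sqrt(2 * sp2 / k)
  as.numeric(tstat > stats::qt(1 - params$alpha, 2 * k - 2))
}

#' Trial simulator for the cluster randomised trial
#'
#' Draws cluster effects and residuals, forms cluster means, and applies the
#' one-sided two-sample t-test at the configured level; returns the reject
#' indicator. Hypotheses: `"null"` (no effect) and `"alternative"` (the
#' configured effect).
#'
#' @param params A [cluster_params()].
#' @return A [trial_simulator()] over designs `(k, n)`.
#' @export
cluster_simulator <- function(params = cluster_params()) {
  trial_simulator(
    simulate_once = function(design, hypothesis)
      .cluster_sim_batch(design, params, hypothesis, 1),
    simulate_batch = function(design, hypothesis, n)
      .cluster_sim_batch(design, params, hypothesis, n),
    hypotheses = c("null", "alternative"),
    name = "cluster_rct"
  )
}

#' The cluster randomised trial design problem
#'
#' Minimise the total number of participants `2n` and the total number of
#' clusters `2k` over integer `k` and `n`, subject to the Monte Carlo
#' estimated type II error rate at the configured effect being at most the
#' nominal level.
#'
#' @param params A [cluster_params()].
#' @param k_range,n_range Integer search ranges for clusters and per-arm
#'   sample size.
#' @param ref_point Optional hypervolume reference point.
#' @return An [ssd_problem()].
#' @export
cluster_problem <- function(params = cluster_params(),
                            k_range = c(10, 100), n_range = c(100, 500),
                            ref_point = NULL) {
  space <- solution_space(c("k", "n"),
                          lower = c(k_range[1], n_range[1]),
                          upper = c(k_range[2], n_range[2]),
                          integer = c(TRUE, TRUE))
  objectives <- function(X)
    cbind(total_n = 2 * X[, "n"], total_k = 2 * X[, "k"])
  ssd_problem(space, objectives,
              constraints = list(oc_constraint("type2", "alternative",
                                               params$nominal_type2,
                                               event = "accept")),
              ref_point = ref_point, name = "cluster_rct")
}

#' True Pareto set of the cluster trial by exhaustive search
#'
#' Scans every integer `(k, n)` in the box, keeps designs whose analytic
#' type II error is at most the nominal bound, and returns the nondominated
#' subset under objectives `(2n, 2k)`. Serves as the optimality oracle for
#' the stochastic methods: no feasible approximation set can dominate more
#' hypervolume.
#'
#' @param params A [cluster_params()].
#' @param k_range,n_range Integer search ranges.
#' @return A tibble with columns `k`, `n`, `total_n`, `total_k`, `power`.
#' @export
cluster_true_pareto <- function(params = cluster_params(),
                                k_range = c(10, 100), n_range = c(100, 500)) {
  grid <- expand.grid(k = seq(k_range[1], k_range[2]),
                      n = seq(n_range[1], n_range[2]))
  grid <- grid[grid$n >= grid$k, , drop = FALSE]
  pow <- cluster_power_analytic(grid$k, grid$n, params)
  feas <- grid[pow >= 1 - params$nominal_type2, , drop = FALSE]
  powf <- pow[pow >= 1 - params$nominal_type2]
  Y <- cbind(total_n = 2 * feas$n, total_k = 2 * feas$k)
  keep <- nondominated(Y)
  out <- tibble::tibble(k = feas$k[keep], n = feas$n[keep],
                        total_n = Y[keep, 1], total_k = Y[keep, 2],
                        power = powf[keep])
  stopifnot(all(out$power >= 1 - params$nominal_type2))
  out[order(out$total_n), ]
}
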