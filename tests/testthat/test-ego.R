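small_problem <- function(p_fun = function(d, h) 0.05) {
  space <- solution_space(c("k", "n"), c(10, 100), c(100, 500), c(TRUE, TRUE))
  prob <- ssd_problem(space,
                      function(X) cbind(total_n = 2 * X[, "n"], total_k = 2 * X[, "k"]),
                      list(oc_constraint("type2", "alternative", 0.1, "accept")),
                      name = "toy")
  sim <- bernoulli_simulator(function(d, h) 1 - p_fun(d, h))  # accept prob p_fun
  list(prob = prob, sim = sim)
}

fast_ctl <- function(...) {
  ego_control(pso = pso_control(swarm = 12, iterations = 25),
              gp = gp_control(n_starts = 4, maxit = 25), ...)
}

test_that("the loop consumes exactly (E + iterations) * N * C simulator draws", {
  tp <- small_problem()
  calls <- new.env(); calls$n <- 0
  counting <- trial_simulator(
    simulate_once = function(d, h) { calls$n <- calls$n + 1; rbinom(1, 1, 0.95) },
    hypotheses = c("null", "alternative"))
  run <- run_ego(tp$prob, counting,
                 fast_ctl(iterations = 3, init_size = 6, n_per_eval = 20, seed = 2))
  expect_equal(calls$n, (6 + 3) * 20 * 1)
  expect_equal(sum(run$archive$n_samples), (6 + 3) * 20)
})

test_that("zero iterations build the approximation set from the initial design", {
  tp <- small_problem()
  run <- run_ego(tp$prob, tp$sim,
                 fast_ctl(iterations = 0, init_size = 8, n_per_eval = 40, seed = 3))
  expect_equal(nrow(run$archive$X), 8)
  expect_true(all(run$log$iteration == 0))
  expect_gt(nrow(run$approx), 0)  # everything is feasible for this simulator
})

test_that("a resumed run reproduces an uninterrupted run exactly", {
  tp <- small_problem(function(d, h) 0.06 + 0.0001 * (500 - d[["n"]]))
  ctl <- fast_ctl(iterations = 4, init_size = 6, n_per_eval = 30, seed = 11)
  full <- run_ego(tp$prob, tp$sim, ctl)
  part <- run_ego(tp$prob, tp$sim, fast_ctl(iterations = 2, init_size = 6,
                                            n_per_eval = 30, seed = 11))
  resumed <- resume_ego(part, 2)
  drop_t <- function(x) x[, setdiff(names(x), "elapsed")]
  expect_equal(drop_t(full$log), drop_t(resumed$log))
  expect_equal(full$approx, resumed$approx)
})

test_that("duplicate proposals pool replicates instead of forking designs", {
  tp <- small_problem()
  # a two-point integer lattice: every proposal rounds onto an existing design
  space <- solution_space(c("k", "n"), c(10, 100), c(11.4, 100.4), c(TRUE, TRUE))
  prob <- ssd_problem(space,
                      function(X) cbind(f1 = X[, "n"], f2 = X[, "k"]),
                      list(oc_constraint("type2", "alternative", 0.1, "accept")),
                      name = "point")
  run <- run_ego(prob, tp$sim,
                 fast_ctl(iterations = 3, init_size = 2, n_per_eval = 25, seed = 5))
  expect_equal(nrow(run$archive$X), 2)
  expect_equal(sum(run$archive$n_samples), 5 * 25)  # budget conserved
  expect_true(any(run$log$pooled))
  # pooled noise shrinks relative to a single evaluation
  i <- which.max(run$archive$n_samples)
  pooled_se <- mc_standard_error(
    run$archive$successes[i] / run$archive$n_samples[i],
    run$archive$n_samples[i])
  expect_lt(pooled_se,
            mc_standard_error(run$archive$successes[i] / run$archive$n_samples[i], 25))
})

test_that("feasibility is recomputed under current surrogates when extracting", {
  tp <- small_problem(function(d, h) 0.5)  # far infeasible everywhere
  run <- run_ego(tp$prob, tp$sim,
                 fast_ctl(iterations = 2, init_size = 6, n_per_eval = 60, seed = 7))
  expect_equal(nrow(run$approx), 0)
  expect_equal(nrow(extract_approximation_set(run)), 0)
  # a single feasible design yields a singleton set
  tp2 <- small_problem(function(d, h)
    if (d[["n"]] >= 490 && d[["k"]] >= 95) 0.01 else 0.6)
  run2 <- run_ego(tp2$prob, tp2$sim,
                  fast_ctl(iterations = 6, init_size = 10, n_per_eval = 80, seed = 8))
  appr <- extract_approximation_set(run2)
  if (nrow(appr) > 0) expect_true(all(appr$n >= 450))
  # a stricter quantile level never grows the feasible pool
  expect_lte(nrow(extract_approximation_set(run2, level = 0.99)),
             nrow(extract_approximation_set(run2, level = 0.6)))
})

test_that("fixed-design screening applies the confidence-interval rule", {
  # deterministic interval arithmetic first
  expect_true(0.04 + 1.96 * 0.019 < 0.1)   # retained
  tp <- small_problem(function(d, h) 0.04)
  fx <- run_fixed_design(tp$prob, tp$sim, n_points = 30, n_per_eval = 100,
                         seed = 9)
  expect_gt(nrow(fx), 0)
  expect_true(all(fx$upper_type2 <= 0.1))
  expect_equal(attr(fx, "n_evaluated"), 30)
  # estimates above the nominal value are always discarded
  tp_bad <- small_problem(function(d, h) 0.35)
  fx_bad <- run_fixed_design(tp_bad$prob, tp_bad$sim, n_points = 20,
                             n_per_eval = 100, seed = 10)
  expect_equal(nrow(fx_bad), 0)
  # survivors are mutually nondominated
  Y <- as.matrix(fx[, c("total_n", "total_k")])
  expect_true(all(ssdopt:::nondominated(Y)))
})

test_that("diagnostics are calibrated for a well-specified surrogate and flag a broken one", {
  tp <- small_problem(function(d, h) 0.05 + 0.0002 * (d[["n"]] - 100) / 4)
  run <- run_ego(tp$prob, tp$sim,
                 fast_ctl(iterations = 5, init_size = 8, n_per_eval = 50, seed = 13))
  d <- ego_diagnostics(run)
  expect_equal(nrow(d), 5)
  expect_true(all(is.finite(d$z)))
  expect_true(all(abs(d$z) < 6))
  # mis-scaled surrogate: shrink predictive sd a hundredfold
  broken <- run
  broken$log$pred_sd <- broken$log$pred_sd / 100
  broken$log$std_error <- broken$log$std_error / 100
  db <- ego_diagnostics(broken)
  expect_true(any(db$flag))
  # no post-initial evaluations -> empty report
  r0 <- run_ego(tp$prob, tp$sim,
                fast_ctl(iterations = 0, init_size = 4, n_per_eval = 30, seed = 1))
  expect_equal(nrow(ego_diagnostics(r0)), 0)
})

test_that("the hindsight hypervolume trajectory is nondecreasing under the final surrogates", {
  tp <- small_problem(function(d, h) 0.04 + 0.0001 * (d[["n"]] - 100))
  run <- run_ego(tp$prob, tp$sim,
                 fast_ctl(iterations = 5, init_size = 8, n_per_eval = 60, seed = 21))
  X <- run$archive$X
  Y <- tp$prob$objectives(X)
  q <- vapply(seq_len(nrow(X)), function(i) {
    pr <- predict(run$models[[1]], X[i, , drop = FALSE])
    feasibility_quantile(pr$mean - tp$prob$thresholds[1], pr$sd,
                         run$control$quantile_level)
  }, numeric(1))
  hv_prefix <- vapply(seq_len(nrow(X)), function(m) {
    sel <- which(q[seq_len(m)] <= 0)
    if (length(sel) == 0) return(0)
    dominated_hypervolume(Y[sel, , drop = FALSE], tp$prob$ref_point)
  }, numeric(1))
  expect_true(all(diff(hv_prefix) >= -1e-9))
})

test_that("run summaries expose budget, set size and hypervolume", {
  tp <- small_problem()
  run <- run_ego(tp$prob, tp$sim,
                 fast_ctl(iterations = 2, init_size = 5, n_per_eval = 30, seed = 4))
  g <- glance(run)
  expect_equal(g$n_draws, 7 * 30)
  expect_equal(g$set_size, nrow(tidy(run)))
  expect_gte(g$hypervolume, 0)
  p <- autoplot(run)
  expect_s3_class(p, "ggplot")
})
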