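test_that("feasibility quantile follows the normal-quantile rule", {
  expect_equal(feasibility_quantile(-0.3, 0, 0.9), -0.3)      # no uncertainty
  expect_equal(feasibility_quantile(-0.3, 0.1, 0.5000001), -0.3, tolerance = 1e-5)
  q <- feasibility_quantile(-0.02, 0.01, 0.9)
  expect_equal(q, -0.02 + qnorm(0.9) * 0.01)
  expect_equal(q, -0.00718, tolerance = 1e-3)
  expect_lt(q, 0)  # deemed feasible
  # nondecreasing in the level
  ps <- seq(0.51, 0.99, by = 0.02)
  expect_true(all(diff(feasibility_quantile(-0.02, 0.01, ps)) >= 0))
})

test_that("quantile update has the correct perfect- and null-information limits", {
  m <- -0.02; s <- 0.01; p <- 0.9
  # omega = 0: next quantile is the current constraint distribution
  qu <- quantile_update(m, s, 0, p)
  expect_equal(qu$mean_plus, m, tolerance = 1e-10)
  expect_equal(qu$sd_plus, s, tolerance = 1e-10)
  # omega -> Inf: quantile cannot move
  for (w in c(Inf, 1e8)) {
    qu <- quantile_update(m, s, w, p)
    expect_equal(qu$mean_plus, feasibility_quantile(m, s, p), tolerance = 1e-10)
    expect_equal(qu$sd_plus, 0, tolerance = 1e-10)
  }
  # equal information: shrinkage by sqrt(2)
  qu <- quantile_update(m, s, s, p)
  expect_equal(qu$mean_plus, m + qnorm(p) * s / sqrt(2), tolerance = 1e-10)
  expect_equal(qu$sd_plus^2, s^2 / 2, tolerance = 1e-10)
  # both degenerate
  qu <- quantile_update(m, 0, 0, p)
  expect_equal(qu$mean_plus, m)
  expect_equal(qu$sd_plus, 0)
})

test_that("feasibility probability handles the degenerate cases", {
  expect_equal(prob_deemed_feasible(0, 1), 0.5)
  expect_equal(prob_deemed_feasible(-1.96, 1), pnorm(1.96))
  expect_equal(prob_deemed_feasible(-0.01, 0), 1)
  expect_equal(prob_deemed_feasible(0.01, 0), 0)
})

test_that("more planned samples help confirm a feasible-mean design not yet deemed feasible", {
  # mean on the feasible side but current quantile above zero: information
  # can only move the quantile towards the mean, so the confirmation
  # probability rises with the planned sample size towards pnorm(-m/s)
  m <- -0.02; s <- 0.02; p <- 0.9
  stopifnot(feasibility_quantile(m, s, p) > 0)
  ns <- c(10, 50, 100, 1000, 1e5, 1e8)
  pf <- vapply(ns, function(n) {
    omega <- sqrt(0.08 * 0.92 / n)
    qu <- quantile_update(m, s, omega, p)
    prob_deemed_feasible(qu$mean_plus, qu$sd_plus)
  }, numeric(1))
  expect_true(all(diff(pf) >= -1e-12))
  expect_equal(pf[length(pf)], pnorm(-m / s), tolerance = 0.01)
  # exact limit with a perfect planned evaluation
  qu <- quantile_update(m, s, 0, p)
  expect_equal(prob_deemed_feasible(qu$mean_plus, qu$sd_plus), pnorm(-m / s),
               tolerance = 1e-12)
})

# hand-set toy: two designs in the current set, one constraint GP replaced
# by fixed predictive moments through a stub model object
stub_model <- function(mean, sd, space) {
  structure(list(mean = mean, sd = sd, space = space), class = "stub_model")
}

test_that("expected improvement composes hypervolume gain and feasibility", {
  space <- unit_space_2d()
  objectives <- function(X) cbind(f1 = X[, 1], f2 = X[, 2])
  current_Y <- rbind(c(0.5, 0.5))
  ref <- c(1, 1)
  # certain feasibility: EI equals the raw hypervolume improvement
  m <- fit_gp(rbind(c(0.1, 0.1), c(0.9, 0.9)), c(-1, -1) + 0.95,
              rep(1e-10, 2), space = space)  # OC ~ -0.05 relative to 0 threshold
  X <- rbind(c(0.2, 0.2), c(0.6, 0.6))
  res <- expected_improvement(X, list(m), thresholds = 0.5, current_Y, ref,
                              objectives, level = 0.9, planned_n = 1e6)
  expect_equal(res$ei[1], res$hvi[1], tolerance = 1e-4)
  expect_equal(res$ei[2], 0)  # dominated candidate: zero gain regardless
  expect_true(all(res$ei >= 0))
})

test_that("expected improvement matches a large-sample Monte Carlo oracle", {
  # one constraint with hand-set predictive moments; candidate adds a known
  # rectangle; the oracle simulates the post-evaluation quantile directly
  m0 <- 0.08; s0 <- 0.03; thr <- 0.1; p <- 0.9; N <- 100
  current_Y <- rbind(c(0.6, 0.6))
  ref <- c(1, 1)
  cand <- c(0.4, 0.4)
  hvi <- hypervolume_improvement(current_Y, cand, ref)
  m_clip <- min(max(m0, 0.001), 0.999)
  omega <- sqrt(m_clip * (1 - m_clip) / N)
  qu <- quantile_update(m0 - thr, s0, omega, p)
  ei <- hvi * prob_deemed_feasible(qu$mean_plus, qu$sd_plus)
  set.seed(202)
  draws <- rnorm(1e6, qu$mean_plus, qu$sd_plus)
  feas <- draws <= 0
  ei_mc <- hvi * mean(feas)
  se_mc <- hvi * sqrt(mean(feas) * (1 - mean(feas)) / 1e6)
  expect_lt(abs(ei - ei_mc), 3 * se_mc)
})

test_that("EI at a precisely known infeasible design is essentially zero", {
  space <- unit_space_2d()
  objectives <- function(X) cbind(f1 = X[, 1], f2 = X[, 2])
  # constraint surface pinned far above threshold with tiny uncertainty
  X <- as.matrix(expand.grid(x1 = c(0.1, 0.5, 0.9), x2 = c(0.1, 0.5, 0.9)))
  m <- fit_gp(X, rep(0.5, 9), rep(1e-12, 9), space = space)
  res <- expected_improvement(rbind(c(0.3, 0.3)), list(m), thresholds = 0.1,
                              current_Y = rbind(c(0.8, 0.8)), ref = c(1, 1),
                              objectives = objectives, planned_n = 100)
  expect_lt(res$ei[1], 1e-10)
})

test_that("the particle swarm finds a smooth one-dimensional optimum", {
  fn <- function(X) -(X[, 1] - 0.37)^2
  got <- ssdopt:::pso_maximize(fn, 0, 1, pso_control(swarm = 20, iterations = 80),
                               seed = 3)
  grid <- matrix(seq(0, 1, length.out = 2001), ncol = 1)
  best_grid <- grid[which.max(fn(grid)), 1]
  expect_lt(abs(got$par - best_grid), 1e-2)
  again <- ssdopt:::pso_maximize(fn, 0, 1, pso_control(swarm = 20, iterations = 80),
                                 seed = 3)
  expect_identical(got, again)
})

test_that("maximize_ei is deterministic and falls back on flat surfaces", {
  params <- cluster_params()
  prob <- cluster_problem(params)
  space <- prob$space
  X <- sobol_design(space, 12, seed = 5)
  y <- 1 - cluster_power_analytic(X[, "k"], X[, "n"], params)
  mod <- fit_gp(X, y, rep(1e-4, 12), space = space)
  ctl <- pso_control(swarm = 15, iterations = 30)
  a <- maximize_ei(prob, list(mod), current_Y = matrix(numeric(0), 0, 2),
                   control = ctl, stream = 4)
  b <- maximize_ei(prob, list(mod), current_Y = matrix(numeric(0), 0, 2),
                   control = ctl, stream = 4)
  expect_identical(a, b)
  expect_gt(a$ei, 0)
  # an everywhere-dominated objective space: EI is 0, fallback explores
  dominated_Y <- rbind(c(0, 0))  # dominates the whole box
  f <- maximize_ei(prob, list(mod), current_Y = dominated_Y, control = ctl,
                   stream = 4)
  expect_true(f$fallback)
  expect_equal(f$ei, 0)
})
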