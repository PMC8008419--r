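des <- c(n1 = 60, k = 4, r = 1.2, j = 6, a = 0.1)

test_that("simulated datasets realise the allocation structure", {
  set.seed(1)
  d <- simulate_multilevel_trial(des, hypothesis = "alternative")
  expect_equal(sum(d$arm == 1), 60)
  expect_equal(sum(d$arm == 0), 72)  # round(1.2 * 60)
  expect_true(all(is.na(d$therapist[d$arm == 0])))
  # round-robin: cluster sizes as balanced as possible
  expect_lte(diff(range(table(d$therapist[d$arm == 1]))), 1)
  expect_lte(diff(range(table(d$doctor))), 1)
  expect_equal(sort(unique(d$doctor)), 1:6)
  # half-up rounding of the control arm
  d2 <- simulate_multilevel_trial(c(n1 = 61, k = 4, r = 0.5, j = 6, a = 0.1))
  expect_equal(sum(d2$arm == 0), 31)  # 30.5 rounds up
  expect_error(simulate_multilevel_trial(c(n1 = 3, k = 4, r = 1, j = 2, a = .1)),
               "empty therapist")
  expect_error(simulate_multilevel_trial(c(n1 = 5, k = 2, r = 0.5, j = 30, a = .1)),
               "empty doctor")
})

test_that("arm-specific marginal variances and correlations match the model", {
  params <- multilevel_params()
  set.seed(7)
  big <- c(n1 = 5e4, k = 200, r = 1, j = 200, a = 0.1)
  d <- simulate_multilevel_trial(big, params, "null")
  v_ctrl <- var(d$y_F[d$arm == 0])
  v_int <- var(d$y_F[d$arm == 1])
  # sampling error has a residual-level and a cluster-level component
  se_v <- sqrt(2 / 5e4) * params$residual_var +
    sqrt(2 / 200) * (params$doctor_var + params$therapist_var)
  expect_lt(abs(v_ctrl - (params$doctor_var + params$residual_var)), 5 * se_v)
  expect_lt(abs(v_int - (params$therapist_var + params$doctor_var +
                           params$residual_var)), 5 * se_v)
  # residual-only structure: endpoint correlation is rho_w
  p0 <- multilevel_params(therapist_var = 1e-12, doctor_var = 1e-12,
                          rho_w = 0.9)
  d0 <- simulate_multilevel_trial(big, p0, "null")
  expect_lt(abs(cor(d0$y_F, d0$y_D) - 0.9), 0.01)
})

test_that("the working-model likelihood equals the dense multivariate normal density", {
  set.seed(3)
  d <- simulate_multilevel_trial(des, hypothesis = "alternative")
  n <- nrow(d)
  beta <- c(0.3, 0.9); st2 <- 0.25; sd2 <- 0.4; sw2 <- 3.1
  ZT <- matrix(0, n, 4)
  idx <- which(d$arm == 1)
  ZT[cbind(idx, d$therapist[idx])] <- 1
  ZD <- matrix(0, n, 6)
  ZD[cbind(1:n, d$doctor)] <- 1
  V <- st2 * tcrossprod(ZT) + sd2 * tcrossprod(ZD) + sw2 * diag(n)
  res <- d$y_F - cbind(1, d$arm) %*% beta
  dense <- -0.5 * (n * log(2 * pi) + as.numeric(determinant(V)$modulus) +
                     drop(t(res) %*% solve(V) %*% res))
  expect_equal(multilevel_loglik(d, "F", beta, st2, sd2, sw2), dense,
               tolerance = 1e-8)
})

test_that("the profiled fit agrees with an established mixed-model package", {
  skip_if_not_installed("lme4")
  set.seed(5)
  d <- simulate_multilevel_trial(des, hypothesis = "alternative")
  mine <- lmm_fit_lrt(d, "F", 0.1)
  d2 <- as.data.frame(d)
  d2$therapist[is.na(d2$therapist)] <- 999L
  m1 <- lme4::lmer(y_F ~ arm + (0 + arm | therapist) + (1 | doctor),
                   data = d2, REML = FALSE)
  expect_equal(mine$loglik1, as.numeric(stats::logLik(m1)), tolerance = 1e-5)
  expect_equal(mine$beta1, unname(lme4::fixef(m1)[2]), tolerance = 1e-4)
  m0 <- lme4::lmer(y_F ~ 1 + (0 + arm | therapist) + (1 | doctor),
                   data = d2, REML = FALSE)
  expect_equal(mine$loglik0, as.numeric(stats::logLik(m0)), tolerance = 1e-5)
})

test_that("null variance components are estimated near zero", {
  params <- multilevel_params(therapist_var = 1e-12, doctor_var = 1e-12,
                              rho_t = 0, rho_d = 0)
  set.seed(9)
  d <- simulate_multilevel_trial(c(n1 = 100, k = 5, r = 1, j = 8, a = 0.1),
                                 params, "null")
  f <- lmm_fit_lrt(d, "F", 0.1)
  expect_lt(f$sigma_t2, 0.15)
  expect_lt(f$sigma_d2, 0.15)
  expect_equal(f$sigma_w2, params$residual_var, tolerance = 0.35)
})

test_that("parameters are recovered as every dimension of the design grows", {
  params <- multilevel_params()
  set.seed(13)
  reps <- 10
  est <- t(vapply(seq_len(reps), function(i) {
    d <- simulate_multilevel_trial(c(n1 = 800, k = 30, r = 1, j = 30, a = 0.1),
                                   params, "alternative")
    f <- lmm_fit_lrt(d, "F", 0.1)
    c(f$beta1, f$sigma_t2, f$sigma_d2, f$sigma_w2)
  }, numeric(4)))
  truth <- c(1.10, params$therapist_var, params$doctor_var, params$residual_var)
  expect_true(all(abs(colMeans(est) - truth) / truth < 0.2))
})

test_that("either-endpoint decisions respect the Bonferroni-type bounds", {
  params <- multilevel_params()
  sim <- multilevel_simulator(params)
  a <- 0.15
  est <- estimate_oc(sim, c(n1 = 30, k = 3, r = 1, j = 4, a = a), "null", 250,
                     rng_stream(19))
  expect_gt(est$estimate, a - 3 * est$std_error)
  expect_lt(est$estimate, 2 * a + 3 * est$std_error)
})

test_that("perfectly correlated identical endpoints behave as one test", {
  params <- multilevel_params(rho_w = 1, rho_t = 1, rho_d = 1)
  set.seed(23)
  d <- simulate_multilevel_trial(c(n1 = 40, k = 4, r = 1, j = 5, a = 0.1),
                                 params, "null")
  expect_equal(d$y_F, d$y_D, tolerance = 1e-12)
  fF <- lmm_fit_lrt(d, "F", 0.1)
  fD <- lmm_fit_lrt(d, "D", 0.1)
  expect_equal(fF$p_value, fD$p_value, tolerance = 1e-6)
})

test_that("the built-in problem computes its documented objective vectors", {
  prob <- pace_problem()
  Y <- prob$objectives(cbind(n1 = 94, k = 5, r = 108 / 94, j = 15, a = 0.11))
  expect_equal(unname(Y), cbind(202, 5, 15))
  Y2 <- prob$objectives(cbind(n1 = 97, k = 10, r = 93 / 97, j = 5, a = 0.14))
  expect_equal(unname(Y2), cbind(190, 10, 5))
  expect_equal(prob$thresholds, c(0.1, 0.2))
  expect_equal(prob$constraints[[1]]$event, "accept")
  expect_equal(prob$constraints[[2]]$event, "reject")
})
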