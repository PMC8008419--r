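# Built-in problem 2: a two-arm, two-endpoint trial with a partially nested
# therapist factor (intervention arm only), a doctor factor crossed with
# arms, and correlated endpoints. Each endpoint is analysed with its own
# (deliberately misspecified, univariate) mixed model and a one-sided
# likelihood ratio test; the trial is positive if either endpoint is
# significant, inflating the familywise type I error.

#' Parameters of the two-endpoint multilevel trial example
#'
#' Response model per endpoint r:
#' `y_ir = b0r + b1r t_i + u_{therapist(i),r} t_i + v_{doctor(i),r} + e_ir`,
#' with bivariate (across endpoints) therapist effects, doctor effects and
#' residuals, each with common marginal variance and cross-endpoint
#' correlation. Defaults give a control-arm variance partition coefficient
#' of `doctor_var / (doctor_var + residual_var) = 0.1` and a standardised
#' intervention-arm effect of `1.10 / sqrt(0.19 + 0.37 + 3.29) = 0.56`.
#'
#' @param therapist_var,doctor_var,residual_var Marginal variances of the
#'   random effects and residuals (each endpoint).
#' @param rho_w,rho_t,rho_d Cross-endpoint correlations of residuals,
#'   therapist effects and doctor effects.
#' @param effect Treatment effect per endpoint under the alternative
#'   (named vector for endpoints F and D).
#' @param intercept Intercept per endpoint.
#' @return A list of class `multilevel_params`.
#' @export
multilevel_params <- function(therapist_var = 0.19, doctor_var = 0.37,
                              residual_var = 3.29,
                              rho_w = 0.9, rho_t = 0.9, rho_d = 0.9,
                              effect = c(F = 1.10, D = 1.10),
                              intercept = c(F = 0, D = 0)) {
  stopifnot(therapist_var > 0, doctor_var > 0, residual_var > 0,
            all(abs(c(rho_w, rho_t, rho_d)) <= 1))
  structure(list(therapist_var = therapist_var, doctor_var = doctor_var,
                 residual_var = residual_var, rho_w = rho_w, rho_t = rho_t,
                 rho_d = rho_d, effect = effect, intercept = intercept),
            class = "multilevel_params")
}

# bivariate normal draws: n x 2 with marginal variance v, correlation rho
.rbiv <- function(n, v, rho) {
  z <- matrix(stats::rnorm(2 * n), n, 2)
  a <- sqrt(v); b <- sqrt(v) * rho; c2 <- sqrt(v * (1 - rho^2))
  cbind(a * z[, 1], b * z[, 1] + c2 * z[, 2])
}

#' Simulate one dataset from the multilevel trial
#'
#' Intervention participants are assigned round-robin to the `k` therapists
#' and, independently round-robin, to the `j` doctors (cross-classified);
#' control participants are assigned round-robin to the doctors only
#' (nested). Cluster sizes are therefore as balanced as possible. The
#' control arm holds `n0 = round(r * n1)` participants (half-up).
#'
#' @param design Named vector or list with `n1` (intervention-arm size),
#'   `k` (therapists), `r` (allocation ratio `n0/n1`), `j` (doctors); an
#'   `a` entry (nominal test level) is carried along if present.
#' @param params A [multilevel_params()].
#' @param hypothesis `"alternative"` (configured effects) or `"null"` (both
#'   effects zero).
#' @return A tibble: `patient`, `arm` (0/1), `therapist` (NA in control),
#'   `doctor`, `y_F`, `y_D`.
#' @export
simulate_multilevel_trial <- function(design, params = multilevel_params(),
                                      hypothesis = "alternative") {
  n1 <- as.integer(design[["n1"]]); k <- as.integer(design[["k"]])
  j <- as.integer(design[["j"]])
  n0 <- as.integer(floor(design[["r"]] * n1 + 0.5))
  if (n1 < k) stop("empty therapist cells: n1 = ", n1, " < k = ", k)
  if (n1 + n0 < j) stop("empty doctor cells: n1 + n0 = ", n1 + n0, " < j = ", j)
  eff <- if (hypothesis == "alternative") params$effect else c(F = 0, D = 0)
  u <- .rbiv(k, params$therapist_var, params$rho_t)
  v <- .rbiv(j, params$doctor_var, params$rho_d)
  n <- n1 + n0
  e <- .rbiv(n, params$residual_var, params$rho_w)
  arm <- c(rep(1L, n1), rep(0L, n0))
  therapist <- c((seq_len(n1) - 1L) %% k + 1L, rep(NA_integer_, n0))
  doctor <- c((seq_len(n1) - 1L) %% j + 1L, (seq_len(n0) - 1L) %% j + 1L)
  ther_eff <- matrix(0, n, 2)
  ther_eff[seq_len(n1), ] <- u[therapist[seq_len(n1)], , drop = FALSE]
  y <- matrix(params$intercept, n, 2, byrow = TRUE) +
    outer(arm, unname(eff[c("F", "D")])) + ther_eff +
    v[doctor, , drop = FALSE] + e
  tibble::tibble(patient = seq_len(n), arm = arm, therapist = therapist,
                 doctor = doctor, y_F = y[, 1], y_D = y[, 2])
}

# --- profiled marginal ML for the univariate working model ----------------
# V = sW2 * W,  W = I + phiT Z_T Z_T' + phiD Z_D Z_D'. The random-effects
# structure has rank k + j, so W is handled through the Woodbury identity:
# all quadratic forms reduce to (k+j) x (k+j) algebra after one pass of
# cross-products over the data.

.lmm_precompute <- function(data, endpoint) {
  y <- data[[paste0("y_", endpoint)]]
  n <- nrow(data)
  t <- data$arm
  k <- max(data$therapist, na.rm = TRUE)
  j <- max(data$doctor)
  ZT <- matrix(0, n, k)
  idx <- which(!is.na(data$therapist) & data$arm == 1)
  ZT[cbind(idx, data$therapist[idx])] <- 1
  ZD <- matrix(0, n, j)
  ZD[cbind(seq_len(n), data$doctor)] <- 1
  U <- cbind(ZT, ZD)
  X1 <- cbind(1, t)
  X0 <- matrix(1, n, 1)
  list(n = n, k = k, j = j, y = y, U = U, X1 = X1, X0 = X0,
       CUU = crossprod(U), CU1 = crossprod(U, X1), CU0 = crossprod(U, X0),
       CUy = drop(crossprod(U, y)),
       C11 = crossprod(X1), C10 = crossprod(X0),
       C1y = drop(crossprod(X1, y)), C0y = drop(crossprod(X0, y)),
       yy = sum(y * y))
}

# profiled log-likelihood at variance ratios phi = (sT2, sD2)/sW2;
# beta and sW2 are profiled out by GLS. Returns ll, beta, sW2.
.lmm_profile <- function(pc, phi, null_model = FALSE) {
  srt <- sqrt(c(rep(phi[1], pc$k), rep(phi[2], pc$j)))
  M <- diag(pc$k + pc$j) + (srt %o% srt) * pc$CUU
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  logdetW <- 2 * sum(log(diag(ch)))
  CX <- if (null_model) pc$CU0 else pc$CU1
  CXX <- if (null_model) pc$C10 else pc$C11
  CXy <- if (null_model) pc$C0y else pc$C1y
  tX <- backsolve(ch, srt * CX, transpose = TRUE)
  ty <- backsolve(ch, srt * pc$CUy, transpose = TRUE)
  GXX <- CXX - crossprod(tX)
  GXy <- CXy - drop(crossprod(tX, ty))
  Gyy <- pc$yy - sum(ty * ty)
  beta <- tryCatch(solve(GXX, GXy), error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  rss <- max(Gyy - sum(GXy * beta), 1e-12)
  sW2 <- rss / pc$n
  ll <- -0.5 * (pc$n * log(2 * pi) + pc$n * log(sW2) + pc$n + logdetW)
  list(ll = ll, beta = drop(beta), sW2 = sW2)
}

.lmm_ml_fit <- function(pc, null_model = FALSE, n_restarts = 3) {
  obj <- function(eta) {
    eta <- pmin(pmax(eta, -20), 7)
    r <- .lmm_profile(pc, exp(eta), null_model)
    if (is.null(r) || !is.finite(r$ll)) 1e10 else -r$ll
  }
  starts <- list(c(log(0.05), log(0.1)), c(0, 0), c(-8, -8))[seq_len(n_restarts)]
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, obj, method = "Nelder-Mead",
                   control = list(maxit = 300, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best) || best$value >= 1e10) return(NULL)
  eta <- pmin(pmax(best$par, -20), 7)
  fit <- .lmm_profile(pc, exp(eta), null_model)
  fit$phi <- exp(eta)
  fit
}

#' Evaluate the working-model log-likelihood at fixed parameters
#'
#' The marginal Gaussian log-likelihood of one endpoint's univariate working
#' model `y = b0 + b1 t + therapist effect (intervention only) + doctor
#' effect + residual`, with
#' `V = sigma_T^2 Z_T Z_T' + sigma_D^2 Z_D Z_D' + sigma_W^2 I` assembled
#' from the dataset's therapist/doctor index columns. Exposed so the
#' likelihood can be checked against a dense multivariate-normal density.
#'
#' @param data A dataset from [simulate_multilevel_trial()].
#' @param endpoint `"F"` or `"D"`.
#' @param beta Fixed-effect vector `c(b0, b1)` (or `b0` alone for the null
#'   model).
#' @param sigma_t2,sigma_d2,sigma_w2 Variance components.
#' @return The log-likelihood value.
#' @export
multilevel_loglik <- function(data, endpoint, beta, sigma_t2, sigma_d2,
                              sigma_w2) {
  pc <- .lmm_precompute(data, endpoint)
  X <- if (length(beta) == 1) pc$X0 else pc$X1
  res <- pc$y - drop(X %*% beta)
  phi <- c(sigma_t2, sigma_d2) / sigma_w2
  srt <- sqrt(c(rep(phi[1], pc$k), rep(phi[2], pc$j)))
  M <- diag(pc$k + pc$j) + (srt %o% srt) * pc$CUU
  ch <- chol(M)
  tU <- backsolve(ch, srt * drop(crossprod(pc$U, res)), transpose = TRUE)
  quad <- (sum(res * res) - sum(tU * tU)) / sigma_w2
  logdet <- pc$n * log(sigma_w2) + 2 * sum(log(diag(ch)))
  -0.5 * (pc$n * log(2 * pi) + logdet + quad)
}

#' Mixed-model fit and one-sided likelihood ratio test for one endpoint
#'
#' Fits the univariate working model by maximum likelihood (variance ratios
#' on the log scale, Nelder-Mead with three restarts, fixed effects and the
#' residual variance profiled out by generalised least squares) under the
#' null (`b1 = 0`) and the alternative (`b1` free). The one-sided p-value
#' uses the signed-root chi-square equivalence: half the two-sided
#' chi-square(1) p-value when the effect estimate is beneficial (positive),
#' else one minus half. Non-convergence after all restarts is recorded as a
#' non-rejection with `converged = FALSE` (conservative).
#'
#' @param data A dataset from [simulate_multilevel_trial()].
#' @param endpoint `"F"` or `"D"`.
#' @param alpha Nominal one-sided test level.
#' @return A one-row tibble: `p_value`, `reject`, `lrt`, `beta1`,
#'   `sigma_t2`, `sigma_d2`, `sigma_w2`, `loglik1`, `loglik0`, `converged`.
#' @export
lmm_fit_lrt <- function(data, endpoint, alpha) {
  pc <- .lmm_precompute(data, endpoint)
  f1 <- .lmm_ml_fit(pc, null_model = FALSE)
  f0 <- .lmm_ml_fit(pc, null_model = TRUE)
  if (is.null(f1) || is.null(f0)) {
    return(tibble::tibble(p_value = NA_real_, reject = FALSE, lrt = NA_real_,
                          beta1 = NA_real_, sigma_t2 = NA_real_,
                          sigma_d2 = NA_real_, sigma_w2 = NA_real_,
                          loglik1 = NA_real_, loglik0 = NA_real_,
                          converged = FALSE))
  }
  lrt <- max(2 * (f1$ll - f0$ll), 0)
  p_two <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  beta1 <- unname(f1$beta[2])
  p <- if (beta1 > 0) p_two / 2 else 1 - p_two / 2
  tibble::tibble(p_value = p, reject = p <= alpha, lrt = lrt, beta1 = beta1,
                 sigma_t2 = f1$phi[1] * f1$sW2, sigma_d2 = f1$phi[2] * f1$sW2,
                 sigma_w2 = f1$sW2, loglik1 = f1$ll, loglik0 = f0$ll,
                 converged = TRUE)
}

#' Simulate one trial decision for the multilevel example
#'
#' Simulates a dataset, analyses both endpoints at the design's nominal
#' level, and applies the decision rule: positive if either endpoint (or,
#' optionally, both endpoints) shows a significant beneficial difference.
#' Under the global null this realises the inflated familywise type I
#' error; under the alternative, the power.
#'
#' @param design Named vector with `n1`, `k`, `r`, `j`, `a`.
#' @param params A [multilevel_params()].
#' @param hypothesis `"null"` or `"alternative"`.
#' @param rule `"either"` (default, the familywise rule) or `"both"`.
#' @return 0/1 reject indicator.
#' @export
multilevel_reject_once <- function(design, params = multilevel_params(),
                                   hypothesis = "alternative",
                                   rule = c("either", "both")) {
  rule <- match.arg(rule)
  data <- simulate_multilevel_trial(design, params, hypothesis)
  a <- design[["a"]]
  rf <- lmm_fit_lrt(data, "F", a)$reject
  rd <- lmm_fit_lrt(data, "D", a)$reject
  as.numeric(if (rule == "either") rf || rd else rf && rd)
}

#' Trial simulator for the multilevel example
#'
#' @param params A [multilevel_params()].
#' @param rule Decision rule, as in [multilevel_reject_once()].
#' @return A [trial_simulator()] over designs `(n1, k, r, j, a)`.
#' @export
multilevel_simulator <- function(params = multilevel_params(),
                                 rule = c("either", "both")) {
  rule <- match.arg(rule)
  trial_simulator(
    simulate_once = function(design, hypothesis)
      multilevel_reject_once(design, params, hypothesis, rule),
    hypotheses = c("null", "alternative"),
    name = "multilevel_two_endpoint"
  )
}

#' The two-endpoint multilevel trial design problem
#'
#' Five design parameters — intervention-arm size `n1` in [50, 100],
#' therapists `k` in [2, 10], allocation ratio `r` in [0.5, 1.5], doctors
#' `j` in [3, 20], nominal test level `a` in [0.05, 0.2] — with three
#' objectives (total participants `n1 + round(r n1)`, therapists, doctors)
#' and two simulation-estimated constraints: type II error at most 0.1
#' under the alternative and familywise type I error at most 0.2 under the
#' global null.
#'
#' @param params A [multilevel_params()].
#' @param type2_bound,type1_bound Nominal constraint thresholds.
#' @param ref_point Optional hypervolume reference point.
#' @return An [ssd_problem()].
#' @export
pace_problem <- function(params = multilevel_params(),
                         type2_bound = 0.1, type1_bound = 0.2,
                         ref_point = NULL) {
  space <- solution_space(c("n1", "k", "r", "j", "a"),
                          lower = c(50, 2, 0.5, 3, 0.05),
                          upper = c(100, 10, 1.5, 20, 0.2),
                          integer = c(TRUE, TRUE, FALSE, TRUE, FALSE))
  objectives <- function(X)
    cbind(total_n = X[, "n1"] + floor(X[, "r"] * X[, "n1"] + 0.5),
          therapists = X[, "k"], doctors = X[, "j"])
  ssd_problem(space, objectives,
              constraints = list(
                oc_constraint("type2", "alternative", type2_bound, "accept"),
                oc_constraint("type1", "null", type1_bound, "reject")),
              ref_point = ref_point, name = "multilevel_two_endpoint")
}
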