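# Gaussian process regression with a squared-exponential kernel and a fixed
# heteroscedastic noise diagonal: the noise variances are the known Monte
# Carlo error variances of each observation, not a free nugget.

#' Squared-exponential covariance between two points
#'
#' `k(x, x') = sigma * exp(-sum_j (x_j - x'_j)^2 / lambda_j^2)` with signal
#' variance `sigma` and one length-scale per input dimension.
#'
#' @param x,x2 Numeric vectors of equal length D.
#' @param sigma Signal variance (> 0).
#' @param lengthscales Length-D vector of positive length-scales.
#' @return The covariance value.
#' @examples
#' se_kernel(0, 1, sigma = 1, lengthscales = 1)  # exp(-1)
#' @export
se_kernel <- function(x, x2, sigma, lengthscales) {
  if (length(x) != length(x2))
    stop("dimension mismatch: ", length(x), " vs ", length(x2))
  if (length(lengthscales) == 1) lengthscales <- rep(lengthscales, length(x))
  if (length(lengthscales) != length(x))
    stop("lengthscales has length ", length(lengthscales), "; points have ", length(x))
  sigma * exp(-sum((x - x2)^2 / lengthscales^2))
}

# per-dimension squared-difference arrays, cached once per training set
.sqdist_list <- function(X, X2 = NULL) {
  if (is.null(X2)) X2 <- X
  lapply(seq_len(ncol(X)), function(d) outer(X[, d], X2[, d], "-")^2)
}

.kernel_from_sqdist <- function(sq, sigma, lengthscales) {
  s <- sq[[1]] / lengthscales[1]^2
  if (length(sq) > 1) for (d in 2:length(sq)) s <- s + sq[[d]] / lengthscales[d]^2
  sigma * exp(-s)
}

# Cholesky of K + noise, escalating jitter 0 -> 1e-8 -> ... -> 1e-4 only
# when factorisation fails (the noise diagonal usually suffices)
.chol_with_jitter <- function(K, noise) {
  A <- K + diag(noise, nrow(K))
  for (jit in c(0, 10^(-8:-4))) {
    ch <- tryCatch(chol(A + diag(jit * (mean(diag(K)) + 1), nrow(A))),
                   error = function(e) NULL)
    if (!is.null(ch)) return(list(chol = ch, jitter = jit))
  }
  NULL
}

#' Log marginal likelihood of a Gaussian process model
#'
#' `-1/2 y'(K+D)^-1 y - 1/2 log|K+D| - (n/2) log 2pi` on centred targets,
#' where D is the diagonal of fixed noise variances. Inputs are used as
#' given (no internal rescaling); [fit_gp()] handles scaling.
#'
#' @param X Matrix of inputs (rows = observations).
#' @param y Numeric targets.
#' @param noise_var Vector of per-observation noise variances.
#' @param sigma,lengthscales Kernel hyperparameters.
#' @param offset Constant subtracted from `y` before applying the zero-mean
#'   formulas (default: the empirical mean).
#' @return The log marginal likelihood.
#' @export
log_marginal_likelihood <- function(X, y, noise_var, sigma, lengthscales,
                                    offset = mean(y)) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, length(noise_var) == n)
  sq <- .sqdist_list(X)
  K <- .kernel_from_sqdist(sq, sigma, lengthscales)
  cj <- .chol_with_jitter(K, noise_var)
  if (is.null(cj))
    stop("K + noise not positive definite after maximal jitter (sigma=", sigma,
         ", lengthscales=", paste(signif(lengthscales, 3), collapse = ","), ")")
  yc <- y - offset
  a <- backsolve(cj$chol, backsolve(cj$chol, yc, transpose = TRUE))
  -0.5 * sum(yc * a) - sum(log(diag(cj$chol))) - n / 2 * log(2 * pi)
}

#' Control parameters for Gaussian process fitting
#'
#' @param n_starts Number of multi-start points for the hyperparameter search.
#' @param lengthscale_bounds Bounds for each length-scale on the unit-box
#'   scale.
#' @param sigma_bounds Bounds for the signal variance.
#' @param maxit Iteration cap for each local (L-BFGS-B) search.
#' @return A list of class `gp_control`.
#' @export
gp_control <- function(n_starts = 10, lengthscale_bounds = c(0.01, 10),
                       sigma_bounds = c(1e-6, 1), maxit = 50) {
  structure(list(n_starts = n_starts, lengthscale_bounds = lengthscale_bounds,
                 sigma_bounds = sigma_bounds, maxit = maxit),
            class = "gp_control")
}

#' Fit a Gaussian process surrogate by maximum marginal likelihood
#'
#' Inputs are affinely mapped to the unit box (design parameters have wildly
#' different ranges); targets are centred on their empirical mean and the
#' zero-mean equations applied to residuals. Hyperparameters (signal variance
#' and one length-scale per dimension) are found by the best of `n_starts`
#' bounded L-BFGS-B maximisations of the log marginal likelihood, started
#' from a quasi-random design in log-hyperparameter space. Noise variances
#' are fixed inputs (the squared Monte Carlo standard errors), never
#' estimated.
#'
#' @param X Design matrix (raw parameter values, rows = evaluated designs).
#' @param y Observed Monte Carlo estimates.
#' @param noise_var Per-observation noise variances (strictly positive).
#' @param space A [solution_space()] supplying the scaling box; if `NULL`,
#'   the ranges of `X` are used.
#' @param control A [gp_control()].
#' @return An object of class `gp_model`.
#' @export
fit_gp <- function(X, y, noise_var, space = NULL, control = gp_control()) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 2, length(y) == n, length(noise_var) == n)
  if (!all(is.finite(y))) stop("targets must be finite")
  if (any(noise_var < 0)) stop("noise variances must be >= 0")
  if (is.null(space)) {
    lo <- apply(X, 2, min); hi <- apply(X, 2, max)
    hi[hi <= lo] <- lo[hi <= lo] + 1
    space <- solution_space(colnames(X) %||% paste0("x", seq_len(ncol(X))), lo, hi)
  }
  Xs <- space_scale(space, X)
  D <- ncol(Xs)
  offset <- mean(y)
  yc <- y - offset
  sq <- .sqdist_list(Xs)

  lb <- c(log(control$sigma_bounds[1]), rep(log(control$lengthscale_bounds[1]), D))
  ub <- c(log(control$sigma_bounds[2]), rep(log(control$lengthscale_bounds[2]), D))

  nll <- function(par) {
    K <- .kernel_from_sqdist(sq, exp(par[1]), exp(par[-1]))
    cj <- .chol_with_jitter(K, noise_var)
    if (is.null(cj)) return(1e10)
    a <- backsolve(cj$chol, backsolve(cj$chol, yc, transpose = TRUE))
    0.5 * sum(yc * a) + sum(log(diag(cj$chol))) + n / 2 * log(2 * pi)
  }
  ngr <- function(par) {
    sigma <- exp(par[1]); ls <- exp(par[-1])
    K <- .kernel_from_sqdist(sq, sigma, ls)
    cj <- .chol_with_jitter(K, noise_var)
    if (is.null(cj)) return(rep(0, length(par)))
    Qi <- chol2inv(cj$chol)
    a <- Qi %*% yc
    W <- Qi - tcrossprod(a)            # d(-lml)/dQ = 1/2 W (trace sense)
    g <- numeric(length(par))
    g[1] <- 0.5 * sum(W * K)           # dK/dlog sigma = K
    for (d in seq_len(D))              # dK/dlog lambda_d = K * 2 sq_d / lambda_d^2
      g[1 + d] <- 0.5 * sum(W * (K * (2 * sq[[d]] / ls[d]^2)))
    g
  }

  # multi-start: quasi-random points in the log box, plus a median heuristic
  starts <- sobol_sequence(max(1, control$n_starts - 1), D + 1)
  starts <- sweep(sweep(starts, 2, ub - lb, "*"), 2, lb, "+")
  med_ls <- vapply(seq_len(D), function(d) {
    dd <- sqrt(sq[[d]][upper.tri(sq[[d]])])
    m <- stats::median(dd[dd > 0])
    if (!is.finite(m) || m <= 0) 0.5 else m
  }, numeric(1))
  heuristic <- c(log(max(min(stats::var(yc), control$sigma_bounds[2]),
                         control$sigma_bounds[1] * 10)),
                 log(pmin(pmax(med_ls, control$lengthscale_bounds[1]),
                          control$lengthscale_bounds[2])))
  starts <- rbind(heuristic, starts)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(pmin(pmax(starts[i, ], lb), ub), nll, ngr,
                   method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = control$maxit)),
      error = function(e) NULL)
    if (is.null(res)) next
    # contract: achieved value >= value at every start point
    if (res$value > nll(starts[i, ]) + 1e-9) res <- list(par = starts[i, ], value = nll(starts[i, ]))
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    warning("all hyperparameter searches failed; falling back to median-heuristic length-scales")
    best <- list(par = heuristic, value = nll(heuristic))
  }

  sigma <- exp(best$par[1]); ls <- exp(best$par[-1])
  K <- .kernel_from_sqdist(sq, sigma, ls)
  cj <- .chol_with_jitter(K, noise_var)
  if (is.null(cj)) stop("fitted kernel matrix not positive definite")
  alpha <- backsolve(cj$chol, backsolve(cj$chol, yc, transpose = TRUE))
  structure(
    list(sigma = sigma, lengthscales = ls, space = space,
         X = X, Xs = Xs, y = y, noise_var = noise_var,
         offset = offset, chol = cj$chol, jitter = cj$jitter,
         alpha = as.numeric(alpha), log_marginal = -best$value),
    class = "gp_model"
  )
}

#' Predictive distribution of a fitted Gaussian process
#'
#' Mean `k*' (K+D)^-1 y` (plus the centring offset) and variance
#' `k(x*,x*) - k*' (K+D)^-1 k*`, clipped at zero where round-off makes it
#' negative.
#'
#' @param object A `gp_model`.
#' @param newdata Matrix/data frame of raw design points.
#' @param ... Unused.
#' @return A tibble with columns `mean`, `var`, `sd` (one row per point).
#' @export
predict.gp_model <- function(object, newdata, ...) {
  p <- .gp_predict_raw(object, newdata)
  tibble::tibble(mean = p$mean, var = p$var, sd = p$sd)
}

# tibble-free prediction for hot loops
.gp_predict_raw <- function(object, newdata) {
  Xs2 <- space_scale(object$space, newdata)
  sq <- .sqdist_list(object$Xs, Xs2)
  Ks <- .kernel_from_sqdist(sq, object$sigma, object$lengthscales)  # n_train x n_new
  mu <- unname(drop(crossprod(Ks, object$alpha))) + object$offset
  V <- backsolve(object$chol, Ks, transpose = TRUE)
  var <- unname(pmax(object$sigma - colSums(V^2), 0))
  list(mean = mu, var = var, sd = sqrt(var))
}

#' @export
print.gp_model <- function(x, ...) {
  cat("<gp_model> ", nrow(x$X), " observations, D=", ncol(x$X), "\n", sep = "")
  cat("  sigma = ", signif(x$sigma, 4), "; lengthscales (unit box): ",
      paste(signif(x$lengthscales, 4), collapse = ", "), "\n", sep = "")
  cat("  log marginal likelihood = ", signif(x$log_marginal, 6), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.gp_model <- function(x, ...) {
  tibble::tibble(
    term = c("sigma", paste0("lengthscale_", x$space$names)),
    estimate = c(x$sigma, x$lengthscales)
  )
}

#' @export
glance.gp_model <- function(x, ...) {
  tibble::tibble(n_obs = nrow(x$X), log_marginal = x$log_marginal,
                 offset = x$offset, jitter = x$jitter)
}

# JSON-serialisable state for checkpoints
gp_state <- function(model) {
  list(sigma = model$sigma, lengthscales = model$lengthscales,
       offset = model$offset)
}
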