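# Independent oracles used across the suite. Each deliberately avoids the
# package's own computational path: brute-force enumeration, dense matrix
# algebra, or plain Monte Carlo integration.

# pairwise brute-force nondominated filter
oracle_nondominated <- function(Y) {
  n <- nrow(Y)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && all(Y[j, ] <= Y[i, ]) && any(Y[j, ] < Y[i, ])) keep[i] <- FALSE
      if (i != j && j < i && all(Y[j, ] == Y[i, ])) keep[i] <- FALSE
    }
  }
  keep
}

# rejection-sampling hypervolume estimate with its MC standard error
oracle_hypervolume_mc <- function(Y, ref, n_draws = 1e6, seed = 1) {
  set.seed(seed)
  B <- length(ref)
  lo <- apply(Y, 2, min)
  U <- sapply(seq_len(B), function(d) runif(n_draws, lo[d], ref[d]))
  dominated <- rep(FALSE, n_draws)
  for (i in seq_len(nrow(Y))) {
    inside <- U[, 1] >= Y[i, 1]
    for (d in 2:B) inside <- inside & U[, d] >= Y[i, d]
    dominated <- dominated | inside
  }
  box <- prod(ref - lo)
  p <- mean(dominated)
  list(estimate = p * box, se = sqrt(p * (1 - p) / n_draws) * box)
}

# dense-formula GP predictive moments (explicit inversion, no Cholesky reuse)
oracle_gp_predict <- function(X, y, noise_var, sigma, ls, xstar, offset = mean(y)) {
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- sigma * exp(-sum((X[i, ] - X[j, ])^2 / ls^2))
  ks <- sapply(seq_len(n), function(i) sigma * exp(-sum((X[i, ] - xstar)^2 / ls^2)))
  Qi <- solve(K + diag(noise_var, n))
  m <- drop(t(ks) %*% Qi %*% (y - offset)) + offset
  v <- sigma - drop(t(ks) %*% Qi %*% ks)
  list(mean = m, var = v)
}

oracle_gp_lml <- function(X, y, noise_var, sigma, ls, offset = mean(y)) {
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- sigma * exp(-sum((X[i, ] - X[j, ])^2 / ls^2))
  Q <- K + diag(noise_var, n)
  yc <- y - offset
  drop(-0.5 * t(yc) %*% solve(Q) %*% yc -
         0.5 * as.numeric(determinant(Q)$modulus) - n / 2 * log(2 * pi))
}

# simulator rejecting with known probability p (possibly design-dependent)
bernoulli_simulator <- function(p_fun) {
  trial_simulator(
    simulate_once = function(design, hypothesis)
      as.numeric(runif(1) < p_fun(design, hypothesis)),
    simulate_batch = function(design, hypothesis, n)
      as.numeric(runif(n) < p_fun(design, hypothesis)),
    hypotheses = c("null", "alternative"),
    name = "bernoulli"
  )
}

unit_space_2d <- function() solution_space(c("x1", "x2"), c(0, 0), c(1, 1))
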