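# Shared test utilities: random dataset generation and slow reference
# implementations kept independent of the package internals.

# Random study-level dataset with known truth; moderate variance spread.
random_dataset <- function(k, p_covariates = 0, tau2 = 0.1) {
  x <- if (p_covariates > 0)
    matrix(rnorm(k * p_covariates), k, p_covariates,
           dimnames = list(NULL, paste0("x", seq_len(p_covariates))))
  else NULL
  v <- runif(k, 0.02, 0.5)
  mu <- if (is.null(x)) rep(0.3, k) else drop(0.3 + x %*% rep(0.5, p_covariates))
  y <- rnorm(k, mu, sqrt(tau2 + v))
  meta_dataset(y = y, vi = v,
               moderators = if (!is.null(x)) as.data.frame(x))
}

# Restricted log-likelihood evaluated directly (dense formulation);
# used by the grid-search REML oracle below.
restricted_ll_oracle <- function(tau2, y, v, X) {
  V <- diag(v + tau2)
  W <- solve(V)
  M <- t(X) %*% W %*% X
  b <- solve(M, t(X) %*% W %*% y)
  r <- y - X %*% b
  -0.5 * (determinant(V)$modulus[1] + determinant(M)$modulus[1] +
            drop(t(r) %*% W %*% r))
}

# Dense grid search over tau2 (step 1e-5): the brute-force REML oracle.
grid_reml_oracle <- function(y, v, X, upper = NULL, step = 1e-5) {
  if (is.null(upper)) upper <- max(var(y) * 3, 0.5)
  grid <- seq(0, upper, by = step)
  ll <- vapply(grid, function(t2) restricted_ll_oracle(t2, y, v, X),
               numeric(1))
  grid[which.max(ll)]
}

# Direct evaluation of Vn from its defining sum (no matrices): refits the
# model with each study omitted using the package REML fitter only through
# the public interface.
vn_by_definition <- function(fit) {
  loo <- loo_estimates(fit)
  sum((loo$y - loo$estimate)^2 / (fit$vi + loo$se^2))
}
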