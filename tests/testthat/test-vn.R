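test_that("Vn equals its quadratic-form representation on random data", {
  set.seed(42)
  for (rep in 1:8) {
    k <- sample(5:9, 1)
    p_cov <- rep %% 2
    d <- random_dataset(k, p_cov, tau2 = 0.12)
    fit <- rema(if (p_cov) y ~ x1 else y ~ 1, d)
    v <- vn_test(fit)
    # direct sum over studies vs y' A' W* A y from the constructed matrix
    quad <- drop(t(fit$y) %*% t(v$A) %*% (v$w_star * (v$A %*% fit$y)))
    expect_equal(v$statistic, quad, tolerance = 1e-8)
    expect_equal(v$statistic, vn_by_definition(fit), tolerance = 1e-8)
  }
})

test_that("the contrast matrix has unit diagonal, zero row sums and rank k-p", {
  set.seed(9)
  for (p_cov in 0:1) {
    d <- random_dataset(8, p_cov)
    fit <- rema(if (p_cov) y ~ x1 else y ~ 1, d)
    v <- vn_test(fit)
    expect_equal(unname(diag(v$A)), rep(1, 8))
    # intercept models: the constant vector lies in the kernel
    expect_lt(max(abs(v$A %*% rep(1, 8))), 1e-10)
    expect_equal(qr(v$A)$rank, 8 - fit$p)
    # number of retained eigenvalues matches the rank
    expect_equal(length(v$lambdas), 8 - fit$p)
    expect_true(all(v$lambdas > 0))
  }
})

test_that("the kernel is exactly the fitted-mean subspace", {
  set.seed(23)
  # meta-analysis: kernel = constants only (dimension 1)
  d <- random_dataset(7)
  v <- vn_test(rema(y ~ 1, d))
  expect_equal(qr(v$A)$rank, 6)
  mu_in <- rep(2.5, 7)
  expect_lt(max(abs(v$A %*% mu_in)), 1e-9)
  mu_out <- c(rep(2.5, 6), 2.6)
  expect_gt(max(abs(v$A %*% mu_out)), 1e-4)

  # one covariate: kernel = {a + b x} (dimension 2)
  dm <- random_dataset(8, 1)
  vm <- vn_test(rema(y ~ x1, dm))
  expect_equal(qr(vm$A)$rank, 6)
  on_line <- 1.2 - 0.7 * dm$x1
  expect_lt(max(abs(vm$A %*% on_line)), 1e-9)
  off_line <- on_line + c(1, rep(0, 7))
  expect_gt(max(abs(vm$A %*% off_line)), 1e-4)
})

test_that("equal variances and equal loo tau2 give the closed-form contrast", {
  # with equal weights every leave-one-out mean weights the rest equally,
  # so off-diagonal entries are -1/(k-1)
  k <- 6
  d <- meta_dataset(y = rnorm(k, 0, 0.0001), vi = rep(0.25, k))
  fit <- rema(y ~ 1, d)
  v <- vn_test(fit)
  expected <- matrix(-1 / (k - 1), k, k); diag(expected) <- 1
  expect_equal(v$A, expected, tolerance = 1e-8)
})

test_that("identical studies predict themselves and give Vn = 0", {
  d <- meta_dataset(y = rep(0.8, 6), vi = rep(0.3, 6))
  fit <- rema(y ~ 1, d)
  loo <- loo_estimates(fit)
  expect_equal(loo$estimate, rep(0.8, 6))
  v <- vn_test(fit)
  expect_equal(v$statistic, 0, tolerance = 1e-12)
  expect_equal(v$p.value, 1, tolerance = 1e-6)
})

test_that("loo predictions are the weighted means of the remaining studies", {
  set.seed(31)
  d <- random_dataset(7, tau2 = 0.1)
  fit <- rema(y ~ 1, d)
  loo <- loo_estimates(fit)
  for (i in c(1, 4, 7)) {
    w <- 1 / (d$vi[-i] + loo$tau2_loo[i])
    expect_equal(loo$estimate[i], sum(w * d$y[-i]) / sum(w),
                 tolerance = 1e-10)
    expect_equal(loo$se[i]^2, 1 / sum(w), tolerance = 1e-10)
  }
})

test_that("null distribution of Vn matches the chi-squared mixture (KS)", {
  # known variances, tau2 fixed at the true value 0: the mixture law is
  # exact, so the empirical CDF over many draws must track it closely
  set.seed(77)
  k <- 6
  v <- runif(k, 0.05, 0.4)
  X <- matrix(1, k, 1)
  # contrast built at the truth (weights 1/v), not from estimated fits
  A <- diag(k)
  for (i in 1:k) {
    w <- 1 / v; w[i] <- 0
    A[i, -i] <- -(w[-i] / sum(w[-i]))
  }
  varhat <- vapply(1:k, function(i) 1 / sum(1 / v[-i]), numeric(1))
  wstar <- 1 / (v + varhat)
  M <- t(A) %*% (wstar * A)
  B <- sqrt(v) * t(sqrt(v) * M)
  lam <- eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-10]
  ndraw <- 1e4
  Y <- matrix(rnorm(ndraw * k, 1.5, rep(sqrt(v), each = ndraw)), ndraw, k)
  U <- Y %*% t(A)
  vn_draws <- drop((U^2) %*% wstar)
  cdf <- ruben_cdf(lam, sort(vn_draws), tol = 1e-8)$value
  ks <- max(abs(seq_len(ndraw) / ndraw - cdf),
            abs((seq_len(ndraw) - 1) / ndraw - cdf))
  expect_lt(ks, 0.02)
})

test_that("Vn options expose the tau2 weighting variants", {
  d <- berkey_bcg()
  fit <- rema(y ~ 1, d)
  v_loo <- vn_test(fit)
  v_common <- vn_test(fit, tau2_weights = "common")
  # the statistic itself does not depend on the A-weight choice
  expect_equal(v_loo$statistic, v_common$statistic)
  # but the spectrum (hence p) shifts slightly
  expect_false(isTRUE(all.equal(v_loo$lambdas, v_common$lambdas)))
  v_marg <- vn_test(fit, denominator_tau2 = TRUE)
  expect_lt(v_marg$statistic, v_loo$statistic)
})

test_that("per-study table carries contributions that sum to Vn", {
  fit <- rema(y ~ lgtprev, leeflang_galactomannan())
  v <- vn_test(fit)
  expect_equal(nrow(v$per_study), 7)
  expect_equal(sum(v$per_study$contribution), v$statistic)
  expect_true(all(v$per_study$ci.lb < v$per_study$ci.ub))
})
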