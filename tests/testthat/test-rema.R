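test_that("REML estimate agrees with a dense grid-search oracle", {
  # 3-study toy set with a closed grid
  X <- matrix(1, 3, 1)
  y <- c(0, 1, 2); v <- c(1, 1, 1)
  fit <- rema(y ~ 1, data.frame(y = y), vi = v)
  expect_lte(abs(fit$tau2 - grid_reml_oracle(y, v, X)), 1e-4)

  # random 4-6 study datasets, intercept and one-covariate models
  set.seed(101)
  for (rep in 1:6) {
    k <- sample(4:6, 1)
    p_cov <- rep %% 2
    d <- random_dataset(k, p_cov, tau2 = 0.15)
    fml <- if (p_cov) y ~ x1 else y ~ 1
    fit <- rema(fml, d)
    X <- fit$X
    expect_lte(abs(fit$tau2 - grid_reml_oracle(d$y, d$vi, X)), 1e-4)
  }
})

test_that("REML matches the mainstream meta-analysis implementation", {
  skip_if_not_installed("metafor")
  b <- berkey_bcg()
  fit <- rema(y ~ 1, b)
  ref <- metafor::rma(yi = b$y, vi = b$vi, method = "REML")
  # the two optimisers use different stopping rules, so agreement is to
  # optimisation accuracy, not machine accuracy
  expect_equal(fit$tau2, ref$tau2, tolerance = 1e-4)
  expect_equal(unname(fit$beta), unname(as.numeric(ref$beta)),
               tolerance = 1e-4)
  expect_equal(unname(sqrt(diag(fit$vcov))), unname(ref$se),
               tolerance = 1e-4)

  fitmr <- rema(y ~ latitude, b)
  refmr <- metafor::rma(yi = b$y, vi = b$vi, mods = ~ b$latitude,
                        method = "REML")
  expect_equal(fitmr$tau2, refmr$tau2, tolerance = 2e-4)
  expect_equal(unname(fitmr$beta), unname(as.numeric(refmr$beta)),
               tolerance = 1e-4)
})

test_that("identical studies give tau2 = 0 and the common estimate", {
  d <- meta_dataset(y = rep(1.3, 5), vi = rep(0.2, 5))
  fit <- rema(y ~ 1, d)
  expect_equal(fit$tau2, 0, tolerance = 1e-10)
  expect_equal(unname(fit$beta), 1.3)
  expect_equal(i_squared(fit), 0)
})

test_that("fit validates design rank and minimum size", {
  d <- meta_dataset(y = c(0, 1, 2), vi = rep(1, 3),
                    moderators = data.frame(x = c(1, 2, 3)))
  expect_error(rema(y ~ x, d), "at least p \\+ 2")
  d2 <- meta_dataset(y = rnorm(6), vi = rep(1, 6),
                     moderators = data.frame(x = rep(2, 6)))
  expect_error(rema(y ~ x, d2), "rank deficient")
})

test_that("Cochran's Q is location invariant and zero for identical studies", {
  set.seed(7)
  d <- random_dataset(8)
  q1 <- cochran_q(rema(y ~ 1, d))
  d_shift <- d; d_shift$y <- d$y + 5
  q2 <- cochran_q(rema(y ~ 1, d_shift))
  expect_equal(q1$Q, q2$Q, tolerance = 1e-10)
  expect_equal(q1$df, 7)

  same <- meta_dataset(y = rep(0.4, 4), vi = rep(0.1, 4))
  expect_equal(cochran_q(rema(y ~ 1, same))$Q, 0, tolerance = 1e-12)
})

test_that("Q holds its nominal size under homogeneity with known variances", {
  set.seed(2024)
  reps <- 2000
  k <- 6
  v <- runif(k, 0.05, 0.3)
  rej <- 0
  for (r in seq_len(reps)) {
    y <- rnorm(k, 0.2, sqrt(v))
    w <- 1 / v
    Q <- sum(w * (y - sum(w * y) / sum(w))^2)
    rej <- rej + (pchisq(Q, k - 1, lower.tail = FALSE) < 0.05)
  }
  rate <- rej / reps
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("typical SE reduces to sqrt(v) for equal variances", {
  expect_equal(typical_se(rep(0.37, 9)), sqrt(0.37))
  expect_equal(typical_se(meta_dataset(y = 1:3, vi = rep(2, 3))), sqrt(2))
})

test_that("I-squared is zero at tau2 = 0 and increases with tau2", {
  s <- 0.4
  expect_equal(i_squared(0, s), 0)
  vals <- vapply(c(0.01, 0.1, 0.5, 2), i_squared, numeric(1), typical_se = s)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals <= 100))
})

test_that("prediction intervals degenerate without any variance", {
  d <- meta_dataset(y = rep(2, 5), vi = rep(1e-8, 5))
  fit <- rema(y ~ 1, d)
  pr <- predict(fit, interval = "prediction")[1, ]
  expect_equal(pr$lower, pr$upper, tolerance = 1e-3)
  expect_equal(pr$fit, 2, tolerance = 1e-6)
})

test_that("prediction widens confidence intervals by the between-study sd", {
  set.seed(11)
  d <- random_dataset(8, tau2 = 0.3)
  fit <- rema(y ~ 1, d)
  ci <- predict(fit, interval = "confidence")[1, ]
  pri <- predict(fit, interval = "prediction")[1, ]
  expect_lt(ci$upper - ci$lower, pri$upper - pri$lower)
  expect_equal(pri$upper - pri$lower,
               2 * qnorm(0.975) * sqrt(fit$tau2 + ci$se^2), tolerance = 1e-10)
})

test_that("residuals standardize by the marginal variance", {
  set.seed(3)
  d <- random_dataset(6, tau2 = 0.2)
  fit <- rema(y ~ 1, d)
  raw <- residuals(fit)
  std <- residuals(fit, type = "standardized")
  expect_equal(std, raw / sqrt(d$vi + fit$tau2))
  expect_equal(raw, d$y - fitted(fit))
})
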