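#' Simulate one primary study from patient-level observations
#'
#' Draws `n` patient-level observations from \eqn{N(\mu_i, \sigma^2)} and
#' summarises them the way a primary study would be reported: the effect
#' estimate is the sample mean, the patient-level variance is the unbiased
#' sample variance, and the sampling variance of the effect is
#' \eqn{\hat\sigma_i^2 / n}.
#'
#' @param mu_i True study mean.
#' @param sigma2 Patient-level variance.
#' @param n Patients per study (at least 2).
#' @return List with `y`, `vi`, `sigma2` (the estimate) and `n`.
#' @examples
#' set.seed(1); simulate_primary_study(0, 1, 50)
#' @export
simulate_primary_study <- function(mu_i, sigma2, n) {
  if (n < 2) stop("'n' must be at least 2")
  obs <- stats::rnorm(n, mu_i, sqrt(sigma2))
  s2 <- stats::var(obs)
  list(y = mean(obs), vi = s2 / n, sigma2 = s2, n = n)
}

# Vectorised version over k studies: one matrix of n x k observations.
.sim_studies <- function(mu, sigma2, n) {
  k <- length(mu)
  obs <- matrix(stats::rnorm(n * k, rep(mu, each = n), sqrt(sigma2)), n, k)
  y <- colMeans(obs)
  s2 <- (colSums(obs^2) - n * y^2) / (n - 1)
  list(y = y, vi = s2 / n)
}

#' Null-scenario true study means
#'
#' `make_null_ma()` draws a single common mean \eqn{\mu \sim N(0, 1)} and
#' repeats it for all k studies: the homogeneous null of the
#' meta-analysis model, i.e. the kernel of the Vn contrast matrix.
#' `make_null_mr()` draws study covariates \eqn{x_i \sim N(0,1)} and two
#' anchor means \eqn{\mu_{k-1}, \mu_k \sim N(0, \tau^2)}, then places all
#' remaining means exactly on the line through the two anchors, so the
#' true means lie in the (two-dimensional) kernel of the meta-regression
#' contrast matrix while the studies remain heterogeneous.
#'
#' @param k Number of studies (at least 3; at least 4 for the regression
#'   null).
#' @param tau2 Variance of the two anchor means in `make_null_mr()`.
#' @return `make_null_ma()`: numeric vector of k equal means.
#'   `make_null_mr()`: list with `mu` and covariate vector `x`.
#' @export
make_null_ma <- function(k) {
  if (k < 3) stop("'k' must be at least 3")
  rep(stats::rnorm(1), k)
}

#' @rdname make_null_ma
#' @export
make_null_mr <- function(k, tau2) {
  if (k < 4) stop("'k' must be at least 4 for the meta-regression null")
  repeat {
    x <- stats::rnorm(k)
    if (x[k] != x[k - 1]) break
  }
  anchors <- stats::rnorm(2, 0, sqrt(tau2))
  slope <- (anchors[2] - anchors[1]) / (x[k] - x[k - 1])
  list(mu = anchors[1] + slope * (x - x[k - 1]), x = x)
}

#' Alternative-scenario true study means
#'
#' Independent draws \eqn{\mu_i \sim N(0, \tau^2)}; with probability one
#' they fall outside the null kernel, so heterogeneity (and, for the
#' regression model, departure from any covariate line) is present.
#'
#' @param k Number of studies.
#' @param tau2 Positive between-study variance.
#' @return Numeric vector of k means.
#' @export
make_alternative <- function(k, tau2) {
  if (tau2 <= 0) stop("'tau2' must be positive under the alternative")
  mu <- stats::rnorm(k, 0, sqrt(tau2))
  while (stats::sd(mu) == 0) mu <- stats::rnorm(k, 0, sqrt(tau2))
  mu
}

#' Define a simulation scenario
#'
#' One cell of the factorial design over between-study variance
#' \eqn{\tau^2} (grid 0, 0.05, 0.1, 0.25, 0.5), patient-level variance
#' \eqn{\sigma^2} (0.0001, 0.01, 0.1, 1), per-study sample size n (50 to
#' 1000) and number of studies k (5, 10, 25, 50), for either the
#' meta-analysis model (`"ma"`) or the one-covariate meta-regression
#' (`"mr1"`), under the null (means in the kernel) or the alternative.
#'
#' @param tau2,sigma2,n,k Generative parameters (see Details).
#' @param model `"ma"` or `"mr1"`.
#' @param hypothesis `"null"` or `"alternative"`.
#' @param reps Replications per cell (default 4000; the reference design
#'   used 40000).
#' @param alpha Rejection threshold for both tests.
#' @return A list of class `"sim_scenario"`.
#' @examples
#' sim_scenario(tau2 = 0, sigma2 = 0.1, n = 1000, k = 5)
#' @export
sim_scenario <- function(tau2 = 0, sigma2 = 0.1, n = 100, k = 5,
                         model = c("ma", "mr1"),
                         hypothesis = c("null", "alternative"),
                         reps = 4000, alpha = 0.05) {
  model <- match.arg(model)
  hypothesis <- match.arg(hypothesis)
  stopifnot(tau2 >= 0, sigma2 > 0, n >= 2, k >= 3, reps >= 100,
            alpha > 0, alpha < 1)
  if (hypothesis == "alternative" && tau2 <= 0)
    stop("the alternative requires tau2 > 0")
  structure(list(tau2 = tau2, sigma2 = sigma2, n = as.integer(n),
                 k = as.integer(k), model = model, hypothesis = hypothesis,
                 reps = as.integer(reps), alpha = alpha),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("Scenario: %s/%s  tau2=%g sigma2=%g n=%d k=%d reps=%d alpha=%g\n",
              x$model, x$hypothesis, x$tau2, x$sigma2, x$n, x$k, x$reps,
              x$alpha))
  invisible(x)
}

#' Run one simulation cell
#'
#' For each replication: draw the true study means for the scenario's
#' model and hypothesis, simulate patient-level data and summarise each
#' study, fit the random-effects model by REML, compute the Vn p-value
#' (leave-one-out refits, eigenvalue spectrum, Ruben series) and the Q
#' p-value (\eqn{\chi^2_{k-p}}), and record rejections at `alpha`.
#' Replications where a fit fails are dropped and counted; a warning is
#' issued if they exceed 1% of `reps`.
#'
#' @param scenario A [sim_scenario()].
#' @param seed Integer seed; the cell is deterministic given the seed.
#' @return An object of class `"sim_result"`: list with the scenario,
#'   `reject_rate_vn`, `reject_rate_q`, `mc_se` (binomial Monte-Carlo
#'   standard errors), `tau_over_se` (\eqn{\tau / (\sigma/\sqrt n)}),
#'   `n_failed`, `reps_used`.
#' @examples
#' \donttest{
#' run_sim_cell(sim_scenario(tau2 = 0, n = 1000, k = 5, reps = 500), seed = 1)
#' }
#' @export
run_sim_cell <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(seed)
  s <- scenario
  rej_vn <- rej_q <- 0L
  failed <- 0L
  p <- if (s$model == "ma") 1L else 2L
  for (r in seq_len(s$reps)) {
    if (s$model == "ma") {
      mu <- if (s$hypothesis == "null") make_null_ma(s$k)
            else make_alternative(s$k, s$tau2)
      X <- matrix(1, s$k, 1L)
    } else {
      if (s$hypothesis == "null") {
        nm <- make_null_mr(s$k, s$tau2)
        mu <- nm$mu; x <- nm$x
      } else {
        mu <- make_alternative(s$k, s$tau2)
        x <- stats::rnorm(s$k)
      }
      X <- cbind(1, x)
    }
    dat <- .sim_studies(mu, s$sigma2, s$n)
    res <- tryCatch({
      w <- 1 / dat$vi
      b <- solve(t(X * w) %*% X, t(X * w) %*% dat$y)
      Q <- sum(w * drop(dat$y - X %*% b)^2)
      pq <- stats::pchisq(Q, s$k - p, lower.tail = FALSE)
      loo <- .loo_fits(dat$y, dat$vi, X)
      vn <- sum((dat$y - loo$yhat)^2 / (dat$vi + loo$varhat))
      A <- .vn_A_matrix(dat$vi, X, loo$tau2)
      Msym <- t(A) %*% ((1 / (dat$vi + loo$varhat)) * A)
      siw <- sqrt(dat$vi)
      B <- siw * t(siw * Msym)
      lam <- eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values
      lam <- lam[lam > 1e-10 * max(lam)]
      pv <- .quadform_tail(lam, vn, tol = 1e-6)$p
      c(pv < s$alpha, pq < s$alpha)
    }, error = function(e) NULL)
    if (is.null(res)) failed <- failed + 1L
    else { rej_vn <- rej_vn + res[1]; rej_q <- rej_q + res[2] }
  }
  used <- s$reps - failed
  if (failed > 0.01 * s$reps)
    warning(sprintf("%d of %d replications failed", failed, s$reps))
  rv <- rej_vn / used
  rq <- rej_q / used
  structure(list(scenario = s, seed = seed,
                 reject_rate_vn = rv, reject_rate_q = rq,
                 mc_se = c(vn = sqrt(rv * (1 - rv) / used),
                           q = sqrt(rq * (1 - rq) / used)),
                 tau_over_se = sqrt(s$tau2) / (sqrt(s$sigma2) / sqrt(s$n)),
                 n_failed = failed, reps_used = used),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  print(x$scenario)
  cat(sprintf("reject Vn = %.4f (MC SE %.4f)   reject Q = %.4f (MC SE %.4f)\n",
              x$reject_rate_vn, x$mc_se["vn"], x$reject_rate_q, x$mc_se["q"]))
  cat(sprintf("tau/se = %.3f   replications used = %d (failed %d)\n",
              x$tau_over_se, x$reps_used, x$n_failed))
  invisible(x)
}

# Deterministic per-cell seed from the master seed and the cell's own
# parameters (not its position), so grids are order-independent.
.cell_seed <- function(master, scenario) {
  s <- scenario
  key <- sprintf("%s|%s|%.10g|%.10g|%d|%d|%d|%.10g",
                 s$model, s$hypothesis, s$tau2, s$sigma2, s$n, s$k,
                 s$reps, s$alpha)
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483629
  as.integer((h + as.numeric(master)) %% 2147483629 + 1)
}

#' Run a grid of simulation scenarios
#'
#' Runs [run_sim_cell()] for every scenario, with per-cell seeds derived
#' deterministically from the master seed and the cell's parameters, so
#' the same grid gives the same table regardless of cell order.
#'
#' @param scenarios List of [sim_scenario()] objects.
#' @param seed Master seed.
#' @return A data frame with one row per cell (parameters, rejection
#'   rates, Monte-Carlo SEs, tau/se, failures).
#' @export
run_sim_grid <- function(scenarios, seed = 1L) {
  if (inherits(scenarios, "sim_scenario")) scenarios <- list(scenarios)
  rows <- lapply(scenarios, function(sc) {
    r <- run_sim_cell(sc, seed = .cell_seed(seed, sc))
    data.frame(model = sc$model, hypothesis = sc$hypothesis,
               tau2 = sc$tau2, sigma2 = sc$sigma2, n = sc$n, k = sc$k,
               reps = sc$reps, alpha = sc$alpha,
               tau_over_se = r$tau_over_se,
               reject_vn = r$reject_rate_vn, reject_q = r$reject_rate_q,
               mc_se_vn = r$mc_se[["vn"]], mc_se_q = r$mc_se[["q"]],
               n_failed = r$n_failed)
  })
  do.call(rbind, rows)
}
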