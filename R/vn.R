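#' Leave-one-out summary estimates
#'
#' Refits the random-effects model by REML with each study omitted in
#' turn and evaluates the summary (or tailored) estimate at the omitted
#' study's covariates, together with its model variance
#' \eqn{x_i^T \mathrm{cov}(\hat\beta_{-i}) x_i}. These are the
#' cross-validated predictions that the Vn validity statistic compares
#' with the observed study effects.
#'
#' @param object A fitted [rema()] model.
#' @param level Confidence level for the reported interval.
#' @return A data frame of class `"loo_estimates"` with one row per
#'   study: observed `y` and its CI, leave-one-out `estimate`, `se`
#'   (model SE), CI, and `tau2_loo` (the REML between-study variance of
#'   that leave-one-out fit).
#' @examples
#' loo_estimates(rema(y ~ 1, berkey_bcg()))
#' @export
loo_estimates <- function(object, level = NULL) {
  stopifnot(inherits(object, "rema"))
  level <- level %||% object$level
  loo <- .loo_fits(object$y, object$vi, object$X)
  z <- stats::qnorm((1 + level) / 2)
  out <- data.frame(label = object$labels,
                    y = object$y,
                    y.lb = object$y - z * sqrt(object$vi),
                    y.ub = object$y + z * sqrt(object$vi),
                    estimate = loo$yhat,
                    se = sqrt(loo$varhat),
                    ci.lb = loo$yhat - z * sqrt(loo$varhat),
                    ci.ub = loo$yhat + z * sqrt(loo$varhat),
                    tau2_loo = loo$tau2,
                    stringsAsFactors = FALSE)
  class(out) <- c("loo_estimates", "data.frame")
  out
}

# One REML refit per omitted study, on raw vectors for speed.
# Returns the LOO predictions and everything needed for the A matrix.
.loo_fits <- function(y, v, X, tol = 1e-8, maxit = 100L) {
  k <- length(y)
  yhat <- varhat <- tau2 <- numeric(k)
  conv <- logical(k)
  for (i in seq_len(k)) {
    f <- .reml_fit(y[-i], v[-i], X[-i, , drop = FALSE], tol = tol,
                   maxit = maxit)
    x0 <- X[i, ]
    yhat[i] <- sum(x0 * f$beta)
    varhat[i] <- drop(t(x0) %*% f$vcov %*% x0)
    tau2[i] <- f$tau2
    conv[i] <- f$converged
  }
  list(yhat = yhat, varhat = varhat, tau2 = tau2, converged = conv)
}

# The k x k contrast matrix behind Vn: row i is e_i - h_i, where h_i is
# the weighted-least-squares hat row mapping (y_j)_{j != i} to the
# leave-one-out prediction at x_i, with weights 1/(v_j + tau2_loo[i]).
# Unit diagonal by construction; rows sum to zero for intercept models.
.vn_A_matrix <- function(v, X, tau2_loo) {
  k <- length(v)
  A <- diag(k)
  for (i in seq_len(k)) {
    w <- 1 / (v + tau2_loo[i])
    w[i] <- 0
    M <- t(X * w) %*% X
    if (!is.finite(rcond(M)) || rcond(M) < 1e-14)
      stop("singular leave-one-out design when omitting study ", i)
    h <- drop(X[i, ] %*% solve(M, t(X * w)))
    A[i, -i] <- -h[-i]
  }
  A
}

#' Statistical-validity test of a summary meta-analysis estimate
#'
#' Tests whether the summary estimate of a random-effects meta-analysis
#' (or the tailored estimate of a meta-regression) is statistically valid
#' for a new independent setting, i.e. whether the parameter predicted
#' for each omitted study equals that study's true effect. The test
#' statistic is the leave-one-out cross-validation sum
#' \deqn{V_n = \sum_{i=1}^k \frac{(y_i - \hat y_{-i})^2}
#'       {v_i + \mathrm{var}(\hat y_{-i})},}
#' a quadratic form \eqn{y^T A^T W^* A y} in the study effects. Under the
#' null hypothesis (and known variances) its distribution is the weighted
#' sum \eqn{\sum_i \lambda_i \chi^2_1} where the \eqn{\lambda_i} are the
#' eigenvalues of \eqn{B = W^{-1/2} A^T W^* A W^{-1/2}} with
#' \eqn{W = \mathrm{diag}(1/v_i)}; k - p of them are non-zero. The
#' p-value is computed by [ruben_cdf()] with certified truncation error
#' (characteristic-function inversion as fallback).
#'
#' The leave-one-out between-study variances \eqn{\hat\tau^2_{-i}} are
#' plugged into the weights of `A` and treated as known; set
#' `tau2_weights = "common"` to use the full-data \eqn{\hat\tau^2} in
#' every row instead. The denominator uses the within-study sampling
#' variance only (the null is homogeneity, where the marginal variance is
#' the sampling variance); `denominator_tau2 = TRUE` adds the full-data
#' \eqn{\hat\tau^2}.
#'
#' @param object A fitted [rema()] model.
#' @param tol Truncation error target for the p-value series.
#' @param tau2_weights `"loo"` (default) or `"common"`; which
#'   between-study variance enters the weights defining `A`.
#' @param denominator_tau2 Add the between-study variance to the
#'   denominators of Vn (default `FALSE`).
#' @return An object of class `"vn_test"`: list with `statistic`,
#'   `p.value`, `p.error_bound`, `p.method`, `lambdas`, `A`, `B`,
#'   `w_star`, `per_study` (the [loo_estimates()] table with per-study
#'   contributions), `k`, `p`.
#' @examples
#' fit <- rema(y ~ 1, berkey_bcg())
#' vn_test(fit)
#' @export
vn_test <- function(object, tol = 1e-6,
                    tau2_weights = c("loo", "common"),
                    denominator_tau2 = FALSE) {
  stopifnot(inherits(object, "rema"))
  tau2_weights <- match.arg(tau2_weights)
  y <- object$y; v <- object$vi; X <- object$X
  k <- object$k; p <- object$p
  loo <- .loo_fits(y, v, X)
  if (!all(loo$converged))
    warning("leave-one-out REML fit(s) did not converge for study index: ",
            paste(which(!loo$converged), collapse = ", "))
  denom <- v + loo$varhat + if (denominator_tau2) object$tau2 else 0
  w_star <- 1 / denom
  contrib <- (y - loo$yhat)^2 * w_star
  vn <- sum(contrib)
  tau2A <- if (tau2_weights == "loo") loo$tau2 else rep(object$tau2, k)
  A <- .vn_A_matrix(v, X, tau2A)
  M <- t(A) %*% (w_star * A)           # A^T W* A  (symmetric)
  siw <- sqrt(v)                       # W^{-1/2} diagonal, W = diag(1/v)
  B <- siw * t(siw * M)                # W^{-1/2} A^T W* A W^{-1/2}
  B <- (B + t(B)) / 2
  lam <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-10 * max(lam)]
  pv <- .quadform_tail(lam, vn, tol = tol)
  per_study <- loo_estimates(object)
  per_study$contribution <- contrib
  structure(list(statistic = vn, p.value = unname(pv$p),
                 p.error_bound = pv$error_bound, p.method = pv$method,
                 lambdas = lam, A = A, B = B, w_star = w_star,
                 per_study = per_study, k = k, p = p,
                 tau2_weights = tau2_weights,
                 model = if (p == 1L) "meta-analysis" else "meta-regression"),
            class = "vn_test")
}

#' @export
print.vn_test <- function(x, digits = 4, ...) {
  cat(sprintf("Leave-one-out validity test (%s, k = %d)\n", x$model, x$k))
  cat(sprintf("Vn = %.*f,  p = %s  (null: sum of %d weighted chi-square(1))\n",
              2, x$statistic,
              format.pval(x$p.value, digits = digits, eps = 1e-16),
              length(x$lambdas)))
  if (x$p.method != "ruben")
    cat("p-value computed by characteristic-function inversion fallback\n")
  cat(sprintf("truncation error bound: %.2g\n", x$p.error_bound))
  invisible(x)
}
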