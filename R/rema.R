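#' Fit a random-effects meta-analysis or meta-regression by REML
#'
#' Fits the study-level random-effects model
#' \deqn{y_i = X_i \beta + \delta_i + \varepsilon_i, \qquad
#'       \delta_i \sim N(0, \tau^2), \ \varepsilon_i \sim N(0, v_i),}
#' where the within-study sampling variances \eqn{v_i} are treated as
#' known. With an intercept-only formula this is the univariate
#' random-effects meta-analysis (the summary effect \eqn{\mu} is the
#' single coefficient); with moderators it is a meta-regression whose
#' fitted value at a setting's covariates is the "tailored" summary
#' estimate for that setting.
#'
#' The between-study variance \eqn{\tau^2} is estimated by restricted
#' maximum likelihood: Fisher scoring on the profiled restricted
#' log-likelihood with step-halving, non-negativity enforced by projecting
#' negative updates to zero, convergence when the change in \eqn{\tau^2}
#' falls below `tol`. \eqn{\hat\beta} is the weighted least-squares
#' solution with weights \eqn{1/(v_i + \hat\tau^2)} and coefficient
#' covariance \eqn{(X^T W X)^{-1}}.
#'
#' @param formula Model formula for the effect estimates, e.g. `y ~ 1`
#'   (meta-analysis) or `y ~ latitude` (meta-regression).
#' @param data A [meta_dataset()] or data frame holding the variables.
#' @param vi Sampling variances: a bare column name (default `vi`) or a
#'   numeric vector.
#' @param level Confidence level used by `summary()` and `predict()`.
#' @param control List overriding `tol` (default 1e-8), `maxit` (100).
#' @return An object of class `"rema"` with components `beta`, `tau2`,
#'   `vcov`, `k`, `p`, `iterations`, `converged`, and the model frame
#'   pieces needed by downstream methods.
#' @examples
#' fit <- rema(y ~ 1, berkey_bcg())
#' summary(fit)
#' rema(y ~ latitude, berkey_bcg())
#' @seealso [vn_test()], [heterogeneity()], [predict.rema()]
#' @export
rema <- function(formula, data, vi = NULL, level = 0.95, control = list()) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data = as.data.frame(data))
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  vi <- eval(cl$vi, as.data.frame(data), parent.frame())
  if (is.null(vi)) {
    if (!"vi" %in% names(data)) stop("no 'vi' column and no 'vi' argument")
    vi <- data[["vi"]]
  }
  vi <- as.numeric(vi)
  k <- length(y); p <- ncol(X)
  if (length(vi) != k || any(vi <= 0)) stop("'vi' must be positive, length k")
  if (k < p + 2L)
    stop(sprintf("need at least p + 2 = %d studies, got %d", p + 2L, k))
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  ctrl <- utils::modifyList(list(tol = 1e-8, maxit = 100L), control)
  fit <- .reml_fit(y, vi, X, tol = ctrl$tol, maxit = ctrl$maxit)
  if (!fit$converged)
    warning("REML did not converge in ", ctrl$maxit, " iterations")
  labels <- if (!is.null(data$label)) as.character(data$label)
            else paste("study", seq_len(k))
  structure(c(fit, list(y = y, vi = vi, X = X, k = k, p = p,
                        labels = labels, formula = formula, level = level,
                        effect_scale = attr(data, "effect_scale") %||% "generic",
                        call = cl)),
            class = "rema")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Restricted log-likelihood of the random-effects model, profiled in tau2.
.restricted_ll <- function(tau2, y, v, X) {
  w <- 1 / (v + tau2)
  XtW <- t(X * w)
  M <- XtW %*% X
  b <- solve(M, XtW %*% y)
  r <- drop(y - X %*% b)
  -0.5 * (sum(log(v + tau2)) + determinant(M, logarithm = TRUE)$modulus[1] +
            sum(w * r^2)) - 0.5 * (length(y) - ncol(X)) * log(2 * pi)
}

# Core REML engine on raw vectors; Fisher scoring with step-halving and
# projection to tau2 >= 0, with a golden-section fallback on breakdown.
.reml_fit <- function(y, v, X, tol = 1e-8, maxit = 100L) {
  k <- length(y); p <- ncol(X)
  tau2 <- max(0, stats::var(y) - mean(v))
  ll <- .restricted_ll(tau2, y, v, X)
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    w <- 1 / (v + tau2)
    wX <- X * w
    Minv <- solve(t(wX) %*% X)
    P <- diag(w, k) - wX %*% Minv %*% t(wX)
    Py <- drop(P %*% y)
    score <- -0.5 * (sum(diag(P)) - sum(Py^2))
    info <- 0.5 * sum(P * P)
    if (!is.finite(score) || !is.finite(info) || info <= 0) break
    step <- score / info
    cand <- max(0, tau2 + step)
    llc <- .restricted_ll(cand, y, v, X)
    h <- 1
    while ((!is.finite(llc) || llc < ll - 1e-12) && h > 1e-10) {
      h <- h / 2
      cand <- max(0, tau2 + h * step)
      llc <- .restricted_ll(cand, y, v, X)
    }
    if (abs(cand - tau2) < tol) {
      tau2 <- cand
      converged <- TRUE
      break
    }
    tau2 <- cand; ll <- llc
  }
  if (!converged && it >= 1L && !is.finite(ll)) {
    # degenerate scoring path: fall back to direct 1-d optimisation
    upper <- max(stats::var(y) * 10, mean(v) * 10, 1)
    opt <- stats::optimize(function(t2) .restricted_ll(t2, y, v, X),
                           c(0, upper), maximum = TRUE, tol = tol)
    tau2 <- opt$maximum
    if (.restricted_ll(0, y, v, X) >= opt$objective) tau2 <- 0
    converged <- TRUE
  }
  w <- 1 / (v + tau2)
  wX <- X * w
  Minv <- solve(t(wX) %*% X)
  beta <- drop(Minv %*% t(wX) %*% y)
  names(beta) <- colnames(X)
  vc <- (Minv + t(Minv)) / 2
  dimnames(vc) <- list(colnames(X), colnames(X))
  list(beta = beta, tau2 = tau2, vcov = vc, iterations = it,
       converged = converged)
}

#' @export
print.rema <- function(x, digits = 4, ...) {
  cat(sprintf("Random-effects %s (REML): k = %d studies\n",
              if (x$p == 1L) "meta-analysis" else "meta-regression", x$k))
  cat("Coefficients:\n")
  print(round(x$beta, digits))
  cat(sprintf("tau^2 = %.*f (tau = %.*f), %d iteration(s)%s\n", digits,
              x$tau2, digits, sqrt(x$tau2), x$iterations,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.rema <- function(object, ...) object$beta

#' @export
vcov.rema <- function(object, ...) object$vcov

#' @export
fitted.rema <- function(object, ...) drop(object$X %*% object$beta)

#' @export
#' @rdname rema
#' @param object,x A fitted `"rema"` object.
#' @param type For `residuals`: `"response"` (raw) or `"standardized"`
#'   (divided by \eqn{\sqrt{v_i + \hat\tau^2}}).
#' @param ... Passed on or ignored.
residuals.rema <- function(object, type = c("response", "standardized"), ...) {
  type <- match.arg(type)
  r <- object$y - fitted(object)
  if (type == "standardized") r <- r / sqrt(object$vi + object$tau2)
  r
}

#' @export
logLik.rema <- function(object, ...) {
  ll <- .restricted_ll(object$tau2, object$y, object$vi, object$X)
  structure(ll, df = object$p + 1, class = "logLik")
}

#' Predictions, confidence intervals and prediction intervals
#'
#' For a meta-analysis the fitted value is the summary effect; for a
#' meta-regression it is the tailored summary estimate at the covariates
#' in `newdata`. `interval = "confidence"` gives normal-theory intervals
#' on the summary estimate; `interval = "prediction"` widens them by the
#' between-study variance, \eqn{\pm z \sqrt{\hat\tau^2 + x_0^T
#' \mathrm{cov}(\hat\beta) x_0}}, the interval expected to contain the
#' true effect in a new study or setting.
#'
#' @param object A fitted [rema()] model.
#' @param newdata Data frame of moderator values (omit for the fitted
#'   studies; a meta-analysis needs none).
#' @param interval `"none"`, `"confidence"` or `"prediction"`.
#' @param level Coverage; defaults to the level stored in the fit.
#' @return A data frame with columns `fit`, `se`, and (with an interval)
#'   `lower`, `upper`.
#' @examples
#' fit <- rema(y ~ 1, berkey_bcg())
#' predict(fit, interval = "prediction")
#' @export
predict.rema <- function(object, newdata = NULL,
                         interval = c("none", "confidence", "prediction"),
                         level = NULL, ...) {
  interval <- match.arg(interval)
  level <- level %||% object$level
  if (is.null(newdata)) {
    X0 <- if (object$p == 1L) object$X[1, , drop = FALSE] else object$X
  } else {
    tt <- stats::delete.response(stats::terms(object$formula))
    X0 <- stats::model.matrix(tt, stats::model.frame(tt, as.data.frame(newdata)))
  }
  est <- drop(X0 %*% object$beta)
  se_fit <- sqrt(rowSums((X0 %*% object$vcov) * X0))
  out <- data.frame(fit = est, se = se_fit)
  if (interval != "none") {
    z <- stats::qnorm((1 + level) / 2)
    s <- if (interval == "prediction") sqrt(object$tau2 + se_fit^2) else se_fit
    out$lower <- est - z * s
    out$upper <- est + z * s
  }
  rownames(out) <- NULL
  out
}

#' Classical heterogeneity summary of a fitted model
#'
#' Computes Cochran's Q (the inverse-variance weighted residual sum of
#' squares about the fixed-effect fit, referred to \eqn{\chi^2_{k-p}}),
#' the I-squared percentage \eqn{100\,\hat\tau^2 / (\hat\tau^2 + s^2)}
#' with \eqn{s^2} the Higgins-Thompson typical sampling variance, the
#' typical standard error \eqn{\bar{se}}, and the heterogeneity ratio
#' \eqn{\hat\tau / \bar{se}} which (together with k) indexes the power of
#' the Vn validity test.
#'
#' @param object A fitted [rema()] model.
#' @return An object of class `"heterogeneity"`: list with `Q`, `df`,
#'   `p_value`, `I2`, `typical_se`, `tau`, `ratio`.
#' @examples
#' heterogeneity(rema(y ~ 1, berkey_bcg()))
#' @export
heterogeneity <- function(object) {
  stopifnot(inherits(object, "rema"))
  q <- cochran_q(object)
  se_t <- typical_se(object$vi)
  i2 <- i_squared(object$tau2, se_t)
  structure(list(Q = q$Q, df = q$df, p_value = q$p_value, I2 = i2,
                 typical_se = se_t, tau = sqrt(object$tau2),
                 ratio = sqrt(object$tau2) / se_t),
            class = "heterogeneity")
}

#' @export
print.heterogeneity <- function(x, digits = 4, ...) {
  cat(sprintf("Q = %.*f (df = %d, p = %.4g)\n", 2, x$Q, x$df, x$p_value))
  cat(sprintf("I^2 = %.1f%%   typical SE = %.*f   tau = %.*f   tau/SE = %.*f\n",
              x$I2, digits, x$typical_se, digits, x$tau, digits, x$ratio))
  invisible(x)
}

#' Cochran's Q statistic
#'
#' Weighted residual sum of squares about the fixed-effect (tau^2 = 0)
#' weighted least-squares fit, with weights \eqn{1/v_i}; under homogeneity
#' and known variances it is \eqn{\chi^2} with k - p degrees of freedom.
#'
#' @param object A fitted [rema()] model.
#' @return List with `Q`, `df` and `p_value`.
#' @export
cochran_q <- function(object) {
  stopifnot(inherits(object, "rema"))
  y <- object$y; v <- object$vi; X <- object$X
  w <- 1 / v
  b <- solve(t(X * w) %*% X, t(X * w) %*% y)
  Q <- sum(w * drop(y - X %*% b)^2)
  df <- object$k - object$p
  list(Q = Q, df = df, p_value = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Higgins-Thompson typical standard error
#'
#' The "typical" within-study standard error
#' \deqn{\bar{se} = \left[\frac{(k-1)\sum w_i}{(\sum w_i)^2 - \sum w_i^2}
#'   \right]^{1/2}, \qquad w_i = 1/v_i,}
#' the scale against which the between-study standard deviation is judged.
#' When all variances are equal it reduces to \eqn{\sqrt{v}}.
#'
#' @param vi Positive sampling variances (or a [meta_dataset()]).
#' @return The typical standard error.
#' @examples
#' typical_se(berkey_bcg())
#' @export
typical_se <- function(vi) {
  if (inherits(vi, "meta_dataset")) vi <- vi$vi
  if (any(vi <= 0)) stop("'vi' must be positive")
  w <- 1 / vi
  k <- length(w)
  sqrt((k - 1) * sum(w) / (sum(w)^2 - sum(w^2)))
}

#' I-squared from the between-study variance
#'
#' \eqn{I^2 = 100\,\hat\tau^2 / (\hat\tau^2 + s^2)} with \eqn{s^2} the
#' square of the [typical_se()]; the percentage of total variability
#' attributed to between-study heterogeneity.
#'
#' @param tau2 Non-negative between-study variance (or a `"rema"` fit).
#' @param typical_se Typical standard error; ignored when `tau2` is a fit.
#' @return I-squared, in percent, clipped to \[0, 100\].
#' @export
i_squared <- function(tau2, typical_se = NULL) {
  if (inherits(tau2, "rema")) {
    typical_se <- typical_se(tau2$vi)
    tau2 <- tau2$tau2
  }
  min(100, max(0, 100 * tau2 / (tau2 + typical_se^2)))
}

#' Heterogeneity ratio tau / typical SE
#'
#' The ratio of the estimated between-study standard deviation to the
#' typical within-study standard error; the power of both Vn and Q grows
#' with this ratio at a fixed number of studies.
#'
#' @param object A fitted [rema()] model.
#' @return Non-negative scalar.
#' @export
heterogeneity_ratio <- function(object) {
  stopifnot(inherits(object, "rema"))
  sqrt(object$tau2) / typical_se(object$vi)
}

#' @export
summary.rema <- function(object, x0 = NULL, ...) {
  het <- heterogeneity(object)
  pi_tab <- NULL
  if (object$p == 1L) {
    pi_tab <- predict.rema(object, newdata = NULL,
                           interval = "prediction")[1, ]
  } else if (!is.null(x0)) {
    pi_tab <- predict.rema(object, newdata = x0, interval = "prediction")
  }
  z <- stats::qnorm((1 + object$level) / 2)
  ct <- data.frame(estimate = object$beta,
                   se = sqrt(diag(object$vcov)))
  ct$zval <- ct$estimate / ct$se
  ct$pval <- 2 * stats::pnorm(-abs(ct$zval))
  ct$ci.lb <- ct$estimate - z * ct$se
  ct$ci.ub <- ct$estimate + z * ct$se
  structure(list(fit = object, coefficients = ct, heterogeneity = het,
                 prediction = pi_tab, level = object$level),
            class = "summary.rema")
}

#' @export
print.summary.rema <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nCoefficient table:\n")
  print(round(as.matrix(x$coefficients), digits))
  cat("\nHeterogeneity:\n")
  print(x$heterogeneity, digits = digits)
  if (!is.null(x$prediction)) {
    cat(sprintf("\n%.0f%% prediction interval: (%.2f, %.2f)\n",
                100 * x$level, x$prediction$lower, x$prediction$upper))
  }
  invisible(x)
}
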