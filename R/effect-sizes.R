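#' Log relative risk and its sampling variance from a 2x2 table
#'
#' Computes the log relative risk for a treated/control 2x2 table together
#' with its large-sample sampling variance
#' \deqn{v = 1/tp + 1/cp - 1/(tp + tn) - 1/(cp + cn).}
#' A continuity correction is added to every cell if (and only if) any cell
#' is zero, so that tables free of zeros are left untouched.
#'
#' @param tp,tn Event-positive and event-negative counts in the treated arm.
#' @param cp,cn Event-positive and event-negative counts in the control arm.
#' @param continuity Non-negative constant added to all four cells when any
#'   cell is zero. Default 0.5.
#' @return A list with components `y` (log relative risk), `v` (sampling
#'   variance) and `corrected` (logical, whether the correction was applied).
#' @examples
#' effect_log_rr(5, 95, 10, 90)
#' effect_log_rr(0, 50, 5, 45)  # continuity correction rescues the zero cell
#' @export
effect_log_rr <- function(tp, tn, cp, cn, continuity = 0.5) {
  counts <- c(tp = tp, tn = tn, cp = cp, cn = cn)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (continuity < 0) stop("'continuity' must be non-negative")
  corrected <- any(counts == 0)
  if (corrected) counts <- counts + continuity
  tp <- counts[["tp"]]; tn <- counts[["tn"]]
  cp <- counts[["cp"]]; cn <- counts[["cn"]]
  if (tp <= 0 || cp <= 0 || tp + tn <= 0 || cp + cn <= 0)
    stop("zero margin after continuity correction; cannot form log RR")
  y <- log((tp / (tp + tn)) / (cp / (cp + cn)))
  v <- 1 / tp + 1 / cp - 1 / (tp + tn) - 1 / (cp + cn)
  list(y = y, v = v, corrected = corrected)
}

#' Logit positive predictive value and its sampling variance
#'
#' Computes logit(PPV) from true-positive and false-positive counts with
#' sampling variance \eqn{1 / [(tp + fp) \cdot PPV (1 - PPV)]}. A continuity
#' correction is added to both cells if either is zero.
#'
#' @param tp,fp True-positive and false-positive counts.
#' @param continuity Non-negative constant added to both cells when either
#'   is zero. Default 0.5.
#' @return A list with components `y` (logit PPV), `v` (sampling variance)
#'   and `corrected`.
#' @examples
#' effect_logit_ppv(30, 10)
#' @export
effect_logit_ppv <- function(tp, fp, continuity = 0.5) {
  if (any(!is.finite(c(tp, fp))) || tp < 0 || fp < 0)
    stop("counts must be finite and non-negative")
  if (continuity < 0) stop("'continuity' must be non-negative")
  corrected <- tp == 0 || fp == 0
  if (corrected) { tp <- tp + continuity; fp <- fp + continuity }
  m <- tp + fp
  if (m <= 0) stop("tp + fp must be positive")
  ppv <- tp / m
  if (ppv <= 0 || ppv >= 1)
    stop("PPV of 0 or 1; supply a positive continuity correction")
  list(y = log(ppv / (1 - ppv)), v = 1 / (m * ppv * (1 - ppv)),
       corrected = corrected)
}

#' Sampling variance reconstructed from a reported confidence interval
#'
#' Inverts a symmetric normal-theory confidence interval to the implied
#' sampling variance, \eqn{[(upper - lower) / (2 z_{(1+level)/2})]^2}.
#' The full-precision normal quantile is used (1.959964 at the 95% level,
#' not 1.96), although statistics recovered from intervals printed to two
#' decimals are only reproducible to rounding accuracy.
#'
#' @param lower,upper Confidence limits (vectorised).
#' @param level Coverage of the interval, in (0, 1). Default 0.95.
#' @return Sampling variance(s).
#' @examples
#' variance_from_ci(-1.96, 1.96)          # ~1
#' variance_from_ci(-2.55, -0.70)         # ~0.223
#' @export
variance_from_ci <- function(lower, upper, level = 0.95) {
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)")
  if (any(upper <= lower)) stop("'upper' must exceed 'lower'")
  z <- stats::qnorm((1 + level) / 2)
  ((upper - lower) / (2 * z))^2
}
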