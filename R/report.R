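#' Full validation report for a study-level dataset
#'
#' Convenience wrapper running the whole pipeline: REML fit, leave-one-out
#' estimates, the Vn validity test, the heterogeneity summary, and a
#' prediction interval (at the covariates `x0` for a meta-regression).
#' The report mirrors the per-study table and summary block a reviewer
#' would publish.
#'
#' @param data A [meta_dataset()] (or data frame with `y` and `vi`).
#' @param moderators Character vector of moderator column names (empty
#'   for a plain meta-analysis).
#' @param x0 Optional one-row data frame of moderator values at which the
#'   tailored prediction interval is evaluated.
#' @param level Confidence/prediction level.
#' @param ... Passed to [vn_test()].
#' @return An object of class `"validation_report"`: list with `fit`,
#'   `vn`, `heterogeneity`, `per_study`, `prediction`, `config`.
#' @examples
#' validation_report(berkey_bcg())
#' validation_report(berkey_bcg(), moderators = "latitude",
#'                   x0 = data.frame(latitude = 45))
#' @export
validation_report <- function(data, moderators = character(0), x0 = NULL,
                              level = 0.95, ...) {
  fml <- if (length(moderators))
    stats::reformulate(moderators, response = "y") else y ~ 1
  fit <- rema(fml, data, level = level)
  vn <- vn_test(fit, ...)
  het <- heterogeneity(fit)
  pred <- if (fit$p == 1L)
    predict(fit, interval = "prediction", level = level)[1, ]
  else if (!is.null(x0))
    predict(fit, newdata = x0, interval = "prediction", level = level)
  structure(list(fit = fit, vn = vn, heterogeneity = het,
                 per_study = vn$per_study, prediction = pred,
                 config = list(moderators = moderators, x0 = x0,
                               level = level, k = fit$k, p = fit$p,
                               effect_scale = fit$effect_scale,
                               package_version =
                                 as.character(utils::packageVersion("metavalid")))),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, digits = 3, ...) {
  cat("==== Validation report ====\n")
  print(x$fit)
  cat("\nPer-study leave-one-out estimates:\n")
  tab <- x$per_study
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print.data.frame(tab, row.names = FALSE)
  cat("\n")
  print(x$vn)
  print(x$heterogeneity)
  if (!is.null(x$prediction))
    cat(sprintf("%.0f%% prediction interval: (%.2f, %.2f)\n",
                100 * x$config$level, x$prediction$lower, x$prediction$upper))
  invisible(x)
}

#' Write a validation report to JSON or CSV
#'
#' JSON output embeds the full summary block, the eigenvalue spectrum,
#' the per-study table and the configuration used (the reproducibility
#' contract); CSV output writes the per-study table with the summary
#' statistics attached as comment header lines.
#'
#' @param report A [validation_report()].
#' @param file Output path.
#' @param format `"json"` or `"csv"` (default from the file extension).
#' @return `file`, invisibly.
#' @export
write_validation_report <- function(report, file,
                                    format = c("auto", "json", "csv")) {
  stopifnot(inherits(report, "validation_report"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "csv" else "json"
  het <- report$heterogeneity
  summ <- list(vn = report$vn$statistic, vn_p = report$vn$p.value,
               vn_p_error_bound = report$vn$p.error_bound,
               lambdas = report$vn$lambdas,
               Q = het$Q, Q_df = het$df, Q_p = het$p_value,
               I2 = het$I2, typical_se = het$typical_se,
               tau = het$tau, tau_over_se = het$ratio)
  if (!is.null(report$prediction))
    summ$prediction_interval <- c(report$prediction$lower,
                                  report$prediction$upper)
  if (format == "json") {
    jsonlite::write_json(list(summary = summ,
                              per_study = report$per_study,
                              config = report$config),
                         file, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    con <- file(file, "w")
    on.exit(close(con))
    scalars <- summ[!names(summ) %in% "lambdas"]
    for (nm in names(scalars))
      writeLines(sprintf("# %s = %s", nm,
                         paste(format(scalars[[nm]], digits = 10),
                               collapse = ", ")), con)
    utils::write.csv(report$per_study, con, row.names = FALSE)
  }
  invisible(file)
}
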