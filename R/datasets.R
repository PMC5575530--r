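#' Construct a study-level meta-analysis dataset
#'
#' A `meta_dataset` is a plain data frame with one row per primary study,
#' columns `label`, `y` (effect estimate on the analysis scale) and `vi`
#' (within-study sampling variance), optional `n` and `sigma2` (patient
#' sample size and patient-level variance, in which case `vi = sigma2/n`),
#' and any number of numeric moderator columns.
#'
#' @param y Numeric vector of study effect estimates.
#' @param vi Positive sampling variances, same length as `y`.
#' @param labels Optional study labels (default "study 1", ...).
#' @param moderators Optional data frame (or named list) of numeric
#'   study-level covariates.
#' @param n,sigma2 Optional per-study sample sizes and patient-level
#'   variances; when both are supplied, `vi` must equal `sigma2/n`.
#' @param effect_scale One of `"generic"`, `"log_rr"`, `"logit_ppv"`;
#'   recorded as an attribute and used only for labelling output.
#' @return A data frame of class `meta_dataset`.
#' @examples
#' meta_dataset(y = c(0, 1, 2), vi = c(1, 1, 1))
#' @export
meta_dataset <- function(y, vi, labels = NULL, moderators = NULL,
                         n = NULL, sigma2 = NULL,
                         effect_scale = c("generic", "log_rr", "logit_ppv")) {
  effect_scale <- match.arg(effect_scale)
  k <- length(y)
  if (k < 3L) stop("a meta-analysis dataset needs at least 3 studies")
  if (length(vi) != k) stop("'y' and 'vi' must have the same length")
  if (any(!is.finite(y)) || any(!is.finite(vi)) || any(vi <= 0))
    stop("'y' must be finite and 'vi' finite and strictly positive")
  if (is.null(labels)) labels <- paste("study", seq_len(k))
  if (length(labels) != k) stop("'labels' has the wrong length")
  d <- data.frame(label = as.character(labels), y = as.numeric(y),
                  vi = as.numeric(vi), stringsAsFactors = FALSE)
  if (!is.null(n)) {
    if (length(n) != k || any(n <= 0)) stop("'n' must be positive, length k")
    d$n <- as.numeric(n)
  }
  if (!is.null(sigma2)) {
    if (length(sigma2) != k || any(sigma2 <= 0))
      stop("'sigma2' must be positive, length k")
    d$sigma2 <- as.numeric(sigma2)
    if (!is.null(n)) {
      rel <- abs(d$vi - d$sigma2 / d$n) / d$vi
      if (any(rel > 1e-12))
        stop("'vi' must equal sigma2/n when both are supplied")
    }
  }
  mods <- character(0)
  if (!is.null(moderators)) {
    moderators <- as.data.frame(moderators)
    if (nrow(moderators) != k) stop("moderators must have one row per study")
    if (!all(vapply(moderators, is.numeric, logical(1))))
      stop("moderator columns must be numeric")
    if (any(vapply(moderators, anyNA, logical(1))))
      stop("moderator columns must not contain missing values")
    d <- cbind(d, moderators)
    mods <- names(moderators)
  }
  structure(d, effect_scale = effect_scale, moderators = mods,
            class = c("meta_dataset", "data.frame"))
}

#' @export
print.meta_dataset <- function(x, ...) {
  cat(sprintf("Meta-analysis dataset: %d studies (scale: %s)\n",
              nrow(x), attr(x, "effect_scale")))
  mods <- attr(x, "moderators")
  if (length(mods)) cat("Moderators:", paste(mods, collapse = ", "), "\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' BCG vaccine efficacy trials (13 studies, log relative risk)
#'
#' The classic dataset of 13 trials of the Bacillus Calmette-Guerin (BCG)
#' vaccine against tuberculosis, on the log relative-risk scale, with the
#' absolute latitude of each trial site as a moderator. Effect estimates
#' are the published per-study values; sampling variances are reconstructed
#' from the published 95% confidence intervals via [variance_from_ci()],
#' so downstream statistics carry the rounding of the printed intervals
#' (two decimal places).
#'
#' @return A [meta_dataset()] with 13 rows and moderator `latitude`.
#' @examples
#' d <- berkey_bcg()
#' nrow(d)
#' @export
berkey_bcg <- function() {
  lab <- c("Vandiviere et al. 1973", "Ferguson & Simes 1949",
           "Hart & Sutherland 1977", "Rosenthal et al. 1961",
           "Rosenthal et al. 1960", "Aronson 1948",
           "Stein & Aronson 1953", "Coetzee & Berjak 1968",
           "Comstock et al. 1974", "Frimodt-Miller et al. 1973",
           "Comstock et al. 1976", "TPT Madras 1980",
           "Comstock & Webster 1969")
  lat <- c(19, 55, 52, 42, 42, 44, 44, 27, 18, 13, 33, 13, 33)
  y   <- c(-1.62, -1.59, -1.44, -1.37, -1.35, -0.89, -0.79, -0.47, -0.34,
           -0.22, -0.02, 0.01, 0.45)
  lo  <- c(-2.55, -2.45, -1.72, -1.90, -2.61, -2.01, -0.95, -0.94, -0.56,
           -0.66, -0.54, -0.11, -0.98)
  hi  <- c(-0.70, -0.72, -1.16, -0.84, -0.08, 0.23, -0.62, 0.00, -0.12,
           0.23, 0.51, 0.14, 1.88)
  meta_dataset(y = y, vi = variance_from_ci(lo, hi), labels = lab,
               moderators = data.frame(latitude = lat),
               effect_scale = "log_rr")
}

#' Galactomannan assay positive predictive value (7 studies, logit PPV)
#'
#' Seven diagnostic-accuracy studies of the galactomannan assay for
#' invasive aspergillosis (positivity threshold: optical density index
#' 0.5), on the logit positive-predictive-value scale, with the logit
#' disease prevalence of each study as a moderator. As with
#' [berkey_bcg()], effects are the published estimates and variances are
#' reconstructed from the published 95% confidence intervals; the first
#' study's published estimate includes a 0.5 continuity correction.
#'
#' @return A [meta_dataset()] with 7 rows and moderator `lgtprev`.
#' @examples
#' leeflang_galactomannan()
#' @export
leeflang_galactomannan <- function() {
  lab <- c("Allan 2005", "Florent 2006", "Kawazu 2004", "Foy 2007",
           "Yoo 2005", "Weisser 2005", "Suankratay 2006")
  lgtprev <- c(-4.82, -2.56, -2.53, -2.21, -2.10, -1.95, -0.66)
  y  <- c(-3.09, -1.58, -0.74, -0.15, -0.73, -0.94, 0.21)
  lo <- c(-5.93, -2.34, -1.46, -1.24, -1.42, -1.52, -0.52)
  hi <- c(-0.26, -0.82, -0.02, 0.94, -0.05, -0.36, 0.94)
  meta_dataset(y = y, vi = variance_from_ci(lo, hi), labels = lab,
               moderators = data.frame(lgtprev = lgtprev),
               effect_scale = "logit_ppv")
}

#' Read a study-level dataset from CSV
#'
#' Reads an RFC-4180 CSV with a header row and assembles a
#' [meta_dataset()]. Exactly one variance source must be available:
#' a variance column (`vi`), confidence-limit columns (`ci_lb`/`ci_ub`,
#' variance via [variance_from_ci()]), or 2x2 count columns
#' (`tp`,`tn`,`cp`,`cn` for log relative risk, or `tp`,`fp` for logit PPV,
#' effects computed internally).
#'
#' @param file Path to a CSV file.
#' @param mapping Named list mapping roles to column names. Recognised
#'   roles: `label`, `y`, `vi`, `ci_lb`, `ci_ub`, `tp`, `tn`, `cp`, `cn`,
#'   `fp`, `moderators` (character vector of column names), `n`, `sigma2`.
#'   May also be the path to a flat `key=value` configuration file with
#'   one role per line (moderators comma-separated).
#' @param effect_scale Effect scale recorded in the result; forced to
#'   `"log_rr"`/`"logit_ppv"` when built from counts.
#' @param level Confidence level of `ci_lb`/`ci_ub` columns.
#' @param continuity Continuity correction passed to the effect builders.
#' @return A [meta_dataset()].
#' @seealso [write_meta_dataset()]
#' @export
read_meta_dataset <- function(file, mapping = list(label = "label", y = "y",
                                                   vi = "vi"),
                              effect_scale = "generic", level = 0.95,
                              continuity = 0.5) {
  if (is.character(mapping) && length(mapping) == 1L)
    mapping <- read_mapping(mapping)
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- function(role) {
    col <- mapping[[role]]
    if (is.null(col)) return(NULL)
    if (!all(col %in% names(d)))
      stop(sprintf("column '%s' (role '%s') not found in %s",
                   paste(setdiff(col, names(d)), collapse = ", "),
                   role, file))
    for (cc in col) {
      if (role != "label" && !is.numeric(d[[cc]])) {
        bad <- which(is.na(suppressWarnings(as.numeric(d[[cc]]))))
        stop(sprintf("non-numeric cell(s) in column '%s', row(s) %s",
                     cc, paste(utils::head(bad, 3), collapse = ", ")))
      }
    }
    if (length(col) == 1L) d[[col]] else d[col]
  }
  lab <- need("label")
  if (!is.null(mapping$tp) && !is.null(mapping$cp)) {
    tp <- need("tp"); tn <- need("tn"); cp <- need("cp"); cn <- need("cn")
    eff <- mapply(function(a, b, c2, d2)
      unlist(effect_log_rr(a, b, c2, d2, continuity)[c("y", "v")]),
      tp, tn, cp, cn)
    y <- eff["y", ]; vi <- eff["v", ]; effect_scale <- "log_rr"
  } else if (!is.null(mapping$tp) && !is.null(mapping$fp)) {
    tp <- need("tp"); fp <- need("fp")
    eff <- mapply(function(a, b)
      unlist(effect_logit_ppv(a, b, continuity)[c("y", "v")]), tp, fp)
    y <- eff["y", ]; vi <- eff["v", ]; effect_scale <- "logit_ppv"
  } else {
    y <- need("y")
    if (is.null(y)) stop("mapping must name a 'y' column or count columns")
    if (!is.null(mapping$vi)) {
      vi <- need("vi")
    } else if (!is.null(mapping$ci_lb) && !is.null(mapping$ci_ub)) {
      vi <- variance_from_ci(need("ci_lb"), need("ci_ub"), level)
    } else stop("mapping must provide 'vi' or 'ci_lb'/'ci_ub' columns")
  }
  mods <- NULL
  if (!is.null(mapping$moderators)) {
    need("moderators")
    mods <- d[mapping$moderators]   # data frame, keeps column names
  }
  meta_dataset(y = y, vi = vi, labels = lab, moderators = mods,
               n = if (!is.null(mapping$n)) need("n"),
               sigma2 = if (!is.null(mapping$sigma2)) need("sigma2"),
               effect_scale = effect_scale)
}

#' Write a study-level dataset to CSV
#'
#' Writes all columns of a [meta_dataset()] so that
#' `read_meta_dataset()` round-trips the numeric fields exactly.
#'
#' @param x A [meta_dataset()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_meta_dataset <- function(x, file) {
  stopifnot(inherits(x, "meta_dataset"))
  utils::write.csv(as.data.frame(x), file, row.names = FALSE)
  invisible(file)
}

# Flat key=value config reader (one role per line; '#' comments;
# moderators given as a comma-separated list).
read_mapping <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed mapping line: ", ln)
    key <- trimws(kv[1]); val <- trimws(strsplit(kv[2], ",")[[1]])
    out[[key]] <- val
  }
  out
}
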