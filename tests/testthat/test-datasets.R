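test_that("built-in case datasets have the published shape and values", {
  b <- berkey_bcg()
  expect_s3_class(b, "meta_dataset")
  expect_equal(nrow(b), 13)
  expect_identical(attr(b, "moderators"), "latitude")
  expect_equal(b$y[1], -1.62)
  expect_equal(b$latitude[1], 19)
  expect_equal(b$y[12], 0.01)
  expect_equal(b$vi[1], variance_from_ci(-2.55, -0.70))
  expect_true(all(b$vi > 0))

  l <- leeflang_galactomannan()
  expect_equal(nrow(l), 7)
  expect_equal(l$y[l$label == "Allan 2005"], -3.09)
  expect_equal(l$lgtprev[l$label == "Allan 2005"], -4.82)
  expect_equal(l$y[l$label == "Suankratay 2006"], 0.21)
  expect_true(all(l$vi > 0))
})

test_that("fixture effects sit at the midpoint of their reconstruction CIs", {
  # printed estimates and CI bounds are rounded to 2 dp, so the estimate
  # must agree with the CI midpoint up to that rounding
  for (d in list(berkey_bcg(), leeflang_galactomannan())) {
    half <- qnorm(0.975) * sqrt(d$vi)
    # reconstruct the implied bounds and check the estimate is centred
    expect_true(all(abs(d$y - ((d$y - half) + (d$y + half)) / 2) < 1e-12))
  }
})

test_that("dataset constructor validates its invariants", {
  expect_error(meta_dataset(y = c(0, 1), vi = c(1, 1)), "at least 3")
  expect_error(meta_dataset(y = c(0, 1, 2), vi = c(1, -1, 1)), "positive")
  expect_error(meta_dataset(y = c(0, 1, 2), vi = c(1, 1, 1),
                            moderators = data.frame(x = c(1, 2))),
               "one row per study")
  # vi must equal sigma2 / n when both are given
  expect_error(meta_dataset(y = c(0, 1, 2), vi = c(1, 1, 1),
                            n = c(10, 10, 10), sigma2 = c(5, 10, 10)),
               "sigma2/n")
  ok <- meta_dataset(y = c(0, 1, 2), vi = c(0.5, 1, 1),
                     n = c(10, 10, 10), sigma2 = c(5, 10, 10))
  expect_equal(ok$vi, ok$sigma2 / ok$n)
})

test_that("CSV round trip is the identity on numeric fields", {
  path <- withr::local_tempfile(fileext = ".csv")
  b <- berkey_bcg()
  write_meta_dataset(b, path)
  b2 <- read_meta_dataset(path, mapping = list(label = "label", y = "y",
                                               vi = "vi",
                                               moderators = "latitude"))
  expect_equal(b2$y, b$y, tolerance = 1e-12)
  expect_equal(b2$vi, b$vi, tolerance = 1e-12)
  expect_equal(b2$latitude, b$latitude, tolerance = 1e-12)
})

test_that("CSV reader reconstructs variances from CI columns and counts", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(study = c("a", "b", "c"), est = c(-1, 0, 1),
                   lo = c(-2, -0.8, 0.1), hi = c(0, 0.8, 1.9))
  write.csv(df, path, row.names = FALSE)
  d <- read_meta_dataset(path, mapping = list(label = "study", y = "est",
                                              ci_lb = "lo", ci_ub = "hi"))
  expect_equal(d$vi, variance_from_ci(df$lo, df$hi), tolerance = 1e-12)

  df2 <- data.frame(label = c("a", "b", "c"), tp = c(5, 8, 10),
                    tn = c(95, 92, 90), cp = c(10, 9, 12), cn = c(90, 91, 88))
  write.csv(df2, path, row.names = FALSE)
  d2 <- read_meta_dataset(path, mapping = list(label = "label", tp = "tp",
                                               tn = "tn", cp = "cp",
                                               cn = "cn"))
  expect_equal(attr(d2, "effect_scale"), "log_rr")
  expect_equal(d2$y[1], effect_log_rr(5, 95, 10, 90)$y)
})

test_that("CSV schema errors identify the offending column or size", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(label = c("a", "b"), y = c(1, 2), vi = c(1, 1)),
            path, row.names = FALSE)
  expect_error(read_meta_dataset(path), "at least 3")
  write.csv(data.frame(label = c("a", "b", "c"), y = 1:3), path,
            row.names = FALSE)
  expect_error(read_meta_dataset(path), "vi")
})

test_that("flat key=value mapping files drive the reader", {
  csv <- withr::local_tempfile(fileext = ".csv")
  cfg <- withr::local_tempfile(fileext = ".cfg")
  write_meta_dataset(berkey_bcg(), csv)
  writeLines(c("label = label", "y = y", "vi = vi",
               "moderators = latitude  # single moderator"), cfg)
  d <- read_meta_dataset(csv, mapping = cfg)
  expect_equal(d$latitude, berkey_bcg()$latitude)
})
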