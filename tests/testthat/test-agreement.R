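test_that("Pearson correlation with degenerate-input guards", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  # explicit sum-of-products oracle
  y <- c(1, 3, 2, 4)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), num / den)
  expect_equal(pearson_r(x, y), 0.8)
  expect_error(pearson_r(x, rep(2, 4)), class = "ranobm_invalid_value")
})

test_that("Lin's CCC penalizes location and scale shift", {
  x <- c(1, 2, 3)
  expect_equal(lin_ccc(x, x), 1)
  expect_equal(lin_ccc(x, c(2, 4, 6)), 8 / 22)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1)  # contrast
  expect_lt(lin_ccc(x, x + 2), 1)
  # CCC <= |r| with equality iff no shift
  set.seed(11)
  for (i in 1:20) {
    a <- stats::rnorm(30); b <- 0.8 * a + stats::rnorm(30, 0.5, 0.4)
    expect_lte(lin_ccc(a, b), abs(pearson_r(a, b)) + 1e-12)
  }
})

test_that("categorical agreement: percent, kappa, PABAK", {
  diagm <- diag(c(5, 6, 7, 8))
  expect_equal(percent_agreement(diagm), 1)
  expect_equal(cohen_kappa(diagm), 1)
  expect_equal(pabak(diagm), 1)
  offm <- matrix(c(0, 3, 4, 0), 2, 2)
  expect_equal(percent_agreement(offm), 0)
  m4 <- diag(c(10, 8, 7, 5)); m4[1, 2] <- 6; m4[3, 4] <- 4
  expect_equal(percent_agreement(m4), 30 / 40)
  # 2x2 marginal-arithmetic oracle
  t22 <- matrix(c(20, 10, 5, 15), 2, 2)
  po <- (20 + 15) / 50
  pe <- (25 / 50) * (30 / 50) + (25 / 50) * (20 / 50)
  expect_equal(cohen_kappa(t22), (po - pe) / (1 - pe))
  # independence-structured table has kappa 0
  ind <- outer(c(10, 30), c(5, 15)) / 10
  expect_equal(cohen_kappa(ind), 0)
  # PABAK closed forms
  expect_equal(pabak(matrix(c(9, 1, 1, 9), 2, 2)), 2 * 0.9 - 1)
  u4 <- matrix(1, 4, 4)  # p_o = 0.25, chance level for 4 categories
  expect_equal(pabak(u4), 0)
  # PABAK equals kappa when marginals are uniform
  um <- matrix(c(30, 10, 10, 30), 2, 2)
  expect_equal(pabak(um), cohen_kappa(um))
  expect_error(percent_agreement(matrix(0, 2, 2)),
               class = "ranobm_invalid_value")
})

test_that("Pearson-Filon: degenerate, symmetric and swapped cases", {
  set.seed(3)
  x <- stats::rnorm(50); y <- 0.6 * x + stats::rnorm(50)
  pf <- pearson_filon_test(x, y, x, y)
  expect_equal(pf$z, 0)
  expect_equal(pf$p_value, 1)
  a <- stats::rnorm(50); b <- 0.3 * a + stats::rnorm(50)
  p1 <- pearson_filon_test(x, y, a, b)
  p2 <- pearson_filon_test(a, b, x, y)
  expect_equal(p1$z, -p2$z)
  expect_error(pearson_filon_test(x, y, x, x),
               class = "ranobm_invalid_value")
  expect_error(pearson_filon_test(x[1:5], y[1:5], a[1:5], b[1:5]),
               class = "ranobm_invalid_value")
})

test_that("Pearson-Filon agrees with a bootstrap-SE oracle", {
  set.seed(7)
  x <- rmvn4(200, pf_null_sigma(0.5))
  x[, 3] <- x[, 3] + 0.3 * x[, 4]
  pf <- pearson_filon_test(x[, 1], x[, 2], x[, 3], x[, 4])
  d_boot <- replicate(10000, {
    i <- sample(200, replace = TRUE)
    stats::cor(x[i, 1], x[i, 2]) - stats::cor(x[i, 3], x[i, 4])
  })
  z_boot <- (pf$r12 - pf$r34) / stats::sd(d_boot)
  p_boot <- 2 * stats::pnorm(-abs(z_boot))
  expect_lt(abs(pf$p_value - p_boot), 0.02)
})

test_that("confusion matrices align on shared (lesion, time) keys", {
  s <- response_sequence("L1", c(30, 90, 150, 210, 270),
                         c("SD", "PR", "PR", "PD", "SD"))
  cm_self <- confusion_matrix(list(s), list(s))
  expect_equal(sum(diag(as.matrix(cm_self))), 5)
  expect_equal(attr(cm_self, "n"), 5)
  s2 <- response_sequence("L1", c(30, 90, 150, 210, 270),
                          c("SD", "PR", "SD", "PD", "PD"))
  cm <- confusion_matrix(list(s), list(s2))
  expect_equal(attr(cm, "n"), 5)
  expect_equal(sum(diag(as.matrix(cm))), 3)
  s3 <- response_sequence("L9", c(30, 90), c("SD", "SD"))
  expect_error(confusion_matrix(list(s), list(s3)),
               class = "ranobm_invalid_value")
})

test_that("biased manual diameters disagree with contour diameters", {
  env <- small_cohort_cache()
  ass <- assess_cohort(env$measurements)
  ag <- agreement_summary(ass[["man-diam"]], ass[["diam-manseg"]])
  expect_lt(ag$percent_agreement, 1)
  expect_gt(ag$n, 20)
  # a method against itself is perfect
  self <- agreement_summary(ass[["diam-manseg"]], ass[["diam-manseg"]])
  expect_equal(self$percent_agreement, 1)
  expect_equal(self$kappa, 1)
})

test_that("diameter-volume correlation is higher for automatic contours", {
  env <- study_cache()
  meas <- env$measurements
  w <- stats::reshape(meas, idvar = c("lesion_id", "time_days"),
                      timevar = "method", direction = "wide")
  names(w) <- sub("value.", "", names(w), fixed = TRUE)
  keep <- stats::complete.cases(
    w[, c("diam-manseg", "vol-manseg", "diam-autoseg", "vol-autoseg")])
  w <- w[keep & w$`vol-manseg` > 0 & w$`diam-manseg` > 0, ]
  pf <- pearson_filon_test(w$`diam-autoseg`, w$`vol-autoseg`^(1 / 3),
                           w$`diam-manseg`, w$`vol-manseg`^(1 / 3))
  expect_gt(pf$r12, pf$r34)   # automatic contours correlate better
  expect_lt(pf$p_value, 0.05) # and the difference is significant
})
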