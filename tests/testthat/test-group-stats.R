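test_that("Levene: identical groups give W = 0, p = 1", {
  expect_equal(levene_test(list(c(5, 5, 5), c(5, 5, 5)))$statistic, 0)
  expect_equal(levene_test(list(c(5, 5, 5), c(5, 5, 5)))$p.value, 1)
  lv <- levene_test(list(c(1, 3), c(1, 3)))
  expect_equal(lv$statistic, 0)
  expect_equal(lv$p.value, 1)
})

test_that("Levene: zero within-group deviation spread guards to W = Inf", {
  lv <- levene_test(list(c(0, 0, 0, 0), c(-10, 10, -10, 10)))
  expect_true(is.infinite(lv$statistic))
  expect_equal(lv$p.value, 0)
})

test_that("Levene matches the mean-centered reference implementation", {
  set.seed(2)
  g1 <- rnorm(10)
  g2 <- rnorm(12, sd = 2)
  g3 <- rnorm(9, sd = 0.5)
  lv <- levene_test(list(g1, g2, g3))
  d <- data.frame(y = c(g1, g2, g3),
                  g = factor(rep(1:3, c(10, 12, 9))))
  ref <- car::leveneTest(y ~ g, d, center = mean)
  expect_equal(lv$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(lv$p.value, ref$`Pr(>F)`[1], tolerance = 1e-10)
  expect_error(levene_test(list(1, c(1, 2))), ">= 2")
})

test_that("ANOVA: equal group means give F = 0", {
  av <- oneway_anova(list(c(1, 2, 3), c(3, 2, 1), c(2, 2, 2)))
  expect_equal(av$F, 0)
})

test_that("raw and summary ANOVA agree exactly (algebraic identity)", {
  for (seed in 1:5) {
    set.seed(seed)
    groups <- lapply(c(8, 8, 8), function(n) rnorm(n, mean = runif(1, 0, 10)))
    raw <- oneway_anova(groups)
    summ <- oneway_anova(data.frame(
      mean = vapply(groups, mean, 0),
      sd = vapply(groups, sd, 0),
      n = lengths(groups)))
    expect_equal(summ$F, raw$F, tolerance = 1e-10)
    expect_equal(summ$ms_within, raw$ms_within, tolerance = 1e-10)
    # and both match the equal-variance Welch-free reference
    d <- data.frame(y = unlist(groups),
                    g = factor(rep(seq_along(groups), lengths(groups))))
    ref <- oneway.test(y ~ g, d, var.equal = TRUE)
    expect_equal(raw$F, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(raw$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("summary-mode ANOVA on the printed SAP row is significant", {
  av <- oneway_anova(sap_summary())
  expect_equal(av$df, c(2, 21))
  expect_gt(av$F, qf(0.95, 2, 21))
  expect_lt(av$p.value, 0.05)
})

test_that("ANOVA rejects degenerate designs", {
  expect_error(oneway_anova(list(1, 2)), "degrees of freedom")
  expect_error(oneway_anova(data.frame(mean = c(1, 2), n = c(8, 8))), "sd or sem")
})

test_that("Pearson correlation: exact lines and reference agreement", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  set.seed(6)
  a <- rnorm(24)
  b <- -0.6 * a + rnorm(24, sd = 0.8)
  pc <- pearson_correlation(a, b)
  ref <- cor.test(a, b)
  expect_equal(pc$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(pc$p.value, ref$p.value, tolerance = 1e-12)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson_correlation(1:2, 1:2), ">= 3")
})

test_that("simulated adipose/IL-10 cohorts give r near -0.6 with p near 0.05", {
  # n = 24 as in a three-group pooled correlation
  rs <- vapply(1:40, function(s) {
    sp <- cohort_spec("G",
                      data.frame(variable = c("adipose", "il10"),
                                 mean = c(3.4, 27.6), sd = c(1.6, 8)),
                      n = 24,
                      correlations = data.frame(var1 = "adipose",
                                                var2 = "il10", r = -0.6),
                      seed = 400 + s)
    w <- cohort_wide(simulate_cohort(sp))
    pearson_correlation(w$adipose, w$il10)$r
  }, 0)
  expect_true(all(rs > -0.9 & rs < -0.2))
  expect_lt(abs(median(rs) - (-0.6)), 0.1)
})
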