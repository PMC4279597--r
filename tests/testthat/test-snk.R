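test_that("studentized range quantile matches the analytic r=2, df=Inf case", {
  expect_lt(abs(studentized_range_quantile(0.05, 2, Inf) -
                  sqrt(2) * qnorm(0.975)), 1e-3)
})

test_that("quantiles match published critical-value tables within 0.01", {
  # alpha = 0.05 tables: df = 20 row and df = Inf row; alpha = 0.01, df = 10
  published <- rbind(
    c(p = 0.05, r = 2, df = 20, q = 2.95),
    c(p = 0.05, r = 3, df = 20, q = 3.58),
    c(p = 0.05, r = 4, df = 20, q = 3.96),
    c(p = 0.05, r = 2, df = Inf, q = 2.77),
    c(p = 0.05, r = 3, df = Inf, q = 3.31),
    c(p = 0.05, r = 4, df = Inf, q = 3.63),
    c(p = 0.01, r = 2, df = 10, q = 4.48))
  for (i in seq_len(nrow(published))) {
    got <- studentized_range_quantile(published[i, "p"], published[i, "r"],
                                      published[i, "df"])
    expect_lt(abs(got - published[i, "q"]), 0.01)
  }
})

test_that("quadrature quantile agrees with R's qtukey across a grid", {
  for (p in c(0.05, 0.01, 0.10)) {
    for (r in c(2, 3, 5)) {
      for (df in c(5, 21, 60)) {
        expect_lt(abs(studentized_range_quantile(p, r, df) -
                        qtukey(1 - p, r, df)), 1e-3)
      }
    }
  }
})

test_that("CDF inverts the quantile to within 1e-3", {
  for (p in c(0.05, 0.2)) {
    for (r in c(2, 4)) {
      for (df in c(10, Inf)) {
        q <- studentized_range_quantile(p, r, df)
        expect_lt(abs(srange_cdf(q, r, df) - (1 - p)), 1e-3)
      }
    }
  }
})

test_that("quantile increases with the number of means spanned", {
  qs <- vapply(2:6, function(r) studentized_range_quantile(0.05, r, 21), 0)
  expect_true(all(diff(qs) > 0))
  expect_error(studentized_range_quantile(1.5, 2, 10), "p must be")
})

test_that("SNK declares nothing when all means are identical", {
  g <- list(a = c(1, 2, 3, 4), b = c(2.5, 2.5, 2, 3), c = c(1, 4, 2, 3))
  ph <- snk_posthoc(g)
  expect_false(any(ph$significant))
})

test_that("SNK reproduces the printed systolic-pressure marker pattern", {
  ph <- snk_posthoc(sap_summary())
  expect_true(snk_significant(ph, "FHO", "H"))
  expect_true(snk_significant(ph, "FHO", "HO"))
  expect_false(snk_significant(ph, "HO", "H"))
})

test_that("SNK reproduces the printed TNF-alpha marker pattern", {
  ph <- snk_posthoc(tnf_summary())
  expect_true(snk_significant(ph, "FHO", "H"))
  expect_true(snk_significant(ph, "FHO", "HO"))
  expect_false(snk_significant(ph, "HO", "H"))
})

test_that("containment: a non-significant enclosing range blocks sub-ranges", {
  # full range barely non-significant but an inner pair's raw q exceeds
  # its own r = 2 critical value -> must still be declared non-significant
  gs <- group_summary(c("a", "b", "c"), c(0, 3.2, 3.3), c(1, 1, 1), c(8, 8, 8))
  ms_w <- 8  # inflate error so the r=3 range fails its taller critical value
  df_e <- 21
  se <- sqrt(ms_w / 8)
  q3 <- (3.3 - 0) / se
  q2 <- (3.2 - 0) / se
  crit3 <- studentized_range_quantile(0.05, 3, df_e)
  crit2 <- studentized_range_quantile(0.05, 2, df_e)
  expect_lt(q3, crit3)  # construction: full range non-significant
  expect_gt(q2, crit2)  # construction: inner pair raw-significant
  ph <- snk_posthoc(gs, ms_within = ms_w, df_error = df_e)
  expect_false(any(ph$significant))
})

test_that("SNK with zero F declares no significant pairs", {
  g <- list(a = c(1, 2, 3), b = c(3, 2, 1), c = c(2, 2, 2))
  expect_equal(oneway_anova(g)$F, 0)
  expect_false(any(snk_posthoc(g)$significant))
})

test_that("unequal group sizes fall back to harmonic mean n with a warning", {
  g <- list(a = rnorm(6, 0), b = rnorm(8, 5), c = rnorm(10, 10))
  expect_warning(ph <- snk_posthoc(g), "harmonic")
  expect_true(attr(ph, "unequal_n"))
  expect_equal(attr(ph, "n_effective"), 3 / (1 / 6 + 1 / 8 + 1 / 10))
})

test_that("SNK family type-I error on null cohorts is near alpha", {
  set.seed(77)
  hits <- 0L
  nsim <- 2000
  for (i in seq_len(nsim)) {
    g <- list(rnorm(8), rnorm(8), rnorm(8))
    if (any(snk_posthoc(g)$significant)) hits <- hits + 1L
  }
  rate <- hits / nsim
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})
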