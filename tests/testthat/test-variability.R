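test_that("time-domain SD/VAR: constant, sinusoid, two-point cases", {
  expect_equal(time_domain(rep(150, 100))$var, 0)
  expect_equal(time_domain(rep(150, 100))$sd, 0)
  tac <- simulate_tachogram(tachogram_spec(amp_lf = 10, duration = 300))
  expect_lt(abs(time_domain(tac$pi_ms)$var - 50) / 50, 0.05)
  td <- time_domain(c(140, 160))
  expect_equal(td$var, 200)
  expect_equal(td$sd, sqrt(200))
  expect_error(time_domain(list(c(1, 2), 3)), "fewer than 2")
})

test_that("spline resampling is exact for cubic polynomials", {
  t <- seq(0, 10, by = 0.25)
  v <- 2 + 3 * t - 0.5 * t^2 + 0.1 * t^3
  es <- resample_even(t, v, fine_rate = 8, out_rate = 8)
  tg <- seq(t[1], t[length(t)], by = 1 / 8)
  expect_equal(es$values, 2 + 3 * tg - 0.5 * tg^2 + 0.1 * tg^3,
               tolerance = 1e-10)
})

test_that("constant series resamples to a constant", {
  t <- cumsum(runif(50, 0.1, 0.2))
  es <- resample_even(t, rep(42, 50), fine_rate = 250, out_rate = 10)
  expect_lt(max(abs(es$values - 42)), 1e-6)
})

test_that("a 0.4 Hz sinusoid survives resampling with < 2% amplitude error", {
  set.seed(5)
  t <- cumsum(runif(2100, 0.12, 0.18))  # irregular beat times, ~300 s
  v <- 10 * sin(2 * pi * 0.4 * t)
  es <- resample_even(t, v, fine_rate = 250, out_rate = 10)
  tg <- es$start_time + (seq_along(es$values) - 1) / es$rate
  fit <- lm(es$values ~ sin(2 * pi * 0.4 * tg) + cos(2 * pi * 0.4 * tg))
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  expect_lt(abs(amp - 10) / 10, 0.02)
})

test_that("resampling rejects bad inputs", {
  expect_error(resample_even(c(0, 1, 0.5, 2), 1:4), "increasing")
  expect_error(resample_even(c(0, 1, 2), 1:3), "4 beats")
  expect_error(resample_even(0:9, 1:10, fine_rate = 250, out_rate = 60),
               "integer")
})

test_that("linear detrending removes exactly the OLS line and is idempotent", {
  n <- 200
  t <- (0:(n - 1)) / 10
  es <- even_series(3 + 0.7 * t, 10)
  d <- detrend_linear(es)
  expect_lt(max(abs(d$values)), 1e-9)
  sinser <- even_series(5 * sin(2 * pi * 0.3 * t) + 2 - 0.1 * t, 10)
  d2 <- detrend_linear(sinser)
  expect_lt(abs(mean(d2$values)), 1e-9)
  tc <- t - mean(t)
  expect_lt(abs(sum(tc * d2$values) / sum(tc^2)), 1e-9)
  d3 <- detrend_linear(d2)
  expect_equal(d2$values, d3$values, tolerance = 1e-9)
})

test_that("PSD of a zero series is identically zero", {
  sp <- compute_psd(even_series(rep(0, 64), 10, detrended = TRUE))
  expect_true(all(sp$psd == 0))
})

test_that("Parseval: integrated PSD equals series variance", {
  # exact-bin unit sinusoid -> 0.5, to 1e-6 relative
  n <- 512
  rate <- 10
  f <- 20 * rate / n
  x <- sin(2 * pi * f * (0:(n - 1)) / rate)
  sp <- compute_psd(even_series(x, rate, detrended = TRUE))
  expect_lt(abs(sum(sp$psd) * sp$df - 0.5) / 0.5, 1e-6)
  # arbitrary detrended series, rectangular window: exact Parseval
  set.seed(8)
  es <- detrend_linear(even_series(rnorm(500, sd = 3), 10))
  pv <- mean((es$values - mean(es$values))^2)
  sp2 <- compute_psd(es)
  expect_lt(abs(sum(sp2$psd) * sp2$df - pv) / pv, 1e-9)
  # Hann window preserves broadband Parseval within a few percent
  esl <- detrend_linear(even_series(rnorm(4096), 10))
  pvl <- mean((esl$values - mean(esl$values))^2)
  sph <- compute_psd(esl, window = "hann")
  expect_lt(abs(sum(sph$psd) * sph$df - pvl) / pvl, 0.1)
  expect_error(compute_psd(even_series(rnorm(8), 10)), "16")
})

test_that("band powers match a brute-force O(n^2) DFT oracle", {
  set.seed(13)
  for (n in c(128, 257, 512)) {
    x <- rnorm(n) + 2 * sin(2 * pi * 0.4 * (0:(n - 1)) / 10)
    es <- detrend_linear(even_series(x, 10))
    sp <- compute_psd(es)
    for (band in list(c(0.2, 0.75), c(0.75, 4), c(0.2, 3))) {
      got <- band_power(sp, band[1], band[2])
      want <- dft_band_oracle(es$values, 10, band[1], band[2])
      expect_lt(abs(got - want) / want, 1e-9)
    }
  }
})

test_that("bands partition the spectrum exactly (half-open edges)", {
  set.seed(14)
  # odd length: every bin lies strictly below Nyquist, so [0, 5) is total
  es <- detrend_linear(even_series(rnorm(301), 10))
  sp <- compute_psd(es)
  total <- band_power(sp, 0, 5)
  lf <- band_power(sp, 0.2, 0.75)
  hf <- band_power(sp, 0.75, 4)
  rest <- band_power(sp, 0, 0.2) + band_power(sp, 4, 5)
  expect_lt(abs(lf + hf + rest - total) / total, 1e-9)
  expect_error(band_power(sp, 1, 6), "support")
  expect_error(band_power(sp, -1, 2), "lo")
})

test_that("injected LF modulation is recovered as LF band power", {
  tac <- simulate_tachogram(tachogram_spec(amp_lf = 10, duration = 300))
  vr <- analyze_variability(tachogram_segment(tac), channels = "pi")
  expect_lt(abs(vr$hrv$lf - 50) / 50, 0.05)
  expect_lt(vr$hrv$hf / vr$hrv$lf, 0.02)
})

test_that("a 1.5 Hz modulation lands almost entirely in the HF band", {
  tac <- simulate_tachogram(tachogram_spec(amp_hf = 10, duration = 300))
  vr <- analyze_variability(tachogram_segment(tac), channels = "pi")
  expect_lt(abs(vr$hrv$hf - 50) / 50, 0.05)
  expect_gt(vr$hrv$hf / vr$hrv$total_power, 0.98)
})

test_that("recovery holds with 2 ms beat-to-beat noise (10%)", {
  tac <- simulate_tachogram(tachogram_spec(amp_lf = 10, noise_sd = 2,
                                           duration = 300, seed = 5))
  vr <- analyze_variability(tachogram_segment(tac), channels = "pi")
  expect_lt(abs(vr$hrv$lf - 50) / 50, 0.10)
})

test_that("three identical segments average to the single-segment result", {
  tac <- simulate_tachogram(tachogram_spec(amp_lf = 6, amp_hf = 4,
                                           noise_sd = 1, duration = 300,
                                           seed = 30))
  seg <- tachogram_segment(tac)[[1]]
  one <- analyze_variability(list(seg), channels = "pi")
  three <- analyze_variability(list(seg, seg, seg), channels = "pi")
  expect_equal(three$hrv$lf, one$hrv$lf)
  expect_equal(three$hrv$var, one$hrv$var)
  expect_equal(three$hrv$n_segments, 3)
})

test_that("table2 band preset caps HF and total power at 3 Hz", {
  b <- band_preset("table2")
  expect_equal(b$hf[2], 3)
  expect_equal(b$total, c(0.2, 3))
  bm <- band_preset("methods")
  expect_equal(bm$hf[2], 4)
})
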