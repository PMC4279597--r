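#' Time-domain variability of beat-value segments
#'
#' Per segment, VAR is the sample variance (denominator n-1) of the beat
#' values and SD its square root; both are then averaged across
#' segments. SD and VAR are each segment-averaged separately, so the
#' reported SD is not in general the square root of the reported VAR.
#'
#' @param segments A list of numeric vectors (one per segment), or a
#'   single numeric vector.
#' @return List with `sd`, `var` and `n_segments`.
#' @export
time_domain <- function(segments) {
  if (is.numeric(segments)) segments <- list(segments)
  if (length(segments) < 1) stop_bad("no segments")
  vars <- vapply(segments, function(s) {
    if (length(s) < 2) stop_bad("segment with fewer than 2 values")
    var(s)
  }, 0)
  list(sd = mean(sqrt(vars)), var = mean(vars), n_segments = length(segments))
}

#' Resample an irregular beat series onto an even grid
#'
#' Cubic-spline interpolation (Forsythe-Malcolm-Moler end conditions,
#' which reproduce cubic polynomials exactly) of the beat-value versus
#' beat-time function onto a fine grid at `fine_rate`, followed by
#' anti-aliased decimation to `out_rate`. The anti-alias filter is a
#' linear-phase windowed-sinc FIR (designed with [signal::fir1()],
#' passband edge at 0.85 of the new Nyquist, stopband reached at the new
#' Nyquist) applied with zero phase and reflection padding, so passband
#' components -- the 0.20-4 Hz variability bands -- are preserved with
#' negligible gain error and no edge transients.
#'
#' @param times Beat times in seconds, strictly increasing, length >= 4.
#' @param values Beat values (e.g. PI in ms or SAP in mmHg).
#' @param fine_rate Interpolation rate in Hz.
#' @param out_rate Output rate in Hz; `fine_rate / out_rate` must be a
#'   positive integer. Equal rates skip decimation (pure interpolation).
#' @return An object of class `even_series`: list with `values`, `rate`,
#'   `start_time` and `detrended = FALSE`.
#' @export
resample_even <- function(times, values, fine_rate = 250, out_rate = 10) {
  if (length(times) != length(values)) stop_bad("times and values differ in length")
  if (length(times) < 4) stop_bad("need >= 4 beats for cubic spline")
  if (any(diff(times) <= 0)) stop_bad("beat times must be strictly increasing")
  if (fine_rate < out_rate) stop_bad("fine_rate must be >= out_rate")
  q <- fine_rate / out_rate
  if (abs(q - round(q)) > 1e-9) stop_bad("fine_rate/out_rate must be an integer")
  q <- as.integer(round(q))
  sf <- splinefun(times, values, method = "fmm")
  tf <- seq(times[1], times[length(times)], by = 1 / fine_rate)
  y <- sf(tf)
  if (q > 1L) y <- decimate_fir(y, q)
  structure(list(values = y, rate = out_rate, start_time = times[1],
                 detrended = FALSE),
            class = "even_series")
}

# Zero-phase FIR decimation by integer factor q: odd-length windowed-sinc
# low-pass (passband edge 0.85 of the new Nyquist, Hamming transition
# reaching the stopband at the new Nyquist), reflection padding against
# edge transients, group delay removed exactly, then subsampling.
decimate_fir <- function(y, q) {
  n <- length(y)
  # Hamming transition width ~ 3.3/ntaps of the sampling rate; size the
  # filter so the 0.15*Nyq_new transition band fits: ntaps ~ 3.3*2q/0.15
  ntaps <- as.integer(2 * ceiling(22 * q) + 1)
  h <- signal::fir1(ntaps - 1, 0.85 / q)
  h <- h / sum(h)                       # unity DC gain
  delay <- (ntaps - 1L) %/% 2L
  if (n <= delay + 1L) {
    stop_bad("series too short (%d fine samples) to decimate by %d", n, q)
  }
  pad <- min(n - 1L, ntaps)
  left <- 2 * y[1] - y[(pad + 1L):2L]          # odd reflection about ends
  right <- 2 * y[n] - y[(n - 1L):(n - pad)]
  z <- signal::fftfilt(h, c(left, y, right))
  aligned <- z[(pad + delay + 1L):(pad + delay + n)]
  aligned[seq(1L, n, by = q)]
}

#' Construct an evenly sampled series
#'
#' @param values Numeric samples.
#' @param rate Sampling rate in Hz.
#' @param start_time Time of the first sample in seconds.
#' @param detrended Logical flag carried through the analysis chain.
#' @return An object of class `even_series`.
#' @export
even_series <- function(values, rate, start_time = 0, detrended = FALSE) {
  if (rate <= 0) stop_bad("rate must be > 0")
  if (length(values) < 2) stop_bad("series needs >= 2 values")
  structure(list(values = as.numeric(values), rate = rate,
                 start_time = start_time, detrended = detrended),
            class = "even_series")
}

#' Remove the least-squares linear trend from an even series
#'
#' Subtracts the ordinary least-squares line, leaving a series with zero
#' mean and zero regression slope; idempotent to floating tolerance.
#'
#' @param series An [even_series()].
#' @return The detrended `even_series` (`detrended = TRUE`).
#' @export
detrend_linear <- function(series) {
  stopifnot(inherits(series, "even_series"))
  x <- series$values
  n <- length(x)
  t <- (seq_len(n) - 1) / series$rate
  tc <- t - mean(t)
  b <- sum(tc * x) / sum(tc^2)
  a <- mean(x) - b * mean(t)
  series$values <- x - (a + b * t)
  series$detrended <- TRUE
  series
}

#' One-sided FFT periodogram
#'
#' Computes the power spectral density of an evenly sampled (and already
#' detrended) series via the fast Fourier transform, normalized so that
#' the discrete integral of the one-sided PSD over (0, Nyquist] equals
#' the series' mean squared deviation from its mean (Parseval identity,
#' exact for the rectangular window; a Hann window is corrected by its
#' mean-square so broadband Parseval still holds). The DC bin is
#' excluded; frequency resolution is `rate / length`.
#'
#' @param series An [even_series()] of length >= 16. The series is used
#'   as-is: detrend with [detrend_linear()] beforehand.
#' @param window `"rectangular"` (default) or `"hann"`.
#' @return An object of class `spectrum_result`: list with `frequencies`
#'   (Hz), `psd` (input units squared per Hz), `rate`, `n`, `df` and
#'   `window`.
#' @export
compute_psd <- function(series, window = c("rectangular", "hann")) {
  stopifnot(inherits(series, "even_series"))
  window <- match.arg(window)
  x <- series$values
  n <- length(x)
  if (n < 16) stop_bad("series must have length >= 16 (got %d)", n)
  w <- switch(window,
              rectangular = rep(1, n),
              hann = 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n)))
  U <- mean(w^2)
  X <- fft(x * w)
  half <- n %/% 2
  j <- seq_len(half)
  pow <- Mod(X[j + 1])^2 / (n^2 * U)
  fac <- rep(2, half)
  if (n %% 2 == 0) fac[half] <- 1  # Nyquist bin is unpaired
  dfreq <- series$rate / n
  structure(list(frequencies = j * dfreq, psd = fac * pow / dfreq,
                 rate = series$rate, n = n, df = dfreq, window = window),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("spectrum_result: %d bins, df = %.4g Hz, Nyquist %.3g Hz (%s window)\n",
              length(x$psd), x$df, x$rate / 2, x$window))
  invisible(x)
}

#' Integrate spectral power over a frequency band
#'
#' Sums the discrete spectral power (`psd * df`) over the half-open band
#' `[lo, hi)`. Half-open intervals prevent double counting at shared
#' band edges, and the bin-sum is the exact discrete integral, so
#' adjacent bands add exactly to the total power.
#'
#' @param spec A `spectrum_result` from [compute_psd()].
#' @param lo,hi Band edges in Hz; `0 <= lo < hi <= Nyquist`.
#' @return Band power in the squared input units.
#' @export
band_power <- function(spec, lo, hi) {
  stopifnot(inherits(spec, "spectrum_result"))
  if (!(lo >= 0 && lo < hi)) stop_bad("need 0 <= lo < hi")
  if (hi > spec$rate / 2 + 1e-9) {
    stop_bad("band edge %g Hz outside spectrum support (Nyquist %g Hz)",
             hi, spec$rate / 2)
  }
  sel <- spec$frequencies >= lo & spec$frequencies < hi
  sum(spec$psd[sel]) * spec$df
}

#' Spectral band presets
#'
#' `"methods"` uses LF 0.20-0.75 Hz, HF 0.75-4.0 Hz, total 0.20-4.0 Hz;
#' `"table2"` caps HF and total power at 3 Hz (LF 0.20-0.75, HF 0.75-3,
#' total 0.20-3), the convention used when variability is reported as
#' total power from 0.20 to 3 Hz.
#'
#' @param preset `"methods"` or `"table2"`.
#' @return List with numeric length-2 elements `lf`, `hf`, `total`.
#' @export
band_preset <- function(preset = c("methods", "table2")) {
  preset <- match.arg(preset)
  switch(preset,
         methods = list(lf = c(0.20, 0.75), hf = c(0.75, 4.0),
                        total = c(0.20, 4.0)),
         table2 = list(lf = c(0.20, 0.75), hf = c(0.75, 3.0),
                       total = c(0.20, 3.0)))
}

#' Heart-rate and blood-pressure variability over analysis segments
#'
#' For each segment and channel, computes time-domain SD and VAR from
#' the raw beat values and spectral LF/HF/total power after
#' spline-resampling to an even grid, linear detrending and FFT
#' periodogram; results are averaged across segments. The default chain
#' interpolates at 250 Hz and decimates to 10 Hz (Nyquist 5 Hz, above
#' the 4 Hz HF ceiling).
#'
#' @param segments A `beat_segments` list from [extract_segments()], or
#'   any list of data frames with columns `time_s`, `pi_ms` and
#'   (optionally) `sap`.
#' @param channels Which series to analyze: `"pi"` (pulse interval, ms;
#'   reported as `hrv`) and/or `"sap"` (systolic pressure, mmHg;
#'   reported as `bpv`).
#' @param bands A band list from [band_preset()] (or the preset name).
#' @param fine_rate,out_rate Resampling rates in Hz, see [resample_even()].
#' @param window Periodogram window, see [compute_psd()].
#' @return A list of class `variability_report` with one element per
#'   channel (`hrv` for PI, `bpv` for SAP), each a list with `sd`,
#'   `var`, `lf`, `hf`, `total_power`, `n_segments` and `units`.
#' @export
analyze_variability <- function(segments, channels = c("pi", "sap"),
                                bands = "methods",
                                fine_rate = 250, out_rate = 10,
                                window = "rectangular") {
  if (is.character(bands)) bands <- band_preset(bands)
  channels <- match.arg(channels, c("pi", "sap"), several.ok = TRUE)
  if (length(segments) < 1) stop_bad("need >= 1 segment")
  out <- list()
  for (ch in channels) {
    col <- if (ch == "pi") "pi_ms" else "sap"
    per_seg <- lapply(segments, function(seg) {
      keep <- !is.na(seg[[col]])
      tt <- seg$time_s[keep]
      vv <- seg[[col]][keep]
      if (length(vv) < 4) stop_bad("segment too short for channel %s", ch)
      es <- resample_even(tt, vv, fine_rate = fine_rate, out_rate = out_rate)
      sp <- compute_psd(detrend_linear(es), window = window)
      c(var = var(vv), sd = sd(vv),
        lf = band_power(sp, bands$lf[1], bands$lf[2]),
        hf = band_power(sp, bands$hf[1], bands$hf[2]),
        total = band_power(sp, bands$total[1], bands$total[2]))
    })
    m <- colMeans(do.call(rbind, per_seg))
    rep_name <- if (ch == "pi") "hrv" else "bpv"
    out[[rep_name]] <- list(sd = m[["sd"]], var = m[["var"]],
                            lf = m[["lf"]], hf = m[["hf"]],
                            total_power = m[["total"]],
                            n_segments = length(segments),
                            units = if (ch == "pi") "ms" else "mmHg")
  }
  structure(out, class = "variability_report")
}

#' @export
print.variability_report <- function(x, ...) {
  for (nm in names(x)) {
    r <- x[[nm]]
    cat(sprintf("%s: SD %.2f %s, VAR %.2f %s^2, LF %.3f, HF %.3f, total %.3f (%d segments)\n",
                toupper(nm), r$sd, r$units, r$var, r$units, r$lf, r$hf,
                r$total_power, r$n_segments))
  }
  invisible(x)
}
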