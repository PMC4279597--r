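#' Specification of the rendered arterial pulse shape
#'
#' Each beat is rendered as a raised-cosine systolic upstroke from DAP to
#' SAP followed by an exponential diastolic decay back to DAP, giving an
#' unambiguous per-beat maximum (= `sap`) and minimum (= `dap`) for
#' detector testing.
#'
#' @param sap,dap Systolic and diastolic pressure in mmHg; `sap > dap > 0`.
#' @param upstroke_fraction Duration of the systolic upstroke as a
#'   fraction (in (0,1)) of the shortest beat interval in the train.
#' @param sampling_rate Output sampling rate in Hz (>= 100).
#' @return An object of class `pulse_shape_spec`.
#' @export
pulse_shape_spec <- function(sap = 180, dap = 120, upstroke_fraction = 0.3,
                             sampling_rate = 2000) {
  if (!(sap > dap && dap > 0)) stop_bad("need sap > dap > 0 (got %g, %g)", sap, dap)
  if (upstroke_fraction <= 0 || upstroke_fraction >= 1) {
    stop_bad("upstroke_fraction must be in (0,1)")
  }
  if (sampling_rate < 100) stop_bad("sampling_rate must be >= 100 Hz")
  structure(list(sap = sap, dap = dap,
                 upstroke_fraction = upstroke_fraction,
                 sampling_rate = sampling_rate),
            class = "pulse_shape_spec")
}

#' Construct a pressure waveform object
#'
#' @param pressure Numeric vector of pressure samples (mmHg), uniformly
#'   sampled.
#' @param sampling_rate Sampling rate in Hz.
#' @param start_time Time of the first sample in seconds.
#' @return An object of class `pressure_waveform`.
#' @export
pressure_waveform <- function(pressure, sampling_rate, start_time = 0) {
  if (sampling_rate <= 0) stop_bad("sampling_rate must be > 0")
  if (length(pressure) < 2) stop_bad("waveform needs at least 2 samples")
  structure(list(pressure = as.numeric(pressure),
                 sampling_rate = sampling_rate,
                 start_time = start_time),
            class = "pressure_waveform")
}

#' @export
print.pressure_waveform <- function(x, ...) {
  cat(sprintf("pressure_waveform: %d samples at %g Hz (%.1f s), %g-%g mmHg\n",
              length(x$pressure), x$sampling_rate,
              length(x$pressure) / x$sampling_rate,
              round(min(x$pressure), 1), round(max(x$pressure), 1)))
  invisible(x)
}

#' Render a beat train into an arterial pressure waveform
#'
#' Given beat (onset) times, renders one pressure pulse per beat: a
#' raised-cosine upstroke of fixed duration `upstroke_fraction *
#' min(beat interval)` from DAP to SAP, then an exponential decay
#' rescaled to reach DAP exactly at the next onset. Because the upstroke
#' duration is constant across beats, systolic peaks are separated by
#' exactly the onset-to-onset intervals, so peak detection recovers the
#' pulse-interval series to within one sample period.
#'
#' @param beats A `tachogram` data frame (from [simulate_tachogram()]),
#'   or a numeric vector of strictly increasing beat times in seconds.
#' @param shape A [pulse_shape_spec()].
#' @param final_interval Duration (s) of the last rendered beat. Defaults
#'   to the beat's own `pi_ms` when `beats` is a tachogram, else to the
#'   median interval (0.15 s for a single plain beat time).
#' @return A [pressure_waveform()] sampled at `shape$sampling_rate`,
#'   starting at the first beat onset.
#' @export
render_waveform <- function(beats, shape, final_interval = NULL) {
  stopifnot(inherits(shape, "pulse_shape_spec"))
  if (is.data.frame(beats)) {
    times <- beats$time_s
    pi_ms <- beats$pi_ms
  } else {
    times <- as.numeric(beats)
    pi_ms <- NULL
  }
  n <- length(times)
  if (n < 1) stop_bad("no beats to render")
  if (n >= 2 && any(diff(times) <= 0)) stop_bad("beat times must be strictly increasing")
  if (is.null(final_interval)) {
    final_interval <- if (!is.null(pi_ms)) {
      pi_ms[n] / 1000
    } else if (n >= 2) {
      median(diff(times))
    } else {
      0.15
    }
  }
  ivl <- c(diff(times), final_interval)
  rate <- shape$sampling_rate
  if (min(ivl) * rate < 10) {
    stop_bad("sampling_rate %g Hz gives < 10 samples for a %.1f ms beat",
             rate, min(ivl) * 1000)
  }
  u <- shape$upstroke_fraction * min(ivl)
  total <- times[n] + ivl[n] - times[1]
  ns <- floor(total * rate)
  tt <- times[1] + (seq_len(ns) - 1) / rate
  b <- findInterval(tt, times)
  phi <- tt - times[b]
  len <- ivl[b]
  amp <- shape$sap - shape$dap
  p <- numeric(ns)
  up <- phi <= u
  p[up] <- shape$dap + amp * 0.5 * (1 - cos(pi * phi[up] / u))
  cc <- 4  # decay shape constant; value at next onset rescaled to DAP exactly
  xx <- (phi[!up] - u) / (len[!up] - u)
  p[!up] <- shape$dap + amp * (exp(-cc * xx) - exp(-cc)) / (1 - exp(-cc))
  pressure_waveform(p, rate, start_time = times[1])
}
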