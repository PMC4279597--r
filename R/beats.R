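#' Detect beats in an arterial pressure waveform
#'
#' Finds systolic peaks as prominence-thresholded local maxima with a
#' refractory period, then derives per-beat systolic (SAP), diastolic
#' (DAP) and mean (MAP) arterial pressure and pulse interval (PI). DAP is
#' the minimum between the preceding and the current systolic peak (from
#' the start of the record for the first beat), MAP the time-average of
#' the waveform over the same interval, and PI the peak-to-peak interval
#' in ms (undefined for the first beat).
#'
#' A candidate local maximum is kept when (a) it is at least `min_pi`
#' after the previous accepted peak and (b) the waveform dips at least
#' `prominence` mmHg below the smaller of the two peaks between them;
#' candidates closer than the refractory period, or not separated by a
#' sufficiently deep valley, are merged into the taller peak. The
#' defaults (80 ms, 20 mmHg) suit large-amplitude arterial pulses at rat
#' heart rates; both are exposed for other signals.
#'
#' @param wave A [pressure_waveform()].
#' @param min_pi Refractory period in ms (> 0).
#' @param prominence Minimum peak prominence in mmHg (> 0).
#' @return A data frame of class `beat_series` with columns `time_s`
#'   (systolic peak time), `sap`, `dap`, `map` (mmHg) and `pi_ms`
#'   (`NA` for the first beat).
#' @export
detect_beats <- function(wave, min_pi = 80, prominence = 20) {
  stopifnot(inherits(wave, "pressure_waveform"))
  if (min_pi <= 0) stop_bad("min_pi must be > 0")
  if (prominence <= 0) stop_bad("prominence must be > 0")
  x <- wave$pressure
  if (any(!is.finite(x))) stop_bad("waveform contains non-finite samples")
  rate <- wave$sampling_rate
  gap <- max(1L, as.integer(round(min_pi / 1000 * rate)))

  dx <- diff(x)
  nd <- length(dx)
  cand <- which(dx[-nd] > 0 & dx[-1] <= 0) + 1L
  cand <- cand[x[cand] >= min(x) + prominence]
  if (length(cand) < 2L) stop_bad("insufficient beats: fewer than 2 prominent peaks")

  pk <- integer(length(cand))
  np <- 1L
  pk[1] <- cand[1]
  valley <- Inf   # running min of x since the current last peak
  prev <- cand[1]
  for (ci in cand[-1]) {
    valley <- min(valley, min(x[(prev + 1L):ci]))
    prev <- ci
    lastpk <- pk[np]
    if (ci - lastpk < gap) {
      if (x[ci] > x[lastpk]) {
        pk[np] <- ci
        valley <- Inf
      }
    } else if (valley <= min(x[ci], x[lastpk]) - prominence) {
      np <- np + 1L
      pk[np] <- ci
      valley <- Inf
    } else if (x[ci] > x[lastpk]) {
      pk[np] <- ci
      valley <- Inf
    }
  }
  pk <- pk[seq_len(np)]
  if (np < 2L) stop_bad("insufficient beats: fewer than 2 detected")

  sap <- x[pk]
  dap <- numeric(np)
  map <- numeric(np)
  lo <- c(1L, pk[-np])
  for (k in seq_len(np)) {
    seg <- x[lo[k]:pk[k]]
    dap[k] <- min(seg)
    map[k] <- mean(seg)
  }
  structure(data.frame(
    time_s = wave$start_time + (pk - 1L) / rate,
    sap = sap, dap = dap, map = map,
    pi_ms = c(NA_real_, diff(pk) / rate * 1000)
  ), class = c("beat_series", "data.frame"))
}

#' Summarize hemodynamics over a beat series
#'
#' Arithmetic means of SAP, DAP and MAP over all beats, plus heart rate
#' as `60000 / mean(PI)` in bpm.
#'
#' @param beats A `beat_series` from [detect_beats()].
#' @return An object of class `hemodynamic_summary`: list with `sap`,
#'   `dap`, `map` (mmHg), `hr` (bpm), `mean_pi` (ms), `n_beats`,
#'   `duration` (s).
#' @export
summarize_hemodynamics <- function(beats) {
  if (is.null(beats) || nrow(beats) < 2) stop_bad("need at least 2 beats")
  mean_pi <- mean(beats$pi_ms, na.rm = TRUE)
  structure(list(
    sap = mean(beats$sap), dap = mean(beats$dap), map = mean(beats$map),
    mean_pi = mean_pi, hr = 60000 / mean_pi,
    n_beats = nrow(beats),
    duration = beats$time_s[nrow(beats)] - beats$time_s[1]
  ), class = "hemodynamic_summary")
}

#' @export
print.hemodynamic_summary <- function(x, ...) {
  cat(sprintf(
    "hemodynamics: SAP %.1f / DAP %.1f / MAP %.1f mmHg, HR %.1f bpm (%d beats, %.1f s)\n",
    x$sap, x$dap, x$map, x$hr, x$n_beats, x$duration))
  invisible(x)
}

#' Split a beat series into consecutive analysis segments
#'
#' Returns `n_seg` contiguous, non-overlapping windows of `seg_len`
#' seconds starting at the first beat (plus `offset`), as used for
#' variability analysis (e.g. three 5-min series per animal from a
#' 30-min record). The record must span at least `n_seg * seg_len`
#' seconds (within one median beat interval, so a record that exactly
#' tiles is accepted).
#'
#' @param beats A `beat_series`.
#' @param seg_len Segment length in seconds.
#' @param n_seg Number of segments.
#' @param offset Start offset from the first beat, in seconds.
#' @return A list of class `beat_segments`; each element is the subset of
#'   the beat series whose systolic times fall in the window.
#' @export
extract_segments <- function(beats, seg_len = 300, n_seg = 3, offset = 0) {
  if (seg_len <= 0 || n_seg < 1) stop_bad("seg_len and n_seg must be positive")
  t0 <- beats$time_s[1] + offset
  t_end <- beats$time_s[nrow(beats)]
  slack <- median(diff(beats$time_s))
  span <- t_end - t0 + slack
  need <- n_seg * seg_len
  if (span < need) {
    stop_bad("record spans %.1f s from offset but %d x %g s = %g s are required",
             t_end - t0, n_seg, seg_len, need)
  }
  segs <- vector("list", n_seg)
  for (k in seq_len(n_seg)) {
    lo <- t0 + (k - 1) * seg_len
    hi <- lo + seg_len
    sub <- beats[beats$time_s >= lo & beats$time_s < hi, , drop = FALSE]
    if (nrow(sub) < 2) stop_bad("segment %d contains fewer than 2 beats", k)
    segs[[k]] <- sub
  }
  structure(segs, class = "beat_segments")
}
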