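#' Specification for a simulated tachogram
#'
#' Describes a beat-interval (pulse interval, PI) series with additive
#' low-frequency and high-frequency sinusoidal modulation plus white
#' beat-to-beat noise. In conscious rats the LF band (0.20-0.75 Hz)
#' carries predominantly sympathetic vascular/cardiac modulation and the
#' HF band (0.75-4.0 Hz) respiratory-linked vagal modulation; the
#' defaults (base PI 150 ms, i.e. 400 bpm, LF at 0.4 Hz, HF at 1.5 Hz)
#' sit inside those bands.
#'
#' @param base_pi Mean pulse interval in ms (> 0).
#' @param amp_lf,amp_hf Amplitudes (ms, >= 0) of the LF and HF sinusoidal
#'   PI modulations.
#' @param freq_lf,freq_hf Modulation frequencies in Hz; `0 < freq_lf <
#'   freq_hf` is required.
#' @param noise_sd SD (ms, >= 0) of white beat-to-beat noise added to PI.
#' @param duration Recording duration in seconds (> 0).
#' @param seed Optional integer seed; identical spec + seed gives
#'   identical output.
#' @return An object of class `tachogram_spec`.
#' @export
tachogram_spec <- function(base_pi = 150, amp_lf = 0, freq_lf = 0.4,
                           amp_hf = 0, freq_hf = 1.5, noise_sd = 0,
                           duration = 300, seed = NULL) {
  if (base_pi <= 0) stop_bad("base_pi must be > 0 (got %g)", base_pi)
  if (amp_lf < 0 || amp_hf < 0) stop_bad("modulation amplitudes must be >= 0")
  if (!(freq_lf > 0 && freq_lf < freq_hf)) {
    stop_bad("need 0 < freq_lf < freq_hf (got %g, %g)", freq_lf, freq_hf)
  }
  if (noise_sd < 0) stop_bad("noise_sd must be >= 0")
  if (duration <= 0) stop_bad("duration must be > 0")
  if (amp_lf + amp_hf + 3 * noise_sd >= base_pi) {
    stop_bad(paste0("amp_lf + amp_hf + 3*noise_sd must be < base_pi ",
                    "(%g + %g + 3*%g >= %g): risk of non-positive intervals"),
             amp_lf, amp_hf, noise_sd, base_pi)
  }
  structure(list(base_pi = base_pi, amp_lf = amp_lf, freq_lf = freq_lf,
                 amp_hf = amp_hf, freq_hf = freq_hf, noise_sd = noise_sd,
                 duration = duration, seed = seed),
            class = "tachogram_spec")
}

#' Simulate a tachogram (beat times and pulse intervals)
#'
#' Beat times are generated by an integrate-and-fire rule on the
#' modulated pulse interval: `t[k+1] = t[k] + PI(t[k])`, with
#' `PI(t) = base_pi + amp_lf*sin(2*pi*freq_lf*t) +
#' amp_hf*sin(2*pi*freq_hf*t) + noise`. This preserves the injected
#' modulation frequencies to first order, so a pure sinusoid of
#' amplitude A contributes close to A^2/2 to the PI variance and lands
#' in its own spectral band.
#'
#' @param spec A [tachogram_spec()].
#' @return A data frame of class `tachogram` with columns `time_s` (beat
#'   time, strictly increasing, starting at 0) and `pi_ms` (the
#'   modulated PI evaluated at that beat; `time_s[k+1] - time_s[k]`
#'   equals `pi_ms[k]/1000`).
#' @export
simulate_tachogram <- function(spec) {
  stopifnot(inherits(spec, "tachogram_spec"))
  with_seed(spec$seed, {
    n_guess <- ceiling(spec$duration / (spec$base_pi / 1000)) + 16L
    times <- numeric(n_guess)
    pis <- numeric(n_guess)
    t <- 0
    k <- 0L
    w_lf <- 2 * pi * spec$freq_lf
    w_hf <- 2 * pi * spec$freq_hf
    while (t <= spec$duration) {
      k <- k + 1L
      if (k > length(times)) {  # noise can shorten intervals
        times <- c(times, numeric(n_guess))
        pis <- c(pis, numeric(n_guess))
      }
      p <- spec$base_pi +
        spec$amp_lf * sin(w_lf * t) +
        spec$amp_hf * sin(w_hf * t)
      if (spec$noise_sd > 0) p <- p + rnorm(1L, 0, spec$noise_sd)
      if (p <= 0) {
        stop_bad("simulated pulse interval <= 0 at t = %.3f s; spec too noisy", t)
      }
      times[k] <- t
      pis[k] <- p
      t <- t + p / 1000
    }
    structure(data.frame(time_s = times[seq_len(k)], pi_ms = pis[seq_len(k)]),
              class = c("tachogram", "data.frame"))
  })
}
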