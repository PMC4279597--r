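#' Simulate an insulin tolerance test (ITT) glucose curve
#'
#' Blood glucose after an insulin bolus follows first-order decline
#' `G(t) = g0 * exp(-k t)`; the curve is sampled at the protocol's fixed
#' times (baseline and 4, 8, 12, 16 minutes) with optional additive
#' measurement noise.
#'
#' @param g0 Baseline glucose in mg/dL (> 0).
#' @param k First-order disappearance rate in 1/min (>= 0). The true
#'   KITT equals `100 * k` %/min.
#' @param noise_sd SD of additive measurement noise in mg/dL (>= 0).
#' @param seed Optional integer seed.
#' @param times Sampling times in minutes (strictly increasing from 0).
#' @return A data frame of class `itt_curve` with columns `time_min` and
#'   `glucose_mg_dl`.
#' @seealso [compute_kitt()]
#' @export
simulate_itt <- function(g0, k, noise_sd = 0, seed = NULL,
                         times = c(0, 4, 8, 12, 16)) {
  if (g0 <= 0) stop_bad("g0 must be > 0")
  if (k < 0) stop_bad("k must be >= 0")
  if (noise_sd < 0) stop_bad("noise_sd must be >= 0")
  if (times[1] != 0 || any(diff(times) <= 0)) {
    stop_bad("times must be strictly increasing and start at 0")
  }
  with_seed(seed, {
    g <- g0 * exp(-k * times)
    if (noise_sd > 0) g <- g + rnorm(length(times), 0, noise_sd)
    if (any(g <= 0)) stop_bad("simulated glucose <= 0; reduce noise_sd")
    structure(data.frame(time_min = times, glucose_mg_dl = g),
              class = c("itt_curve", "data.frame"))
  })
}
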