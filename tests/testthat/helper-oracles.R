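# Brute-force O(n^2) DFT periodogram, normalized like compute_psd();
# independent oracle for the FFT path on short series.
dft_psd_oracle <- function(x, rate) {
  n <- length(x)
  half <- n %/% 2
  j <- seq_len(half)
  X <- vapply(j, function(jj) {
    sum(x * exp(-2i * pi * jj * (0:(n - 1)) / n))
  }, complex(1))
  fac <- rep(2, half)
  if (n %% 2 == 0) fac[half] <- 1
  dfreq <- rate / n
  list(frequencies = j * dfreq, psd = fac * Mod(X)^2 / (n^2 * dfreq),
       df = dfreq)
}

dft_band_oracle <- function(x, rate, lo, hi) {
  o <- dft_psd_oracle(x, rate)
  sel <- o$frequencies >= lo & o$frequencies < hi
  sum(o$psd[sel]) * o$df
}

# Wrap a tachogram as a single analysis segment (PI channel only).
tachogram_segment <- function(tac) {
  list(data.frame(time_s = tac$time_s, pi_ms = tac$pi_ms))
}

# Printed group summaries used across tests (systolic pressure and
# cardiac TNF-alpha rows of the reference study; n = 8 per group).
sap_summary <- function() {
  group_summary(c("H", "HO", "FHO"), c(174, 183, 206), c(5, 6, 4), c(8, 8, 8))
}
tnf_summary <- function() {
  group_summary(c("H", "HO", "FHO"), c(32.9, 31.7, 65.8), c(7.5, 8.6, 9.9),
                c(8, 8, 8))
}
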