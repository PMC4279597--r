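# cardivar

Cardiovascular-autonomic and metabolic analysis for rodent hypertension
studies, with a synthetic-data generator that makes every stage testable
against known ground truth.

Protocols that combine genetic hypertension (SHR), ovariectomy and
dietary fructose overload quantify their outcomes through a standard
computational chain: beat-to-beat analysis of directly recorded arterial
pressure, time- and frequency-domain variability of the pulse-interval
(HRV) and systolic-pressure (BPV) series, insulin sensitivity from the
insulin tolerance test, caloric-intake accounting, and group comparison
by one-way ANOVA with Student–Newman–Keuls (SNK) post hoc tests.
`cardivar` implements that chain as composable, tested R functions.

## What it computes

**Beat analysis.** Systolic peaks are detected in the raw pressure trace
as prominence-thresholded local maxima with a refractory period; each
beat carries SAP (peak), DAP (minimum since the previous peak), MAP
(time-average of the waveform over the beat) and the pulse interval
PI(k) = t(k) − t(k−1) in ms. Heart rate is 60000 / mean(PI) bpm.

**Variability.** Per 5-min segment (three per 30-min record), the
PI and SAP beat series are cubic-spline interpolated to 250 Hz,
decimated with an anti-alias low-pass to 10 Hz, linearly detrended and
Fourier-transformed. The one-sided periodogram is normalized so that its
integral equals the series variance (Parseval); band powers are the
discrete integral over LF (0.20–0.75 Hz) and HF (0.75–4.0 Hz; a
`table2` preset caps HF and total power at 3 Hz). Time-domain SD and VAR
(sample variance) come from the raw beat series. All indices are
averaged across segments.

**Metabolic.** KITT (%/min) is 100·k from the log-linear least-squares
fit of glucose over the 4–16 min post-insulin decline, with glucose
half-life t½ = ln 2 / k. Caloric intake is 2.89 kcal per gram of chow
plus 4.0 kcal per gram of ingested fructose (fluid volume × drinking
water concentration).

**Group statistics.** Mean-centered Levene test, one-way ANOVA in raw or
summary-statistics mode (mean ± SEM with n; exactly equivalent when
summaries come from the raw data), SNK stepwise post hoc using a
studentized-range quantile computed from first principles by
Gauss–Legendre quadrature and root-finding, and Pearson correlation.

**Synthetic data.** Tachograms with sinusoidal LF/HF modulation by an
integrate-and-fire rule (a modulation of amplitude A contributes A²/2 to
PI variance, landing in its own band); pressure pulses with exact SAP/DAP
extrema; exponential ITT curves; multivariate-normal cohorts with target
correlations. The generator's defaults are rat-like: 150 ms base PI
(400 bpm), LF at 0.4 Hz, HF at 1.5 Hz, 2 kHz waveform sampling.

## Worked example

```r
library(cardivar)

tac  <- simulate_tachogram(tachogram_spec(base_pi = 150, amp_lf = 4, amp_hf = 5,
                                          noise_sd = 2, duration = 1800, seed = 42))
wave <- render_waveform(tac, pulse_shape_spec(sap = 206, dap = 153,
                                              sampling_rate = 2000))
beats <- detect_beats(wave, min_pi = 80, prominence = 20)
summarize_hemodynamics(beats)
#> hemodynamics: SAP 206.0 / DAP 153.0 / MAP 169.3 mmHg, HR 400.4 bpm (12012 beats, 1799.9 s)

analyze_variability(extract_segments(beats, seg_len = 300, n_seg = 3),
                    bands = "table2")
#> HRV: SD 5.02 ms, VAR 25.24 ms^2, LF 9.125, HF 14.816, total 23.941 (3 segments)
#> BPV: SD 0.01 mmHg, VAR 0.00 mmHg^2, LF 0.000, HF 0.000, total 0.000 (3 segments)
```

The detector recovers every one of the 12012 simulated beats, the
injected 206/153 mmHg pulse exactly, and 400 bpm from the 150 ms base
PI. The HRV LF power (9.1 ms²) is the injected 4 ms LF sinusoid
(4²/2 = 8 ms²) plus the share of the 2 ms white beat-to-beat noise
falling in 0.20–0.75 Hz; HF (14.8 ms²) likewise sits on the injected
5²/2 = 12.5 ms². BPV is ~0 because this pulse generator renders a fixed
beat amplitude.

```r
compute_kitt(simulate_itt(100, 0.034, noise_sd = 2, seed = 1))
#> KITT 3.17 %/min (glucose t1/2 21.84 min; log fit over 4-16 min)

caloric_intake(14.0, 82.9, 100)       # chow g/day, fluid mL/day, fructose g/L
#>   chow_kcal fructose_g fructose_kcal total_kcal
#> 1     40.46       8.29         33.16      73.62

snk_posthoc(group_summary(c("H","HO","FHO"), c(174,183,206), c(5,6,4), c(8,8,8)))
#>   group_a group_b mean_diff    q r q_crit significant
#> 1      HO       H         9 1.78 2   2.94       FALSE
#> 2     FHO       H        32 6.32 3   3.56        TRUE
#> 3     FHO      HO        23 4.54 2   2.94        TRUE
```

The last call reproduces, from the printed systolic-pressure summary
row alone (mean ± SEM, n = 8), the marker pattern of the source table:
the fructose-overloaded ovariectomized group differs from both others
while ovariectomy alone does not reach significance.

`run_study()` orchestrates the whole chain over configured groups
(either full waveform simulation per animal, or direct cohort draws
from summary statistics) and renders study-style tables with
"vs group" significance markers; `inst/cli/cardivar.R` exposes the
same steps as shell subcommands.

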