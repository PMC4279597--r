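---
title: "Methods: signal chain, estimators and design choices in cardivar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal chain, estimators and design choices in cardivar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`cardivar` implements the computational chain of rodent
hypertension/menopause/fructose protocols: beat-to-beat arterial
pressure analysis, heart-rate (HRV) and systolic-pressure (BPV)
variability, KITT insulin sensitivity, caloric-intake accounting, and
the ANOVA/Student–Newman–Keuls group-comparison layer, plus a synthetic
generator that supplies ground truth for all of it. This vignette
records the models, the tunable parameters, the numerical choices, and
what the tests do and do not establish.

## The synthetic generator

**Tachogram.** The pulse-interval process is
PI(t) = PI₀ + A_LF sin(2π f_LF t) + A_HF sin(2π f_HF t) + ε, with white
beat-to-beat noise ε ~ N(0, σ²). Beats are placed by integrate-and-fire:
t(k+1) = t(k) + PI(t(k)). This rule is deterministic given the seed and
preserves the injected modulation frequencies to first order, so a
sinusoid of amplitude A contributes A²/2 (ms²) to PI variance inside its
own band — the analytic ground truth used throughout the spectral
tests. Defaults are rat-like: PI₀ = 150 ms (400 bpm), f_LF = 0.4 Hz,
f_HF = 1.5 Hz, 300 s duration. Specs whose amplitude budget
(A_LF + A_HF + 3σ) reaches PI₀ are rejected at construction, and any
realized PI ≤ 0 aborts the simulation.

**Pressure pulses.** Each beat is a raised-cosine upstroke from DAP to
SAP followed by an exponential decay rescaled to land on DAP exactly at
the next onset. The upstroke duration is a *fixed time* —
`upstroke_fraction` × the shortest interval in the train — rather than a
fraction of each beat, so systolic peaks are separated by exactly the
onset-to-onset intervals and a peak detector can recover the PI series
to within one sample period even under modulation. The decay constant
(4 time constants per diastole) gives an unambiguous per-beat minimum.
This generator renders a *fixed* pulse amplitude per animal: synthetic
BPV is therefore near zero, and BPV band powers are exercised through
the resampling/spectral machinery rather than through a physiological
SAP modulation model.

**ITT curves and cohorts.** Glucose follows G(t) = G₀ e^(−kt) sampled at
0/4/8/12/16 min with optional additive N(0, σ²) noise. Group cohorts are
multivariate normal: summary tables in this field report mean ± SEM with
known n, so SD = SEM·√n; normality is this module's assumption (nothing
stronger is derivable from published summaries). Correlation targets are
assembled into a correlation matrix, checked for positive
semi-definiteness (minimum eigenvalue ≥ −1e−8) and factored by
eigendecomposition, which also handles singular (|r| = 1 or SD = 0)
requests.

## Beat detection

The detector takes prominence-thresholded local maxima with a
refractory period: a candidate peak is accepted when it is at least
`min_pi` (default 80 ms) after the previous accepted peak *and* the
trace dips at least `prominence` (default 20 mmHg) below the smaller of
the two peaks between them; otherwise candidates merge into the taller
peak. The defaults suit large-amplitude arterial pulses at rat heart
rates (~50 mmHg pulse pressure, PI ≥ 120 ms); both are exposed. DAP is
the minimum and MAP the time-average of the waveform between successive
systolic peaks (MAP is measured from the signal, not approximated as
DAP + PP/3); PI is peak-to-peak. Acquisition-device formats and
artifact/ectopy editing are out of scope; the detector is an engineering
choice, not a reconstruction of any particular commercial algorithm.

On noiseless rendered waveforms the round trip is exact in count with
SAP/DAP errors bounded by the sampling quantization (~0.02 mmHg at
2 kHz), and adding 2 mmHg white measurement noise leaves the beat count
unchanged.

## Variability analysis

Records are analyzed as three consecutive non-overlapping 5-min
segments (placement from the start of the record, offset configurable;
a record that exactly tiles is accepted, with one median-beat slack).
Per segment and channel (PI in ms, SAP in mmHg):

1. **Time domain:** VAR is the sample variance (n−1 denominator) of the
   raw beat values, SD its square root. SD and VAR are each averaged
   across segments separately, so reported SD ≠ √(reported VAR) in
   general.
2. **Resampling:** the beat-value vs beat-time function is cubic-spline
   interpolated (Forsythe–Malcolm–Moler end conditions, exact for cubic
   polynomials) onto a 250 Hz grid, then decimated to 10 Hz. The
   anti-alias filter is a linear-phase windowed-sinc FIR (passband edge
   at 0.85 of the new Nyquist, Hamming transition reaching the stopband
   at the new Nyquist), applied with zero phase after odd-reflection
   padding and exact group-delay removal. A zero-phase FIR was chosen
   over the common Chebyshev-IIR decimator because the latter's passband
   ripple costs ~1.7% amplitude (≈3.4% power) at 0.4 Hz and its startup
   transients leak broadband power into the HF band; the FIR path
   recovers a 0.4 Hz modulation to 0.015% and a 1.5 Hz modulation to
   ~1.9% (the residual being beat-domain spline error at ~4.4 samples
   per cycle). 10 Hz output (Nyquist 5 Hz) comfortably covers the 4 Hz
   HF ceiling.
3. **Detrending:** the ordinary least-squares line is subtracted
   (zero mean, zero slope, idempotent). Detrending is a separate stage:
   the periodogram uses its input as-is, because re-detrending inside
   the transform would perturb exact-bin sinusoids at the 1e−3 level
   (the projection of a finite sinusoid sample on the time axis is not
   exactly zero) and break the machine-precision Parseval property.
4. **Spectrum:** one-sided FFT periodogram, rectangular window by
   default (a Hann option is corrected by its mean square so broadband
   Parseval still holds; single-realization Hann Parseval is only
   approximate). Normalization makes the discrete integral of the PSD
   over (0, Nyquist] equal the series' mean squared deviation from its
   mean — the population variance. With this convention Parseval holds
   to machine precision and an exact-bin unit sinusoid integrates to
   0.5 exactly; a sample-variance (n−1) convention would differ by
   n/(n−1), visible at the 1e−4 level for 5-min segments. The
   time-domain VAR keeps the conventional n−1 denominator.
5. **Band powers:** the discrete bin-sum of PSD×Δf over half-open bands
   [lo, hi). Half-open intervals prevent double counting at the shared
   0.75 Hz edge, and the bin-sum is the exact discrete integral, so
   LF + HF + out-of-band power equals total power to ~1e−15 and band
   powers agree with a brute-force O(n²) DFT to the same precision. A
   trapezoid over the in-band samples was rejected because it cannot
   satisfy band additivity and Parseval exactly at shared edges.
6. **Bands:** `methods` preset LF 0.20–0.75 Hz, HF 0.75–4.0 Hz, total
   0.20–4.0 Hz; `table2` preset caps HF and total at 3 Hz. Both are
   offered because the two conventions coexist in published reports of
   this protocol; no attempt is made to guess which one any given study
   actually used. Welch sub-segment averaging is deliberately absent:
   one periodogram per 5-min segment, averaged across the three
   segments, is the closest literal reading of "three time series of
   5 min".

## Metabolic estimators

KITT regresses ln(glucose) on time over the post-injection window
(default 4–16 min, excluding the baseline sample drawn before insulin
acts) and reports 100·k %/min with t½ = ln 2/k; on noiseless
exponentials the estimator is exact for any k > 0 and it is invariant
to rescaling the glucose axis. First-order kinetics is what makes
"KITT = 0.693/t½" coherent, so the log-linear reading of the "linear
phase of decline" is the default; a raw-glucose regression mode is
provided and flagged in the output for sensitivity analyses. Slopes ≥ 0
(within 1e−12) are reported as KITT 0, non-declining, rather than as a
negative disappearance rate. Caloric intake is linear:
chow·2.89 + (fluid·concentration/1000)·4.0 kcal/day.

## Group statistics

The Levene test uses mean centering (the original form; median
centering would be the Brown–Forsythe variant, which is not what plain
"Levene test" denotes). One-way ANOVA runs in raw or summary mode;
summary mode reconstructs SS_between from means and n and SS_within
from (n−1)·SD², an algebraic identity with the raw decomposition, which
is what allows published mean ± SEM rows to be analyzed directly.

The SNK procedure sorts the group means, tests each pair spanning r
ordered means with q = Δ/√(MS_within/n) against the upper-α studentized
range quantile for that r, and enforces the defining containment rule:
a pair is significant only if every enclosing range is. Equal n is
assumed (the designs here are balanced, n = 8); unequal n falls back to
the harmonic mean with a warning. The studentized-range quantile is
computed from first principles — the CDF as a Gauss–Legendre quadrature
(160 nodes over z ∈ [−9, 9], and over the scale s = √(χ²_ν/ν) between
its 1e−12 tail quantiles) inverted by `uniroot` — and is cached; it
matches R's `ptukey`/`qtukey` and printed critical-value tables to
better than 0.01, including the analytic r = 2, df = ∞ case
√2·z_{0.975} ≈ 2.772. Exact quadrature quantiles, rather than
interpolated table values, are used as critical values. Under the
complete null with three groups of 8, the familywise type-I error of
the procedure sits at α (measured 0.045–0.055 over 2000 simulations).

## Pipeline

`run_study()` runs either mode — `cohort` (animals drawn from
summary-statistics populations) or `waveform` (full signal chain per
animal) — aggregates per-group mean ± SEM, and applies Levene, ANOVA
and SNK per variable, rendering "vs group k" markers only where the
ANOVA itself is significant at α. Every animal receives a sub-seed
derived from the study seed and its group/animal index, so reports are
byte-identical across re-runs; the report carries a config hash, the
seed and package versions. A failing animal (e.g. an unusable ITT
curve) is logged and dropped with its group's n decremented; it does
not abort the run. Marker rendering generalizes the †/¥ footnote
convention to named "vs group" columns so more than three groups work.

## Problem sizes used by the tests

Unit tests run the spectral chain on 300-s single segments (~2000
beats), the detector round trip on 30–60 s trains at 1–2 kHz plus one
full 30-min record at 2 kHz, KITT recovery on 500 noisy replicates,
type-I calibration on 2000 null cohorts, and the pipeline Monte-Carlo
on 100 seeds of three 8-animal groups in cohort mode. These sizes give
Monte-Carlo standard errors comfortably inside the asserted tolerances
(e.g. ±0.5% on the type-I rate) while keeping the suite around half a
minute.

## Limitations

- **Marker-pattern reproducibility.** Published group tables are inputs
  (mean ± SEM, n = 8), not raw data. Deterministic summary-mode
  ANOVA/SNK reproduces the printed marker patterns for rows with large
  standardized separations (systolic pressure, TNF-α). But simulating
  cohorts *at* those summaries and re-running the statistics cannot
  reproduce every printed marker: for the diastolic and mean-pressure
  rows the printed FHO-vs-HO difference corresponds to q ≈ 1.8–2.0,
  below any α = 0.05 critical value, so those markers are not
  recoverable from the summaries at all, and marginal pairs
  (q within ~1 of the critical value) reproduce in well under 90% of
  seeds by straightforward power arithmetic. The Monte-Carlo tests
  therefore assert reproduction only for the full-range comparisons
  whose expected q exceeds 5; nothing stronger is claimable from
  summary statistics.
- **Generator realism.** Additive sinusoids plus white noise emulate
  band-limited autonomic modulation, not baroreflex closed-loop
  dynamics, respiratory–cardiac coupling beyond a fixed HF tone,
  ectopy, or beat-to-beat pulse-amplitude variation (hence near-zero
  synthetic BPV). Passing recovery tests shows the *analysis chain* is
  correct and calibrated; it does not validate any physiological model
  of real recordings.
- **Spectral conventions.** Results depend on the band preset (4 Hz vs
  3 Hz HF ceiling), on the rectangular-window single-periodogram
  choice, and on the 10 Hz resampling rate; all are configurable, and
  cross-study comparisons should match conventions before comparing
  LF/HF values.
- **HF recovery floor.** At 1.5 Hz the beat series itself (≈6.7 Hz
  sampling) limits spline reconstruction to ~2% power accuracy;
  modulations closer to the 4 Hz band edge would degrade further at rat
  heart rates.
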