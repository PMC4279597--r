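Package: cardivar
Title: Beat-to-Beat Arterial Pressure, Cardiovascular Variability and
    Metabolic Indices for Rodent Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the cardiovascular-autonomic and metabolic workup
    used in rodent hypertension studies: beat detection on raw arterial
    pressure waveforms with per-beat systolic, diastolic, mean pressure
    and pulse interval; time-domain (SD, variance) and frequency-domain
    (LF, HF band power) variability of pulse-interval and systolic
    pressure series via cubic-spline resampling, linear detrending and
    FFT periodograms; the KITT insulin-sensitivity estimator from
    insulin tolerance test glucose curves and caloric-intake accounting
    for chow plus fructose-supplemented drinking water; a group-comparison
    layer (Levene test, one-way ANOVA in raw or summary-statistics mode,
    Student-Newman-Keuls post hoc with a quadrature-based studentized
    range quantile, Pearson correlation); and a synthetic-data generator
    (modulated tachograms, rendered pressure pulses, exponential ITT
    curves, correlated group cohorts) providing ground truth for every
    stage. A study pipeline orchestrates simulation, per-animal analysis,
    group aggregation and report rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
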