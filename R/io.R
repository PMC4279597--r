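#' Write / read an arterial pressure waveform as delimited text
#'
#' Two tab-separated columns (`time_s`, `pressure_mmhg`) with a one-line
#' header. On reading, the sampling rate is recovered from the time
#' column, which must be uniform.
#'
#' @param wave A [pressure_waveform()].
#' @param path File path.
#' @return `write_waveform` returns `path` invisibly; `read_waveform`
#'   returns a `pressure_waveform`.
#' @export
write_waveform <- function(wave, path) {
  stopifnot(inherits(wave, "pressure_waveform"))
  tt <- wave$start_time + (seq_along(wave$pressure) - 1) / wave$sampling_rate
  write.table(data.frame(time_s = tt, pressure_mmhg = wave$pressure),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t")
  dt <- diff(d$time_s)
  if (max(dt) - min(dt) > 1e-6 * median(dt)) {
    stop_bad("waveform time column is not uniformly sampled")
  }
  pressure_waveform(d$pressure_mmhg, 1 / median(dt), start_time = d$time_s[1])
}

#' Write / read a beat series as delimited text
#'
#' Tab-separated columns `time_s`, `sap`, `dap`, `map`, `pi_ms`.
#'
#' @param beats A `beat_series` from [detect_beats()].
#' @param path File path.
#' @return `write_beats` returns `path` invisibly; `read_beats` returns a
#'   `beat_series`.
#' @export
write_beats <- function(beats, path) {
  write.table(as.data.frame(beats), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_beats
#' @export
read_beats <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t")
  structure(d, class = c("beat_series", "data.frame"))
}

#' Read an ITT glucose curve from delimited text
#'
#' Expects columns `time_min` and `glucose_mg_dl`.
#'
#' @param path File path (tab- or comma-separated, autodetected).
#' @return An `itt_curve` data frame.
#' @export
read_itt_curve <- function(path) {
  d <- read_delim_auto(path)
  if (!all(c("time_min", "glucose_mg_dl") %in% names(d))) {
    stop_bad("ITT file needs columns time_min, glucose_mg_dl")
  }
  structure(d, class = c("itt_curve", "data.frame"))
}

#' Read per-animal intake records from delimited text
#'
#' Expects columns `animal`, `chow_g`, `fluid_ml`, `fructose_g_per_l`.
#'
#' @param path File path (tab- or comma-separated, autodetected).
#' @return A data frame of intake records.
#' @export
read_intake <- function(path) {
  d <- read_delim_auto(path)
  need <- c("animal", "chow_g", "fluid_ml", "fructose_g_per_l")
  if (!all(need %in% names(d))) {
    stop_bad("intake file needs columns %s", paste(need, collapse = ", "))
  }
  d
}

read_delim_auto <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}

#' Reference group-summary table (SHR fructose/ovariectomy study)
#'
#' Published group summary statistics (mean +/- SEM, n = 8 per group)
#' from a study of fructose overload in ovariectomized spontaneously
#' hypertensive rats: metabolic panel, intake, hemodynamics, pulse
#' interval and systolic pressure variability, cardiac inflammatory
#' markers and oxidative-stress panel for the hypertensive (H),
#' hypertensive ovariectomized (HO) and fructose-overloaded hypertensive
#' ovariectomized (FHO) groups. The `sig_vs_H` / `sig_vs_HO` columns
#' carry the published significance markers (P < 0.05). These summaries
#' serve as simulator targets and as inputs to the summary-statistics
#' ANOVA/SNK mode; the underlying per-animal recordings are not
#' available.
#'
#' @return Data frame with columns `panel`, `variable`, `unit`, `group`,
#'   `mean`, `sem`, `n`, `sig_vs_H`, `sig_vs_HO`.
#' @export
shr_fructose_summary <- function() {
  path <- system.file("extdata", "shr_fructose_summary.tsv",
                      package = "cardivar", mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
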