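`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a study configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file describing the
#'   study (see [run_study()] for the expected fields).
#' @return The configuration as a named list.
#' @export
read_study_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    cfg <- yaml::read_yaml(path)
    # YAML 1.1 resolves a bare `n` key to boolean FALSE; restore it
    cfg$groups <- lapply(cfg$groups, function(g) {
      if (!("n" %in% names(g))) names(g)[names(g) == "FALSE"] <- "n"
      g
    })
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    stop_bad("config must be .yaml/.yml or .json: %s", path)
  }
  validate_study_config(cfg)
  cfg
}

validate_study_config <- function(cfg) {
  if (is.null(cfg$groups) || length(cfg$groups) < 1) stop_bad("config needs groups")
  nms <- vapply(cfg$groups, function(g) g$name %||% "", "")
  if (any(nms == "")) stop_bad("every group needs a name")
  if (anyDuplicated(nms)) stop_bad("group names must be unique")
  invisible(cfg)
}

# Draw a per-animal parameter: `<name>` is the group-level mean and
# optional `<name>_sd` the between-animal SD.
draw_param <- function(params, name, default) {
  m <- params[[name]] %||% default
  s <- params[[paste0(name, "_sd")]] %||% 0
  if (s > 0) rnorm(1, m, s) else m
}

process_animal_waveform <- function(gspec, cfg, aseed) {
  tp <- gspec$tachogram %||% list()
  sp <- gspec$shape %||% list()
  with_seed(aseed, {
    base_pi <- draw_param(tp, "base_pi", 150)
    amp_lf <- draw_param(tp, "amp_lf", 2)
    amp_hf <- draw_param(tp, "amp_hf", 3)
    noise_sd <- tp$noise_sd %||% 2
    sap <- draw_param(sp, "sap", 180)
    dap <- draw_param(sp, "dap", 120)
    itt <- gspec$itt %||% list()
    g0 <- draw_param(itt, "g0", 100)
    kk <- max(draw_param(itt, "k", 0.04), 1e-4)
    itt_noise <- itt$noise_sd %||% 0
    intake <- gspec$intake %||% list()
    chow <- max(draw_param(intake, "chow_g", 15), 0)
    fluid <- max(draw_param(intake, "fluid_ml", 25), 0)
    conc <- intake$fructose_g_per_l %||% 0
  })
  spec <- tachogram_spec(
    base_pi = base_pi, amp_lf = amp_lf, freq_lf = tp$freq_lf %||% 0.4,
    amp_hf = amp_hf, freq_hf = tp$freq_hf %||% 1.5, noise_sd = noise_sd,
    duration = gspec$duration %||% cfg$duration %||% 1800,
    seed = derive_seed(aseed, 1L))
  tac <- simulate_tachogram(spec)
  shape <- pulse_shape_spec(sap = sap, dap = dap,
                            sampling_rate = cfg$sampling_rate %||% 2000)
  wave <- render_waveform(tac, shape)
  beats <- detect_beats(wave, min_pi = cfg$min_pi %||% 80,
                        prominence = cfg$prominence %||% 20)
  hemo <- summarize_hemodynamics(beats)
  segs <- extract_segments(beats, seg_len = cfg$seg_len %||% 300,
                           n_seg = cfg$n_seg %||% 3)
  vr <- analyze_variability(segs, bands = cfg$band_preset %||% "methods")
  curve <- simulate_itt(g0, kk, noise_sd = itt_noise,
                        seed = derive_seed(aseed, 2L))
  kitt <- compute_kitt(curve, window = unlist(cfg$itt_window %||% c(4, 16)))
  cal <- caloric_intake(chow, fluid, conc)
  c(sap = hemo$sap, dap = hemo$dap, map = hemo$map, hr = hemo$hr,
    hrv_sd = vr$hrv$sd, hrv_var = vr$hrv$var,
    hrv_lf = vr$hrv$lf, hrv_hf = vr$hrv$hf,
    bpv_var = vr$bpv$var, bpv_lf = vr$bpv$lf,
    kitt = kitt$kitt, caloric_intake = cal$total_kcal)
}

animals_waveform_group <- function(gspec, cfg, gidx, log) {
  n <- gspec$n %||% 8
  rows <- list()
  for (a in seq_len(n)) {
    aseed <- derive_seed(cfg$seed %||% 1, gidx, a)
    vals <- tryCatch(process_animal_waveform(gspec, cfg, aseed),
                     error = function(e) {
                       log(sprintf("group %s animal %d failed: %s",
                                   gspec$name, a, conditionMessage(e)))
                       NULL
                     })
    if (!is.null(vals)) {
      rows[[length(rows) + 1]] <-
        data.frame(animal = sprintf("%s_%02d", gspec$name, a),
                   group = gspec$name,
                   variable = names(vals), value = unname(vals))
    }
  }
  do.call(rbind, rows)
}

animals_cohort_group <- function(gspec, cfg, gidx) {
  vars <- gspec$variables
  vt <- data.frame(
    variable = names(vars),
    mean = vapply(vars, function(v) v$mean, 0),
    sd = vapply(vars, function(v) {
      if (!is.null(v$sd)) v$sd else (v$sem %||% 0) * sqrt(gspec$n %||% 8)
    }, 0))
  cors <- NULL
  if (!is.null(gspec$correlations)) {
    cors <- do.call(rbind, lapply(gspec$correlations, function(cc) {
      data.frame(var1 = cc$var1, var2 = cc$var2, r = cc$r)
    }))
  }
  spec <- cohort_spec(gspec$name, vt, gspec$n %||% 8, correlations = cors,
                      seed = derive_seed(cfg$seed %||% 1, gidx))
  simulate_cohort(spec)
}

#' Run a simulated (or summary-driven) study end to end
#'
#' Simulates every group of the study, analyzes each animal, aggregates
#' per-group mean +/- SEM for every computed variable, and runs the
#' statistics layer (Levene, one-way ANOVA, SNK post hoc at `alpha`)
#' across groups. Deterministic for a fixed `seed`: each animal gets a
#' seed derived from the study seed and its group/animal index, so
#' re-running the same configuration reproduces the report exactly.
#'
#' Two simulation modes:
#' \describe{
#'   \item{`mode = "cohort"`}{each group lists `variables` (per-variable
#'     `mean` plus `sem` or `sd`) and optional `correlations`; animals
#'     are drawn directly from the multivariate normal cohort. This is
#'     the mode for exercising published summary tables as simulator
#'     targets.}
#'   \item{`mode = "waveform"`}{each group lists `tachogram`, `shape`,
#'     `itt` and `intake` parameters (each accepting `<name>_sd`
#'     between-animal jitter); every animal runs the full signal chain
#'     (simulate tachogram, render waveform, detect beats, hemodynamic
#'     summary, segment variability) plus ITT and intake analysis. A
#'     failing animal is logged and dropped (group n decremented); it
#'     does not abort the run.}
#' }
#'
#' Top-level config fields: `seed`, `alpha` (default 0.05), `mode`,
#' `groups`, and for waveform mode `duration` (s), `sampling_rate` (Hz),
#' `seg_len`, `n_seg`, `band_preset`, `itt_window`, `min_pi`,
#' `prominence`.
#'
#' @param config A configuration list or a path to a YAML/JSON file
#'   (see [read_study_config()]).
#' @param log_file Optional path; per-stage log lines are appended there
#'   as well as emitted via [message()] when `verbose = TRUE`.
#' @param verbose Emit progress messages.
#' @return An object of class `study_report`: list with `summary`
#'   (variable x group mean/sem/n), `anova` (per-variable F, df, p,
#'   Levene p), `posthoc` (per-variable SNK pairs), `markers`
#'   (per-variable, per-group "differs from group k" flags), `animals`
#'   (long per-animal table), `seed`, `alpha`, `config_hash`, `versions`.
#' @export
run_study <- function(config, log_file = NULL, verbose = FALSE) {
  if (is.character(config)) config <- read_study_config(config)
  validate_study_config(config)
  t0 <- Sys.time()
  log <- function(msg) {
    line <- sprintf("[%.2fs] %s", as.numeric(Sys.time() - t0, units = "secs"), msg)
    if (verbose) message(line)
    if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE)
  }
  mode <- config$mode %||% "cohort"
  alpha <- config$alpha %||% 0.05
  long <- list()
  for (gidx in seq_along(config$groups)) {
    gspec <- config$groups[[gidx]]
    log(sprintf("simulating group %s (mode %s)", gspec$name, mode))
    long[[gidx]] <- if (mode == "waveform") {
      animals_waveform_group(gspec, config, gidx, log)
    } else {
      animals_cohort_group(gspec, config, gidx)
    }
  }
  animals <- do.call(rbind, long)
  group_names <- vapply(config$groups, function(g) g$name, "")
  vars <- unique(animals$variable)

  summary_rows <- list()
  anova_rows <- list()
  posthoc <- list()
  markers <- list()
  for (v in vars) {
    sub <- animals[animals$variable == v, ]
    by_group <- lapply(group_names, function(g) sub$value[sub$group == g])
    names(by_group) <- group_names
    by_group <- by_group[lengths(by_group) > 0]
    for (g in names(by_group)) {
      x <- by_group[[g]]
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        variable = v, group = g, n = length(x), mean = mean(x),
        sem = sd(x) / sqrt(length(x)))
    }
    if (length(by_group) >= 2 && all(lengths(by_group) >= 2)) {
      lev <- levene_test(by_group)
      av <- oneway_anova(by_group)
      ph <- tryCatch(snk_posthoc(by_group, alpha = alpha),
                     error = function(e) {
                       log(sprintf("variable %s: posthoc failed: %s", v,
                                   conditionMessage(e)))
                       NULL
                     })
      anova_rows[[length(anova_rows) + 1]] <- data.frame(
        variable = v, F = av$F, df1 = av$df[1], df2 = av$df[2],
        p = av$p.value, levene_p = lev$p.value)
      if (!is.null(ph)) {
        posthoc[[v]] <- ph
        gn <- names(by_group)
        for (gi in 2:length(gn)) {
          for (hi in seq_len(gi - 1)) {
            sig <- av$p.value <= alpha && snk_significant(ph, gn[gi], gn[hi])
            markers[[length(markers) + 1]] <- data.frame(
              variable = v, group = gn[gi], vs = gn[hi], significant = sig)
          }
        }
      }
    }
  }
  log("statistics complete")
  structure(list(
    summary = do.call(rbind, summary_rows),
    anova = if (length(anova_rows)) do.call(rbind, anova_rows) else NULL,
    posthoc = posthoc,
    markers = if (length(markers)) do.call(rbind, markers) else NULL,
    animals = animals,
    groups = group_names,
    seed = config$seed %||% 1,
    alpha = alpha,
    config_hash = config_hash(config),
    versions = list(cardivar = as.character(packageVersion("cardivar")),
                    R = paste(R.version$major, R.version$minor, sep = "."))
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study_report: %d groups, %d variables, seed %s, config %s\n",
              length(x$groups), length(unique(x$summary$variable)),
              x$seed, x$config_hash))
  cat(paste(render_report(x, format = "markdown"), collapse = "\n"), "\n")
  invisible(x)
}

#' Render a study report as a delimited or Markdown table
#'
#' One row per variable. In `"csv"` format each group contributes
#' `<group>_n`, `<group>_mean`, `<group>_sem` columns at full precision
#' plus `F`, `p` and per-pair marker columns `<group>_vs_<group>`
#' (TRUE/FALSE), so the table can be parsed back with [read_report()].
#' The `"markdown"` format prints `mean +/- SEM` with "vs <group>"
#' markers on significant SNK differences (ANOVA gate at the report's
#' alpha), generalizing the dagger/yen footnote convention of printed
#' group tables.
#'
#' @param report A `study_report` from [run_study()].
#' @param format `"csv"` or `"markdown"`.
#' @param path Optional output file.
#' @return Character vector of lines, invisibly when `path` is given.
#' @export
render_report <- function(report, format = c("csv", "markdown"), path = NULL) {
  format <- match.arg(format)
  s <- report$summary
  vars <- unique(s$variable)
  groups <- report$groups
  if (format == "csv") {
    header <- c("variable",
                unlist(lapply(groups, function(g) paste0(g, c("_n", "_mean", "_sem")))),
                "F", "p")
    mk_cols <- character(0)
    if (length(groups) >= 2) {
      for (gi in 2:length(groups)) {
        for (hi in seq_len(gi - 1)) {
          mk_cols <- c(mk_cols, paste0(groups[gi], "_vs_", groups[hi]))
        }
      }
    }
    header <- c(header, mk_cols)
    lines <- paste(header, collapse = ",")
    for (v in vars) {
      cells <- v
      for (g in groups) {
        row <- s[s$variable == v & s$group == g, ]
        cells <- c(cells, if (nrow(row)) {
          c(row$n, sprintf("%.15g", row$mean), sprintf("%.15g", row$sem))
        } else c(NA, NA, NA))
      }
      arow <- report$anova[report$anova$variable == v, ]
      cells <- c(cells, if (!is.null(arow) && nrow(arow)) {
        c(sprintf("%.15g", arow$F), sprintf("%.15g", arow$p))
      } else c(NA, NA))
      for (mc in mk_cols) {
        parts <- strsplit(mc, "_vs_")[[1]]
        mrow <- report$markers[report$markers$variable == v &
                                 report$markers$group == parts[1] &
                                 report$markers$vs == parts[2], ]
        cells <- c(cells, if (!is.null(mrow) && nrow(mrow)) mrow$significant else NA)
      }
      lines <- c(lines, paste(cells, collapse = ","))
    }
  } else {
    lines <- c(paste(c("| variable |", paste(groups, "|"), " F | p |"), collapse = " "),
               paste(c("|---|", rep("---|", length(groups)), "---|---|"), collapse = ""))
    for (v in vars) {
      cells <- v
      for (g in groups) {
        row <- s[s$variable == v & s$group == g, ]
        cell <- if (nrow(row)) sprintf("%.3g ± %.2g", row$mean, row$sem) else ""
        mrow <- report$markers[report$markers$variable == v &
                                 report$markers$group == g &
                                 report$markers$significant, ]
        if (!is.null(mrow) && nrow(mrow)) {
          cell <- paste0(cell, " [", paste("vs", mrow$vs, collapse = ", "), "]")
        }
        cells <- c(cells, cell)
      }
      arow <- report$anova[report$anova$variable == v, ]
      cells <- c(cells, if (!is.null(arow) && nrow(arow)) {
        c(sprintf("%.3g", arow$F), sprintf("%.3g", arow$p))
      } else c("", ""))
      lines <- c(lines, paste0("| ", paste(cells, collapse = " | "), " |"))
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Parse a CSV study report back into a data frame
#'
#' Round-trips the `"csv"` output of [render_report()].
#'
#' @param path Path to the rendered CSV report.
#' @return Data frame with one row per variable.
#' @export
read_report <- function(path) {
  read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
}
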