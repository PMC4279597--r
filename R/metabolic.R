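#' KITT: constant rate of glucose disappearance from an ITT curve
#'
#' Fits the decline of blood glucose after an insulin bolus over the
#' linear phase (default 4-16 min, excluding the baseline sample taken
#' before insulin acts). The default regresses `ln(glucose)` on time, so
#' first-order kinetics `G(t) = G0 exp(-k t)` give a straight line; the
#' disappearance constant is `k = -slope`, the glucose half-life
#' `t1/2 = ln(2) / k`, and `KITT = 100 k` in %/min (equivalently
#' `0.693 / t1/2` scaled to percent). A non-declining fit (slope >= 0)
#' is reported as KITT 0 with `declining = FALSE` and undefined
#' half-life, since a disappearance rate is non-negative by definition.
#'
#' @param curve An `itt_curve` data frame (columns `time_min`,
#'   `glucose_mg_dl`), e.g. from [simulate_itt()] or [read_itt_curve()].
#' @param window Length-2 numeric, fit window in minutes (inclusive);
#'   at least 3 samples must fall inside.
#' @param regress `"log"` (default; log-linear, first-order kinetics) or
#'   `"raw"` (least squares on raw glucose; half-life taken as the time
#'   for the fitted line to fall to half its window-start value).
#' @return An object of class `itt_result`: list with `kitt` (%/min),
#'   `t_half` (min, `NA` when not declining), `slope`, `intercept`,
#'   `window`, `regress` and `declining`.
#' @export
compute_kitt <- function(curve, window = c(4, 16),
                         regress = c("log", "raw")) {
  regress <- match.arg(regress)
  if (!all(c("time_min", "glucose_mg_dl") %in% names(curve))) {
    stop_bad("curve needs columns time_min, glucose_mg_dl")
  }
  t <- curve$time_min
  g <- curve$glucose_mg_dl
  if (any(diff(t) <= 0)) stop_bad("times must be strictly increasing")
  if (any(g <= 0)) stop_bad("glucose values must be positive")
  sel <- t >= window[1] & t <= window[2]
  if (sum(sel) < 3) stop_bad("need >= 3 samples in window [%g, %g] min",
                             window[1], window[2])
  tw <- t[sel]
  yw <- if (regress == "log") log(g[sel]) else g[sel]
  fit <- lm(yw ~ tw)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (slope >= -1e-12) {  # flat within numerical noise counts as non-declining
    res <- list(kitt = 0, t_half = NA_real_, declining = FALSE)
  } else if (regress == "log") {
    k <- -slope
    res <- list(kitt = 100 * k, t_half = log(2) / k, declining = TRUE)
  } else {
    g_start <- intercept + slope * window[1]
    t_half <- g_start / (2 * (-slope))
    res <- list(kitt = 100 * log(2) / t_half, t_half = t_half,
                declining = TRUE)
  }
  structure(c(res, list(slope = slope, intercept = intercept,
                        window = window, regress = regress)),
            class = "itt_result")
}

#' @export
print.itt_result <- function(x, ...) {
  if (x$declining) {
    cat(sprintf("KITT %.2f %%/min (glucose t1/2 %.2f min; %s fit over %g-%g min)\n",
                x$kitt, x$t_half, x$regress, x$window[1], x$window[2]))
  } else {
    cat(sprintf("KITT 0 %%/min: glucose not declining over %g-%g min\n",
                x$window[1], x$window[2]))
  }
  invisible(x)
}

#' Daily caloric intake from chow and fructose-supplemented water
#'
#' Chow contributes 2.89 kcal per gram consumed; each gram of ingested
#' fructose contributes 4.0 kcal, with the fructose dose computed from
#' fluid intake and the drinking-water fructose concentration.
#' Vectorized over animals.
#'
#' @param chow_g Chow intake in g/day (>= 0).
#' @param fluid_ml Fluid intake in mL/day (>= 0).
#' @param fructose_g_per_l Fructose concentration of the drinking water
#'   in g/L (>= 0; 0 for plain water).
#' @param kcal_chow_per_g,kcal_fructose_per_g Energy densities (kcal/g).
#' @return A data frame with columns `chow_kcal`, `fructose_g`,
#'   `fructose_kcal` and `total_kcal` (kcal/day).
#' @export
caloric_intake <- function(chow_g, fluid_ml = 0, fructose_g_per_l = 0,
                           kcal_chow_per_g = 2.89, kcal_fructose_per_g = 4.0) {
  if (any(chow_g < 0) || any(fluid_ml < 0) || any(fructose_g_per_l < 0)) {
    stop_bad("intake quantities must be >= 0")
  }
  n <- max(length(chow_g), length(fluid_ml), length(fructose_g_per_l))
  chow_g <- rep_len(chow_g, n)
  fluid_ml <- rep_len(fluid_ml, n)
  fructose_g_per_l <- rep_len(fructose_g_per_l, n)
  chow_kcal <- chow_g * kcal_chow_per_g
  fructose_g <- fluid_ml * fructose_g_per_l / 1000
  fructose_kcal <- fructose_g * kcal_fructose_per_g
  data.frame(chow_kcal = chow_kcal, fructose_g = fructose_g,
             fructose_kcal = fructose_kcal,
             total_kcal = chow_kcal + fructose_kcal)
}
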