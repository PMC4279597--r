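#' Levene test of variance homogeneity (mean-centered)
#'
#' Classic Levene W statistic on absolute deviations from the group
#' means, referred to an F(k-1, N-k) distribution. Degenerate inputs in
#' which every centered deviation is identical (0/0) are reported as
#' W = 0, p = 1; a zero denominator with spread between groups gives
#' W = Inf, p = 0.
#'
#' @param groups List of numeric vectors, one per group; >= 2 groups,
#'   each with >= 2 observations.
#' @return List with `statistic` (W), `df` (c(k-1, N-k)) and `p.value`.
#' @export
levene_test <- function(groups) {
  k <- length(groups)
  if (k < 2) stop_bad("need >= 2 groups")
  n <- lengths(groups)
  if (any(n < 2)) stop_bad("every group needs >= 2 observations")
  N <- sum(n)
  z <- lapply(groups, function(g) abs(g - mean(g)))
  zbar_i <- vapply(z, mean, 0)
  zbar <- sum(n * zbar_i) / N
  num <- sum(n * (zbar_i - zbar)^2) / (k - 1)
  den <- sum(vapply(seq_len(k), function(i) sum((z[[i]] - zbar_i[i])^2), 0)) /
    (N - k)
  if (den == 0) {
    W <- if (num == 0) 0 else Inf
    p <- if (num == 0) 1 else 0
  } else {
    W <- num / den
    p <- pf(W, k - 1, N - k, lower.tail = FALSE)
  }
  list(statistic = W, df = c(k - 1, N - k), p.value = p)
}

#' Build a group-summary table
#'
#' @param label Group labels.
#' @param mean Group means.
#' @param sem Standard errors of the means (SD is derived as
#'   `sem * sqrt(n)`).
#' @param n Group sizes (>= 2).
#' @return A data frame of class `group_summary` with columns `label`,
#'   `mean`, `sem`, `n` and derived `sd`.
#' @export
group_summary <- function(label, mean, sem, n) {
  if (any(n < 2)) stop_bad("n must be >= 2")
  if (any(sem < 0)) stop_bad("sem must be >= 0")
  structure(data.frame(label = label, mean = mean, sem = sem, n = n,
                       sd = sem * sqrt(n)),
            class = c("group_summary", "data.frame"))
}

#' One-way analysis of variance (raw data or summary statistics)
#'
#' Standard one-way decomposition. In summary mode the between-group sum
#' of squares is computed from the group means and sizes and the
#' within-group sum of squares as `sum((n_i - 1) sd_i^2)`; when the
#' summaries are computed from raw data the two modes agree exactly
#' (algebraic identity).
#'
#' @param x Either a list of numeric vectors (raw mode) or a data frame
#'   with columns `mean`, `n` and `sd` or `sem` (summary mode; see
#'   [group_summary()]).
#' @return An object of class `oneway_anova`: list with `F`, `df`
#'   (c(between, within)), `p.value`, `ms_between`, `ms_within`,
#'   `means`, `ns` and `mode`.
#' @export
oneway_anova <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("mean", "n") %in% names(x))) {
      stop_bad("summary mode needs columns mean and n")
    }
    sds <- if ("sd" %in% names(x)) x$sd else if ("sem" %in% names(x)) {
      x$sem * sqrt(x$n)
    } else stop_bad("summary mode needs an sd or sem column")
    means <- x$mean
    ns <- x$n
    mode <- "summary"
  } else {
    if (!is.list(x) || length(x) < 2) stop_bad("need >= 2 groups")
    means <- vapply(x, mean, 0)
    ns <- lengths(x)
    sds <- vapply(x, sd, 0)
    mode <- "raw"
  }
  k <- length(means)
  if (k < 2) stop_bad("need >= 2 groups")
  N <- sum(ns)
  df_b <- k - 1
  df_w <- N - k
  if (df_w < 1) stop_bad("no within-group degrees of freedom (N = %d, k = %d)", N, k)
  grand <- sum(ns * means) / N
  ss_b <- sum(ns * (means - grand)^2)
  ss_w <- sum((ns - 1) * sds^2)
  ms_b <- ss_b / df_b
  ms_w <- ss_w / df_w
  Fval <- if (ms_w == 0) {
    if (ms_b == 0) 0 else Inf
  } else ms_b / ms_w
  p <- if (is.infinite(Fval)) 0 else pf(Fval, df_b, df_w, lower.tail = FALSE)
  structure(list(F = Fval, df = c(df_b, df_w), p.value = p,
                 ms_between = ms_b, ms_within = ms_w,
                 means = means, ns = ns, mode = mode),
            class = "oneway_anova")
}

#' @export
print.oneway_anova <- function(x, ...) {
  cat(sprintf("one-way ANOVA (%s mode): F(%d, %d) = %.3f, p = %.4g\n",
              x$mode, x$df[1], x$df[2], x$F, x$p.value))
  invisible(x)
}

#' Pearson correlation with t-test
#'
#' Sample product-moment correlation and the two-sided t-test on n - 2
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3, each with non-zero
#'   variance.
#' @return List with `r`, `t`, `df`, `p.value` and `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_bad("x and y differ in length")
  n <- length(x)
  if (n < 3) stop_bad("need >= 3 paired observations")
  if (var(x) == 0 || var(y) == 0) stop_bad("zero variance in x or y")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  df <- n - 2
  tval <- if (abs(r) == 1) Inf * sign(r) else r * sqrt(df / (1 - r^2))
  p <- if (is.infinite(tval)) 0 else 2 * pt(-abs(tval), df)
  list(r = r, t = tval, df = df, p.value = p, n = n)
}
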