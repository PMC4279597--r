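# Studentized range distribution and the Student-Newman-Keuls stepwise
# procedure. The quantile is computed from first principles: the CDF
# P(Q <= q) = E_s[ r * Int phi(z) (Phi(z) - Phi(z - q s))^(r-1) dz ]
# with s = sqrt(chi2_df / df), evaluated by Gauss-Legendre quadrature
# (inner integral over z, outer over the scale s), and inverted by
# root-finding.

.srange_env <- new.env(parent = emptyenv())

gauss_nodes <- function(n, a, b) {
  key <- sprintf("gl_%d_%.12g_%.12g", n, a, b)
  got <- .srange_env[[key]]
  if (!is.null(got)) return(got)
  gl <- pracma::gaussLegendre(n, a, b)
  .srange_env[[key]] <- gl
  gl
}

#' CDF of the studentized range distribution
#'
#' Probability that the range of `r` independent standard normal means,
#' divided by an independent estimate of their standard error on `df`
#' degrees of freedom, is at most `q`. Evaluated by Gauss-Legendre
#' quadrature; `df = Inf` uses the known-variance form.
#'
#' @param q Quantile (> 0); vectorized.
#' @param r Number of group means spanned (>= 2).
#' @param df Error degrees of freedom (>= 1), may be `Inf`.
#' @param n_nodes Number of quadrature nodes per dimension.
#' @return Probability in `[0, 1]`, one per element of `q`.
#' @export
srange_cdf <- function(q, r, df = Inf, n_nodes = 160) {
  if (r < 2) stop_bad("r must be >= 2")
  if (is.finite(df) && df < 1) stop_bad("df must be >= 1")
  glz <- gauss_nodes(n_nodes, -9, 9)
  phi_z <- dnorm(glz$x)
  Phi_z <- pnorm(glz$x)
  inner <- function(qs) {
    # qs: vector of q*s values; returns inner integral for each
    D <- pnorm(outer(glz$x, qs, `-`))          # Phi(z - q s)
    vals <- (pmax(Phi_z - D, 0))^(r - 1) * (glz$w * phi_z)
    r * colSums(vals)
  }
  one <- function(qq) {
    if (qq <= 0) return(0)
    if (!is.finite(df)) return(min(1, inner(qq)))
    slo <- sqrt(qchisq(1e-12, df) / df)
    shi <- sqrt(qchisq(1 - 1e-12, df) / df)
    gls <- gauss_nodes(n_nodes, slo, shi)
    ldens <- log(2) + (df / 2) * log(df / 2) - lgamma(df / 2) +
      (df - 1) * log(gls$x) - df * gls$x^2 / 2
    min(1, sum(gls$w * exp(ldens) * inner(qq * gls$x)))
  }
  vapply(q, one, 0)
}

#' Upper quantile of the studentized range distribution
#'
#' Solves `P(Q > q) = p` by root-finding on the quadrature-evaluated CDF
#' ([srange_cdf()]); used as the critical value in the
#' Student-Newman-Keuls procedure. For `r = 2, df = Inf` the analytic
#' value is `sqrt(2) * qnorm(1 - p/2)`. Results are cached.
#'
#' @param p Upper-tail probability in (0, 1) (e.g. 0.05).
#' @param r Number of ordered group means spanned (>= 2).
#' @param df Error degrees of freedom (>= 1), may be `Inf`.
#' @return The quantile q, accurate to better than 1e-3.
#' @export
studentized_range_quantile <- function(p, r, df = Inf) {
  if (!(p > 0 && p < 1)) stop_bad("p must be in (0, 1)")
  key <- sprintf("q_%.10g_%d_%g", p, as.integer(r), df)
  got <- .srange_env[[key]]
  if (!is.null(got)) return(got)
  target <- 1 - p
  f <- function(q) srange_cdf(q, r, df) - target
  upper <- 4
  while (f(upper) < 0) {
    upper <- upper * 2
    if (upper > 1e4) stop_bad("studentized range quantile did not converge (p=%g, r=%d, df=%g)",
                              p, r, df)
  }
  res <- uniroot(f, lower = 1e-8, upper = upper, tol = 1e-6)
  .srange_env[[key]] <- res$root
  res$root
}

#' Student-Newman-Keuls post hoc comparisons
#'
#' Stepwise multiple comparisons on the studentized range. Group means
#' are sorted; a pair spanning `r` ordered means is tested with
#' `q = |mean_i - mean_j| / sqrt(ms_within / n)` against the upper-alpha
#' studentized range quantile for that `r`, and -- the defining
#' Newman-Keuls containment rule -- a pair is declared significant only
#' if every enclosing range is itself significant. Unequal group sizes
#' fall back to the harmonic mean n with a warning.
#'
#' @param summaries A [group_summary()] data frame (columns `label`,
#'   `mean`, `n`, and `sd` or `sem`), or a named list of raw numeric
#'   vectors.
#' @param ms_within,df_error Error mean square and degrees of freedom
#'   from the one-way ANOVA; computed from `summaries` when omitted.
#' @param alpha Significance level in (0, 1).
#' @return A data frame of class `snk_posthoc` with one row per pair:
#'   `group_a`, `group_b`, `mean_diff` (a - b), `q`, `r`, `q_crit`,
#'   `significant`; attributes `alpha`, `df_error`, `ms_within`,
#'   `n_effective`, `unequal_n`.
#' @export
snk_posthoc <- function(summaries, ms_within = NULL, df_error = NULL,
                        alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop_bad("alpha must be in (0, 1)")
  if (is.data.frame(summaries)) {
    labels <- as.character(summaries$label)
    means <- summaries$mean
    ns <- summaries$n
    sds <- if ("sd" %in% names(summaries)) summaries$sd else summaries$sem * sqrt(ns)
    anova_in <- data.frame(mean = means, sd = sds, n = ns)
  } else {
    labels <- names(summaries)
    if (is.null(labels)) labels <- paste0("group", seq_along(summaries))
    means <- vapply(summaries, mean, 0)
    ns <- lengths(summaries)
    anova_in <- summaries
  }
  k <- length(means)
  if (k < 2) stop_bad("need >= 2 groups")
  if (is.null(ms_within) || is.null(df_error)) {
    aov_res <- oneway_anova(anova_in)
    if (is.null(ms_within)) ms_within <- aov_res$ms_within
    if (is.null(df_error)) df_error <- aov_res$df[2]
  }
  unequal <- length(unique(ns)) > 1
  n_eff <- if (unequal) {
    warning("unequal group sizes: using harmonic mean n for SNK")
    k / sum(1 / ns)
  } else ns[1]
  se <- sqrt(ms_within / n_eff)

  ord <- order(means)
  m <- means[ord]
  lab <- labels[ord]
  qmat <- matrix(NA_real_, k, k)
  raw_sig <- matrix(FALSE, k, k)
  crit_of_r <- vapply(2:k, function(r) {
    studentized_range_quantile(alpha, r, df_error)
  }, 0)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      qmat[i, j] <- if (se == 0) {
        if (m[j] - m[i] == 0) 0 else Inf
      } else (m[j] - m[i]) / se
      raw_sig[i, j] <- qmat[i, j] > crit_of_r[(j - i + 1) - 1]
    }
  }
  # containment: widest range first; a nonsignificant range blocks all
  # sub-ranges it encloses
  declared <- matrix(FALSE, k, k)
  for (span in seq(k, 2)) {
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      ok <- raw_sig[i, j]
      if (span < k) {
        if (i > 1) ok <- ok && declared[i - 1, j]
        if (j < k) ok <- ok && declared[i, j + 1]
      }
      declared[i, j] <- ok
    }
  }
  rows <- list()
  idx <- 1
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      rows[[idx]] <- data.frame(
        group_a = lab[j], group_b = lab[i],
        mean_diff = m[j] - m[i], q = qmat[i, j],
        r = j - i + 1, q_crit = crit_of_r[(j - i + 1) - 1],
        significant = declared[i, j])
      idx <- idx + 1
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "df_error") <- df_error
  attr(out, "ms_within") <- ms_within
  attr(out, "n_effective") <- n_eff
  attr(out, "unequal_n") <- unequal
  class(out) <- c("snk_posthoc", "data.frame")
  out
}

#' Look up one pairwise SNK call
#'
#' @param posthoc An `snk_posthoc` result.
#' @param a,b Group labels (order-insensitive).
#' @return Logical: is the pair significantly different?
#' @export
snk_significant <- function(posthoc, a, b) {
  hit <- (posthoc$group_a == a & posthoc$group_b == b) |
    (posthoc$group_a == b & posthoc$group_b == a)
  if (!any(hit)) stop_bad("pair %s / %s not found", a, b)
  posthoc$significant[hit][1]
}
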