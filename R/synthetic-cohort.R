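#' Specification of a simulated group cohort
#'
#' Describes one experimental group as a multivariate normal population:
#' per-variable mean and SD plus optional pairwise correlation targets.
#' Group tables in this field are reported as mean +/- SEM with known n,
#' so SD = SEM * sqrt(n); normality is this generator's assumption, not
#' a property of any particular data set.
#'
#' @param name Group label.
#' @param variables Data frame with columns `variable`, `mean`, `sd`
#'   (all SDs >= 0).
#' @param n Number of animals (>= 2).
#' @param correlations Optional data frame with columns `var1`, `var2`,
#'   `r` (|r| <= 1) giving target pairwise correlations; the implied
#'   correlation matrix must be positive semi-definite.
#' @param seed Optional integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(name, variables, n, correlations = NULL, seed = NULL) {
  variables <- as.data.frame(variables)
  if (!all(c("variable", "mean", "sd") %in% names(variables))) {
    stop_bad("variables needs columns variable, mean, sd")
  }
  if (anyDuplicated(variables$variable)) stop_bad("duplicate variable names")
  if (any(variables$sd < 0)) stop_bad("SDs must be >= 0")
  if (n < 2) stop_bad("n must be >= 2")
  if (!is.null(correlations)) {
    correlations <- as.data.frame(correlations)
    if (!all(c("var1", "var2", "r") %in% names(correlations))) {
      stop_bad("correlations needs columns var1, var2, r")
    }
    if (any(abs(correlations$r) > 1)) stop_bad("|r| must be <= 1")
    miss <- setdiff(c(correlations$var1, correlations$var2), variables$variable)
    if (length(miss)) stop_bad("unknown variables in correlations: %s",
                               paste(miss, collapse = ", "))
  }
  structure(list(name = name, variables = variables, n = as.integer(n),
                 correlations = correlations, seed = seed),
            class = "cohort_spec")
}

# Correlation matrix implied by a cohort_spec; errors if not PSD.
cohort_cor_matrix <- function(spec) {
  vars <- spec$variables$variable
  p <- length(vars)
  R <- diag(p)
  dimnames(R) <- list(vars, vars)
  if (!is.null(spec$correlations)) {
    for (i in seq_len(nrow(spec$correlations))) {
      a <- spec$correlations$var1[i]
      b <- spec$correlations$var2[i]
      R[a, b] <- R[b, a] <- spec$correlations$r[i]
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop_bad("requested correlation matrix is not positive semi-definite (min eigenvalue %.3g)",
             min(ev))
  }
  R
}

#' Simulate a group cohort
#'
#' Draws `n` animals from the multivariate normal population described
#' by a [cohort_spec()]: correlated standard normals (eigendecomposition
#' factor of the target correlation matrix) scaled by each variable's SD
#' and shifted by its mean. At large `n`, sample means/SDs converge to
#' the spec and requested pairwise correlations are achieved within
#' Monte-Carlo error.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame of class `cohort` in long format with columns
#'   `animal`, `group`, `variable`, `value`.
#' @seealso [cohort_wide()]
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  R <- cohort_cor_matrix(spec)
  vars <- spec$variables$variable
  p <- length(vars)
  with_seed(spec$seed, {
    ed <- eigen(R, symmetric = TRUE)
    L <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), p)
    Z <- matrix(rnorm(spec$n * p), spec$n, p) %*% t(L)
    X <- sweep(Z, 2, spec$variables$sd, `*`)
    X <- sweep(X, 2, spec$variables$mean, `+`)
    colnames(X) <- vars
    out <- data.frame(
      animal = rep(sprintf("%s_%02d", spec$name, seq_len(spec$n)), p),
      group = spec$name,
      variable = rep(vars, each = spec$n),
      value = as.vector(X)
    )
    structure(out, class = c("cohort", "data.frame"))
  })
}

#' Reshape a long cohort table to wide (one row per animal)
#'
#' @param cohort A long cohort table as returned by [simulate_cohort()]
#'   (columns `animal`, `group`, `variable`, `value`).
#' @return A data frame with `animal`, `group` and one column per variable.
#' @export
cohort_wide <- function(cohort) {
  vars <- unique(cohort$variable)
  animals <- unique(cohort$animal)
  out <- data.frame(animal = animals,
                    group = cohort$group[match(animals, cohort$animal)])
  for (v in vars) {
    sub <- cohort[cohort$variable == v, ]
    out[[v]] <- sub$value[match(animals, sub$animal)]
  }
  out
}
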