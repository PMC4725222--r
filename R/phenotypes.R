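#' First unrotated principal component of a test battery
#'
#' Extracts per-individual scores on the first unrotated principal component
#' of a column-standardised score matrix — the classical construction of a
#' general cognitive factor from a battery of tests. Component scores are the
#' projection of the standardised data onto the unit-norm loading vector
#' (equivalent, up to the rescaling applied here, to the regression method of
#' score estimation), re-standardised to mean 0 / SD 1, and oriented so the
#' component correlates positively with the mean of the standardised tests
#' (higher score = better overall performance).
#'
#' Rows with any missing test are excluded (listwise deletion) and receive
#' `NA` scores.
#'
#' @param scores A numeric matrix or data frame, one column per test
#'   (>= 2 tests, >= 3 complete rows). Non-numeric columns are rejected.
#' @return Numeric vector of factor scores, one per input row (`NA` for
#'   incomplete rows), with the loading vector as attribute `"loadings"`.
#' @examples
#' x <- matrix(rnorm(300), ncol = 3)
#' f <- first_unrotated_pc(x)
#' @export
first_unrotated_pc <- function(scores) {
  x <- as.matrix(scores)
  if (!is.numeric(x)) abort_gwaset("`scores` must be numeric")
  if (ncol(x) < 2L) abort_gwaset("need at least 2 tests for a components analysis")
  cc <- complete.cases(x)
  if (sum(cc) < 3L) abort_gwaset("need at least 3 complete rows")
  xc <- x[cc, , drop = FALSE]
  sds <- apply(xc, 2L, sd)
  if (any(sds < 1e-12)) abort_gwaset("zero-variance test column")
  z <- scale(xc)
  v <- eigen(cor(xc), symmetric = TRUE)$vectors[, 1L]
  f <- as.numeric(z %*% v)
  # orient: positive correlation with mean standardised performance
  if (cor(f, rowMeans(z)) < 0) {
    f <- -f
    v <- -v
  }
  f <- as.numeric(scale(f))
  out <- rep(NA_real_, nrow(x))
  out[cc] <- f
  attr(out, "loadings") <- v
  out
}

#' Age- and sex-adjusted standardised residuals
#'
#' Ordinary least squares of `values` on an intercept, age and sex; returns
#' the residuals divided by their standard deviation. The result has mean 0,
#' SD 1 and zero sample correlation with both covariates.
#'
#' @param values Numeric outcome vector.
#' @param age Numeric covariate (years).
#' @param sex Covariate coded 0/1.
#' @return Numeric vector of standardised residuals (`NA` where `values`
#'   is missing).
#' @export
residualize <- function(values, age, sex) {
  if (length(age) != length(values) || length(sex) != length(values)) {
    abort_gwaset("`values`, `age` and `sex` must have equal length")
  }
  keep <- !is.na(values)
  if (anyNA(age[keep]) || anyNA(sex[keep])) {
    abort_gwaset("missing covariates on rows with observed values")
  }
  if (sd(age[keep]) < 1e-12 && sd(sex[keep]) < 1e-12) {
    abort_gwaset("both covariates are constant (collinear with the intercept)")
  }
  fit <- lm(values ~ age + sex, subset = keep)
  r <- residuals(fit)
  s <- sd(r)
  if (s < 1e-10) {
    abort_gwaset("degenerate residuals: outcome is an exact function of age and sex",
                 class = "gwaset_degenerate_residual")
  }
  out <- rep(NA_real_, length(values))
  out[keep] <- r / s
  out
}

#' Mean composite of two standardised phenotypes
#'
#' Element-wise mean of two phenotype vectors (typically the age/sex-adjusted
#' fluid and crystallised factors), re-standardised to mean 0 / SD 1. Used to
#' represent a general cognitive factor when the two components have been
#' derived separately.
#'
#' @param fluid,crystallised Numeric vectors over the same individuals.
#' @param ids Optional pair of id vectors; if supplied, they must match
#'   element-wise.
#' @return Standardised composite vector (`NA` where either input is
#'   missing).
#' @export
mean_composite <- function(fluid, crystallised, ids = NULL) {
  if (length(fluid) != length(crystallised)) {
    abort_gwaset("inputs must cover the same individuals")
  }
  if (!is.null(ids)) {
    if (!identical(ids[[1]], ids[[2]])) abort_gwaset("mismatched individual ids")
  }
  m <- (fluid + crystallised) / 2
  keep <- !is.na(m)
  out <- rep(NA_real_, length(m))
  out[keep] <- as.numeric(scale(m[keep]))
  out
}

#' Derive an adjusted general-factor phenotype from a test battery
#'
#' Convenience wrapper for the standard route: first unrotated principal
#' component of the named test columns, then age/sex residualisation of the
#' component scores.
#'
#' @param pheno A tibble with `age`, `sex` and test-score columns.
#' @param test_cols Character vector of test-score column names; default all
#'   columns starting with `"test_"`.
#' @return `pheno` with two added columns: `factor_score` (raw first-PC
#'   score) and `g` (its age/sex-adjusted standardised residual).
#' @export
derive_general_factor <- function(pheno,
                                  test_cols = grep("^test_", names(pheno), value = TRUE)) {
  if (length(test_cols) < 2L) abort_gwaset("need at least 2 test columns")
  f <- first_unrotated_pc(pheno[, test_cols])
  pheno$factor_score <- as.numeric(f)
  pheno$g <- residualize(pheno$factor_score, pheno$age, pheno$sex)
  pheno
}
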