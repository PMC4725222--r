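#' Additive single-marker association scan
#'
#' Per SNP, ordinary least squares of the (already residualised) phenotype on
#' an intercept, the minor-allele dosage and any covariate columns; reports
#' the dosage coefficient, its standard error and the two-sided t-test
#' p-value. Individuals with a missing phenotype are dropped globally;
#' missing dosages are dropped per SNP. SNPs whose dosage has zero variance
#' after sample filtering are skipped and recorded in the `"skipped"`
#' attribute.
#'
#' The computation uses the Frisch-Waugh-Lovell projection: phenotype and
#' dosages are residualised on the covariate block once, after which each SNP
#' reduces to a simple regression, so a full scan is a handful of matrix
#' products.
#'
#' @param geno A `geno_data` object (post-QC).
#' @param phenotype Numeric vector aligned with `geno$samples`, or a tibble
#'   with columns `iid` and `value`.
#' @param covariates Optional tibble with `iid` plus numeric covariate
#'   columns (e.g. from [genotype_pcs()]), or a numeric matrix.
#' @return A tibble of class `assoc_table` with columns `snp`, `chr`, `pos`,
#'   `a1`, `beta`, `se`, `p`, `n` (one row per tested SNP). P-values are
#'   clamped below at 1e-300.
#' @export
run_gwas <- function(geno, phenotype, covariates = NULL) {
  if (is.data.frame(phenotype)) {
    idx <- match(geno$samples$iid, phenotype$iid)
    if (anyNA(idx)) abort_gwaset("phenotype table is missing some genotyped individuals")
    y <- phenotype$value[idx]
  } else {
    if (length(phenotype) != n_samples(geno)) {
      abort_gwaset("`phenotype` must align with the genotyped individuals")
    }
    y <- as.numeric(phenotype)
  }
  C <- matrix(1, nrow = length(y), ncol = 1L)
  if (!is.null(covariates)) {
    if (is.data.frame(covariates)) {
      idx <- match(geno$samples$iid, covariates$iid)
      if (anyNA(idx)) abort_gwaset("covariate table is missing some genotyped individuals")
      cv <- as.matrix(covariates[idx, setdiff(names(covariates), "iid"), drop = FALSE])
    } else {
      cv <- as.matrix(covariates)
    }
    C <- cbind(C, cv)
  }
  keep <- !is.na(y) & stats::complete.cases(C)
  y <- y[keep]
  C <- C[keep, , drop = FALSE]
  D <- geno$dosages[keep, , drop = FALSE]
  storage.mode(D) <- "double"
  n_full <- length(y)
  k <- ncol(C)
  Q <- qr.Q(qr(C))

  yt <- y - Q %*% crossprod(Q, y)
  yty <- sum(yt^2)

  has_na <- colSums(is.na(D)) > 0L
  out <- vector("list", 2L)
  skipped <- character()

  if (any(!has_na)) {
    Dc <- D[, !has_na, drop = FALSE]
    Dt <- Dc - Q %*% crossprod(Q, Dc)
    xx <- colSums(Dt^2)
    ok <- xx > 1e-10
    skipped <- c(skipped, colnames(Dc)[!ok])
    Dt <- Dt[, ok, drop = FALSE]
    xx <- xx[ok]
    xx <- unname(xx)
    xy <- as.numeric(crossprod(Dt, yt))
    beta <- xy / xx
    df <- n_full - k - 1L
    sigma2 <- pmax(yty - beta * xy, 0) / df
    se <- sqrt(sigma2 / xx)
    tval <- beta / se
    p <- clamp_p(2 * pt(-abs(tval), df))
    out[[1]] <- tibble(snp = colnames(Dc)[ok], beta = beta, se = se, p = p,
                       n = n_full)
  }

  if (any(has_na)) {
    res <- map(which(has_na), function(j) {
      x <- D[, j]
      obs <- !is.na(x)
      if (sum(obs) <= k + 1L || sd(x[obs]) < 1e-10) return(NULL)
      dat <- data.frame(y = y[obs], x = x[obs], C[obs, -1L, drop = FALSE])
      fit <- lm(y ~ ., data = dat)
      sm <- summary(fit)$coefficients
      if (!"x" %in% rownames(sm)) return(NULL)
      tibble(snp = colnames(D)[j], beta = sm["x", 1L], se = sm["x", 2L],
             p = clamp_p(sm["x", 4L]), n = sum(obs))
    })
    nulls <- map_lgl(res, is.null)
    skipped <- c(skipped, colnames(D)[which(has_na)[nulls]])
    out[[2]] <- bind_rows(res[!nulls])
  }

  assoc <- bind_rows(out) |>
    left_join(select(geno$snp_map, "snp", "chr", "pos", "a1"), by = "snp") |>
    select("snp", "chr", "pos", "a1", "beta", "se", "p", "n") |>
    arrange(.data$chr, .data$pos)
  attr(assoc, "skipped") <- skipped
  class(assoc) <- c("assoc_table", class(assoc))
  assoc
}

#' Bonferroni-adjusted significance threshold
#'
#' @param n_tests Number of tests performed (>= 1).
#' @param fwer Family-wise error rate (default 0.05).
#' @return `fwer / n_tests`.
#' @examples
#' bonferroni_alpha(6956)  # 7.188039e-06
#' bonferroni_alpha(40)    # 0.00125
#' @export
bonferroni_alpha <- function(n_tests, fwer = 0.05) {
  n_tests <- check_count(n_tests, "n_tests")
  fwer / n_tests
}

#' Expected vs observed quantiles for a QQ plot
#'
#' @param p Vector of p-values.
#' @return A tibble with `expected` and `observed` -log10 p-value quantiles,
#'   sorted so the i-th row pairs the i-th smallest observed p with its
#'   uniform-order-statistic expectation.
#' @export
qq_data <- function(p) {
  p <- p[!is.na(p)]
  n <- length(p)
  tibble(expected = -log10((seq_len(n) - 0.5) / n),
         observed = -log10(sort(p)))
}

#' Genomic inflation factor lambda
#'
#' Median of the 1-df chi-square statistics implied by the p-values, divided
#' by the null median `qchisq(0.5, 1)`.
#'
#' @param p Vector of p-values.
#' @return A single number; 1 under a well-calibrated null.
#' @export
inflation_lambda <- function(p) {
  p <- p[!is.na(p)]
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' @export
glance.assoc_table <- function(x, ...) {
  tibble(n_snps = nrow(x),
         lambda = inflation_lambda(x$p),
         min_p = min(x$p),
         n_bonferroni_sig = sum(x$p < bonferroni_alpha(nrow(x))))
}

#' @export
tidy.assoc_table <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "assoc_table")
  attr(out, "skipped") <- NULL
  out
}

#' QQ plot of a single-marker association scan
#'
#' @param object An `assoc_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.assoc_table <- function(object, ...) {
  qq <- qq_data(object$p)
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)),
                  subtitle = sprintf("%d SNPs, lambda = %.3f",
                                     nrow(object), inflation_lambda(object$p))) +
    ggplot2::theme_minimal()
}
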