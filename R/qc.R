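#' Quality-control thresholds
#'
#' Container for the marker and sample inclusion thresholds. Defaults are the
#' conventional chip-GWAS values: SNPs are kept with call rate > 0.98,
#' Hardy-Weinberg equilibrium test p > 0.001 and minor allele frequency
#' > 0.01 (all strict inequalities); individuals are removed when their
#' genotype call rate is < 0.95.
#'
#' @param snp_call_rate_min SNP call-rate threshold (keep if strictly
#'   greater), default 0.98.
#' @param sample_call_rate_min Sample call-rate threshold (remove if strictly
#'   lower), default 0.95.
#' @param hwe_p_min HWE p-value threshold (keep if strictly greater),
#'   default 0.001.
#' @param maf_min MAF threshold (keep if strictly greater), default 0.01.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(snp_call_rate_min = 0.98,
                          sample_call_rate_min = 0.95,
                          hwe_p_min = 0.001,
                          maf_min = 0.01) {
  th <- list(
    snp_call_rate_min = check_prob(snp_call_rate_min, "snp_call_rate_min"),
    sample_call_rate_min = check_prob(sample_call_rate_min, "sample_call_rate_min"),
    hwe_p_min = check_prob(hwe_p_min, "hwe_p_min"),
    maf_min = check_prob(maf_min, "maf_min")
  )
  structure(th, class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom chi-square goodness-of-fit test of observed genotype
#' counts against Hardy-Weinberg expectations at the sample allele frequency.
#' Vectorised over SNPs. A monomorphic SNP (one allele absent) has nothing to
#' test and is defined to return p = 1.
#'
#' @param n_aa,n_ab,n_bb Non-negative genotype counts (AA = homozygous for
#'   the a1 allele, AB heterozygous, BB homozygous a2).
#' @return Vector of p-values.
#' @examples
#' hwe_test(25, 50, 25)  # exact HWE proportions: p = 1
#' hwe_test(50, 0, 50)   # complete heterozygote deficit
#' @export
hwe_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (any(n < 1)) abort_gwaset("need at least one genotyped individual")
  if (any(c(n_aa, n_ab, n_bb) < 0)) abort_gwaset("negative genotype count")
  p <- (2 * n_aa + n_ab) / (2 * n)
  q <- 1 - p
  e_aa <- n * p^2
  e_ab <- 2 * n * p * q
  e_bb <- n * q^2
  chi <- ifelse(p == 0 | p == 1, 0,
                (n_aa - e_aa)^2 / pmax(e_aa, .Machine$double.xmin) +
                  (n_ab - e_ab)^2 / pmax(e_ab, .Machine$double.xmin) +
                  (n_bb - e_bb)^2 / pmax(e_bb, .Machine$double.xmin))
  ifelse(p == 0 | p == 1, 1, pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Per-SNP QC metrics
#'
#' @param geno A `geno_data` object.
#' @return A tibble: `snp`, `call_rate`, `maf`, `hwe_p`.
#' @export
snp_qc <- function(geno) {
  d <- geno$dosages
  n <- nrow(d)
  n_obs <- n - colSums(is.na(d))
  call_rate <- n_obs / n
  n_aa <- colSums(d == 2L, na.rm = TRUE)
  n_ab <- colSums(d == 1L, na.rm = TRUE)
  n_bb <- colSums(d == 0L, na.rm = TRUE)
  freq <- ifelse(n_obs > 0, (2 * n_aa + n_ab) / (2 * pmax(n_obs, 1)), NA_real_)
  maf <- pmin(freq, 1 - freq)
  hwe_p <- rep(NA_real_, ncol(d))
  ok <- n_obs >= 1
  hwe_p[ok] <- hwe_test(n_aa[ok], n_ab[ok], n_bb[ok])
  tibble(snp = geno$snp_map$snp, call_rate = unname(call_rate),
         maf = unname(maf), hwe_p = unname(hwe_p))
}

#' Marker quality-control filter
#'
#' Applies the marker inclusion rules with strict inequalities: call rate
#' > threshold, HWE p > threshold, MAF > threshold. The exclusion reason is
#' the first failing rule in the order call-rate, HWE, MAF; the retained set
#' itself does not depend on that order since the rules are marginal.
#'
#' @param geno A `geno_data` object.
#' @param thresholds A [qc_thresholds()].
#' @return A tibble with one row per SNP: `snp`, `call_rate`, `maf`,
#'   `hwe_p`, `keep` (logical) and `reason` (`NA` for kept SNPs, else
#'   `"call_rate"`, `"hwe"` or `"maf"`).
#' @export
filter_snps <- function(geno, thresholds = qc_thresholds()) {
  m <- snp_qc(geno)
  fail_cr <- !(m$call_rate > thresholds$snp_call_rate_min)
  fail_hwe <- !(m$hwe_p > thresholds$hwe_p_min) | is.na(m$hwe_p)
  fail_maf <- !(m$maf > thresholds$maf_min) | is.na(m$maf)
  m$keep <- !(fail_cr | fail_hwe | fail_maf)
  m$reason <- dplyr::case_when(
    fail_cr ~ "call_rate",
    fail_hwe ~ "hwe",
    fail_maf ~ "maf",
    TRUE ~ NA_character_
  )
  m
}

#' Sample call-rate filter
#'
#' Individuals with genotype call rate strictly below the threshold are
#' removed; a call rate exactly at the threshold is retained.
#'
#' @inheritParams filter_snps
#' @return A tibble: `iid`, `call_rate`, `keep`.
#' @export
filter_samples <- function(geno, thresholds = qc_thresholds()) {
  d <- geno$dosages
  call_rate <- 1 - rowSums(is.na(d)) / ncol(d)
  tibble(iid = geno$samples$iid, call_rate = unname(call_rate),
         keep = !(call_rate < thresholds$sample_call_rate_min))
}

#' Apply sample then marker QC to a genotype object
#'
#' Samples are filtered first (call rate over all markers), then the marker
#' rules are evaluated on the retained individuals.
#'
#' @inheritParams filter_snps
#' @return A list: `geno` (the filtered `geno_data`), `snp_log` and
#'   `sample_log` (the per-item filter tibbles).
#' @export
apply_qc <- function(geno, thresholds = qc_thresholds()) {
  samp <- filter_samples(geno, thresholds)
  g1 <- subset_geno(geno, samples = samp$iid[samp$keep])
  snp <- filter_snps(g1, thresholds)
  list(geno = subset_geno(g1, snps = snp$snp[snp$keep]),
       snp_log = snp, sample_log = samp)
}

#' Ancestry covariates from genotype principal components
#'
#' First `k` principal components of the column-standardised dosage matrix
#' (missing calls mean-imputed per SNP), each re-standardised. These play the
#' role of population-stratification covariates in the association model.
#'
#' @param geno A `geno_data` object.
#' @param k Number of components (default 4).
#' @return A tibble: `iid`, `PC1` ... `PCk`.
#' @export
genotype_pcs <- function(geno, k = 4L) {
  k <- check_count(k, "k")
  d <- geno$dosages
  if (k >= min(dim(d))) abort_gwaset("`k` must be smaller than both dimensions")
  storage.mode(d) <- "double"
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2L]]
  }
  sds <- apply(d, 2L, sd)
  keep <- sds > 1e-12
  z <- scale(d[, keep, drop = FALSE])
  pc <- prcomp(z, center = FALSE, scale. = FALSE, rank. = k)
  scores <- apply(pc$x, 2L, function(x) as.numeric(scale(x)))
  colnames(scores) <- paste0("PC", seq_len(k))
  bind_cols(tibble(iid = geno$samples$iid), as_tibble(scores))
}
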