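#' Map SNPs to flanked gene windows
#'
#' Assigns every SNP to every gene whose flanked window contains it: the
#' window is the gene body extended by `flank_bp` on each side (floored at
#' position 1), with inclusive bounds. Membership is not exclusive — a SNP
#' near two genes belongs to both. Genes with no panel SNP are retained with
#' an empty member list.
#'
#' @param annotation Tibble with `gene`, `chr`, `start`, `stop` (1-based,
#'   inclusive).
#' @param snp_map Tibble with `snp`, `chr`, `pos`.
#' @param flank_bp Flanking distance in bp added to each side of the gene
#'   body (default 50,000).
#' @return A tibble: `gene`, `chr`, `start`, `stop`, `window_start`,
#'   `window_stop`, `snps` (list-column of member SNP ids in position
#'   order), `n_snps`.
#' @export
map_snps_to_genes <- function(annotation, snp_map, flank_bp = 50000L) {
  win <- annotation |>
    mutate(window_start = pmax(.data$start - flank_bp, 1L),
           window_stop = .data$stop + flank_bp)
  members <- rep(list(character()), nrow(win))
  for (ch in unique(win$chr)) {
    wi <- which(win$chr == ch)
    si <- which(snp_map$chr == ch)
    if (length(si) == 0L) next
    sm <- snp_map[si, ]
    ord <- order(sm$pos)
    sm <- sm[ord, ]
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(sm$pos, sm$pos),
      IRanges::IRanges(win$window_start[wi], win$window_stop[wi]))
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    for (j in seq_along(wi)) {
      members[[wi[j]]] <- sm$snp[qh[sh == j]]
    }
  }
  win$snps <- members
  win$n_snps <- lengths(members)
  win
}

#' Gene-level sum-of-chi-squares statistic
#'
#' Converts each member SNP's two-sided p-value to its 1-df chi-square
#' statistic (upper-tail quantile, direction discarded) and sums them. Large
#' values indicate that the gene's SNPs are collectively more associated than
#' expected.
#'
#' @param p Vector of member-SNP p-values, each in (0, 1].
#' @return The summed statistic (>= 0).
#' @examples
#' gene_statistic(0.05)          # ~ 3.84
#' gene_statistic(c(0.05, 0.05)) # ~ 7.68
#' @export
gene_statistic <- function(p) {
  if (length(p) == 0L) abort_gwaset("empty member list: gene statistic undefined")
  if (anyNA(p) || any(p <= 0) || any(p > 1)) abort_gwaset("p-values must lie in (0, 1]")
  sum(qchisq(p, df = 1, lower.tail = FALSE))
}

#' Pairwise LD (dosage correlation) matrix from a reference panel
#'
#' @param geno Reference `geno_data`.
#' @param snp_ids SNP ids to include (must exist in `geno`).
#' @return Symmetric correlation matrix with unit diagonal and the SNP ids
#'   as dimnames. Pairwise-complete observations are used when calls are
#'   missing; a zero-variance SNP yields `NA` entries, which
#'   [empirical_gene_p()] treats as uncorrelated.
#' @export
ld_matrix <- function(geno, snp_ids) {
  miss <- setdiff(snp_ids, geno$snp_map$snp)
  if (length(miss) > 0) {
    abort_gwaset(paste0("SNP id(s) absent from the LD reference: ",
                        paste(head(miss, 5), collapse = ", ")))
  }
  d <- geno$dosages[, snp_ids, drop = FALSE]
  storage.mode(d) <- "double"
  r <- suppressWarnings(cor(d, use = "pairwise.complete.obs"))
  diag(r) <- 1
  r
}

# clip negative eigenvalues and reconstruct; rescale to unit diagonal so the
# marginal null statistics stay chi-square(1)
repair_psd <- function(r) {
  r[is.na(r)] <- 0
  diag(r) <- 1
  r <- (r + t(r)) / 2
  e <- eigen(r, symmetric = TRUE)
  if (all(!is.finite(e$values))) abort_gwaset("non-repairable LD matrix")
  vals <- pmax(e$values, 1e-10)
  out <- e$vectors %*% (vals * t(e$vectors))
  stats::cov2cor(out)
}

#' Empirical gene p-value from the LD-correlated null
#'
#' Simulates the null distribution of the gene statistic: multivariate normal
#' vectors z with covariance equal to the (positive-semi-definite-repaired)
#' LD correlation matrix are drawn, each simulated statistic is the sum of
#' squared components, and the empirical p-value is the permutation-style
#' estimate `(count + 1) / (n_sims + 1)` of the probability that a null
#' statistic is at least as large as the observed one. In adaptive mode the
#' simulation size escalates 10^3 -> 10^4 -> 10^5 -> 10^6 until at least 10
#' exceedances are observed (bounding the relative Monte Carlo error of
#' small p-values).
#'
#' @param statistic Observed gene statistic from [gene_statistic()].
#' @param ld LD correlation matrix covering exactly the member SNPs.
#' @param n_sims Simulation size (first stage in adaptive mode),
#'   default 1000.
#' @param adaptive Escalate the simulation size for small p (default TRUE).
#' @param max_sims Cap for adaptive escalation (default 1e6).
#' @param seed Integer seed; the result is deterministic given it.
#' @return A list: `p`, `n_sims` (size actually used), `statistic`,
#'   `n_snps`.
#' @export
empirical_gene_p <- function(statistic, ld, n_sims = 1000L, adaptive = TRUE,
                             max_sims = 1e6, seed = 1L) {
  if (statistic < 0) abort_gwaset("gene statistic must be non-negative")
  ld <- as.matrix(ld)
  if (nrow(ld) != ncol(ld)) abort_gwaset("LD matrix must be square")
  k <- nrow(ld)
  r <- repair_psd(ld)
  e <- eigen(r, symmetric = TRUE)
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), k)
  sizes <- c(1e3, 1e4, 1e5, 1e6)
  sizes <- unique(pmin(pmax(sizes, n_sims), max_sims))
  if (!adaptive) sizes <- n_sims
  with_seed(seed, {
    count <- 0L
    used <- 0L
    for (ns in sizes) {
      count <- 0L
      used <- as.integer(ns)
      done <- 0L
      chunk <- 1e5
      while (done < ns) {
        m <- as.integer(min(chunk, ns - done))
        z <- matrix(rnorm(m * k), nrow = m) %*% t(A)
        count <- count + sum(rowSums(z^2) >= statistic)
        done <- done + m
      }
      if (count >= 10L) break
    }
    list(p = (count + 1) / (used + 1), n_sims = used,
         statistic = statistic, n_snps = k)
  })
}

#' Gene-based association test over all annotated genes
#'
#' For each gene window with at least one member SNP in the association
#' table, sums the member SNPs' 1-df chi-square statistics and computes an
#' empirical p-value by simulation from the LD-correlated null, taking LD
#' from a reference genotype panel (by default the analysis cohort itself).
#' Genes with no scored SNP are skipped and listed in the `"skipped"`
#' attribute.
#'
#' @param assoc An `assoc_table` from [run_gwas()] (or [read_assoc()]).
#' @param ld_ref Reference `geno_data` for LD.
#' @param annotation Gene annotation tibble.
#' @param flank_bp Window flank in bp (default 50,000).
#' @param n_sims,adaptive,max_sims Passed to [empirical_gene_p()].
#' @param seed Integer seed; per-gene simulation seeds are derived from it.
#' @return A tibble of class `gene_scores`: `gene`, `chr`, `start`, `stop`,
#'   `n_snps`, `statistic`, `n_sims`, `p`.
#' @export
gene_test <- function(assoc, ld_ref, annotation, flank_bp = 50000L,
                      n_sims = 1000L, adaptive = TRUE, max_sims = 1e6,
                      seed = 1L) {
  windows <- map_snps_to_genes(annotation, select(assoc, "snp", "chr", "pos"),
                               flank_bp = flank_bp)
  p_lookup <- setNames(assoc$p, assoc$snp)
  rows <- vector("list", nrow(windows))
  skipped <- character()
  for (i in seq_len(nrow(windows))) {
    ids <- intersect(windows$snps[[i]], assoc$snp)
    if (length(ids) == 0L) {
      skipped <- c(skipped, windows$gene[i])
      next
    }
    t_obs <- gene_statistic(p_lookup[ids])
    ld <- ld_matrix(ld_ref, ids)
    res <- empirical_gene_p(t_obs, ld, n_sims = n_sims, adaptive = adaptive,
                            max_sims = max_sims,
                            seed = (seed + i) %% .Machine$integer.max)
    rows[[i]] <- tibble(gene = windows$gene[i], chr = windows$chr[i],
                        start = windows$start[i], stop = windows$stop[i],
                        n_snps = length(ids), statistic = t_obs,
                        n_sims = res$n_sims, p = res$p)
  }
  out <- bind_rows(rows)
  attr(out, "skipped") <- skipped
  class(out) <- c("gene_scores", class(out))
  out
}

#' @export
glance.gene_scores <- function(x, ...) {
  tibble(n_genes = nrow(x), min_p = min(x$p),
         n_bonferroni_sig = sum(x$p < bonferroni_alpha(nrow(x))),
         n_nominal = sum(x$p < 0.05))
}

#' @export
tidy.gene_scores <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "gene_scores")
  attr(out, "skipped") <- NULL
  out
}

#' Plot gene-based association results
#'
#' -log10 empirical p per gene, ordered by genomic position, with the
#' Bonferroni line for the number of genes tested.
#'
#' @param object A `gene_scores` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gene_scores <- function(object, ...) {
  df <- object |> arrange(.data$chr, .data$start) |>
    mutate(idx = row_number())
  thr <- bonferroni_alpha(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = -log10(.data$p),
                                   colour = factor(.data$chr %% 2))) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = 2) +
    ggplot2::labs(x = "gene (genome order)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}
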