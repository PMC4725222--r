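#' Clumping parameters
#'
#' Thresholds for the greedy LD-clumping of association peaks into genomic
#' intervals. Defaults: index SNPs need p < 0.0005 (strict); members need
#' nominal significance p < 0.05, distance from the index of at most 250 kb,
#' and LD r-squared with the index strictly above 0.5; intervals are later
#' kept only when they fall within 20 kb of a gene.
#'
#' @param index_p_max Index SNP p-value ceiling (strict), default 5e-4.
#' @param member_p_max Member (nominal) p-value ceiling (strict),
#'   default 0.05.
#' @param window_bp Maximum distance from the index SNP in bp (inclusive),
#'   default 250,000.
#' @param r2_min LD r-squared floor against the index (strict),
#'   default 0.5.
#' @param gene_margin_bp Margin for gene overlap filtering in bp (inclusive),
#'   default 20,000.
#' @return An object of class `clump_params`.
#' @export
clump_params <- function(index_p_max = 5e-4, member_p_max = 0.05,
                         window_bp = 250000L, r2_min = 0.5,
                         gene_margin_bp = 20000L) {
  if (index_p_max > member_p_max) {
    abort_gwaset("`index_p_max` cannot exceed `member_p_max`")
  }
  structure(list(
    index_p_max = check_prob(index_p_max, "index_p_max"),
    member_p_max = check_prob(member_p_max, "member_p_max"),
    window_bp = check_count(window_bp, "window_bp"),
    r2_min = check_prob(r2_min, "r2_min", hi_open = FALSE),
    gene_margin_bp = check_count(gene_margin_bp, "gene_margin_bp", min = 0L)
  ), class = "clump_params")
}

new_interval_set <- function(df) {
  class(df) <- c("interval_set", setdiff(class(df), "interval_set"))
  df
}

#' Greedy LD clumping of association results into genomic intervals
#'
#' Repeatedly takes the unclaimed SNP with the smallest p-value below
#' `index_p_max` as an index SNP (ties broken by chromosome then position),
#' claims every unclaimed SNP that is nominally significant
#' (p < `member_p_max`), within `window_bp` of the index, and in LD with it
#' (r-squared > `r2_min`, squared Pearson correlation of dosages in
#' `ld_source`), and spans an interval from the minimum to the maximum
#' position of the claimed set (index included). Claimed SNPs can neither
#' seed nor join later clumps, so the resulting intervals represent
#' LD-independent association signals.
#'
#' SNPs absent from `ld_source` are treated as uncorrelated with every index
#' and recorded in the `"missing_ld"` attribute.
#'
#' @param assoc An `assoc_table`.
#' @param ld_source `geno_data` used to compute dosage correlations.
#' @param params A [clump_params()].
#' @return A tibble of class `interval_set`: `chr`, `start`, `stop`,
#'   `index_snp`, `index_p`, `n_snps`, `snps` (list-column), `snp_p`
#'   (list-column, aligned with `snps`).
#' @export
clump <- function(assoc, ld_source, params = clump_params()) {
  a <- arrange(as_tibble(assoc), .data$p, .data$chr, .data$pos)
  in_ref <- a$snp %in% ld_source$snp_map$snp
  missing_ld <- a$snp[!in_ref & a$p < params$member_p_max]
  claimed <- rep(FALSE, nrow(a))
  out <- list()
  repeat {
    cand_idx <- which(!claimed & a$p < params$index_p_max)
    if (length(cand_idx) == 0L) break
    i <- cand_idx[1L]
    claimed[i] <- TRUE
    near <- which(!claimed &
                    a$chr == a$chr[i] &
                    abs(a$pos - a$pos[i]) <= params$window_bp &
                    a$p < params$member_p_max)
    members <- integer()
    if (length(near) > 0L && in_ref[i]) {
      near_ref <- near[in_ref[near]]
      if (length(near_ref) > 0L) {
        x <- as.numeric(ld_source$dosages[, a$snp[i]])
        d <- ld_source$dosages[, a$snp[near_ref], drop = FALSE]
        storage.mode(d) <- "double"
        r <- suppressWarnings(as.numeric(cor(x, d, use = "pairwise.complete.obs")))
        r2 <- r^2
        r2[is.na(r2)] <- 0
        members <- near_ref[r2 > params$r2_min]
      }
    }
    claimed[members] <- TRUE
    all_idx <- c(i, members)
    ord <- order(a$pos[all_idx])
    all_idx <- all_idx[ord]
    out[[length(out) + 1L]] <- tibble(
      chr = a$chr[i],
      start = min(a$pos[all_idx]),
      stop = max(a$pos[all_idx]),
      index_snp = a$snp[i],
      index_p = a$p[i],
      n_snps = length(all_idx),
      snps = list(a$snp[all_idx]),
      snp_p = list(a$p[all_idx])
    )
  }
  res <- if (length(out) == 0L) {
    tibble(chr = integer(), start = integer(), stop = integer(),
           index_snp = character(), index_p = numeric(), n_snps = integer(),
           snps = list(), snp_p = list())
  } else {
    arrange(bind_rows(out), .data$chr, .data$start)
  }
  attr(res, "missing_ld") <- missing_ld
  new_interval_set(res)
}

#' Keep intervals that fall near a known gene
#'
#' Retains intervals whose span intersects any gene body extended by
#' `margin` bp on each side (inclusive bounds on both), and records the
#' overlapped gene ids per interval.
#'
#' @param intervals An `interval_set`.
#' @param annotation Gene annotation tibble (`gene`, `chr`, `start`,
#'   `stop`).
#' @param margin Margin in bp (default 20,000).
#' @return The retained intervals with added list-column `genes` and count
#'   `n_genes`.
#' @export
filter_to_genes <- function(intervals, annotation, margin = 20000L) {
  if (nrow(intervals) == 0L) {
    intervals$genes <- list()
    intervals$n_genes <- integer()
    return(new_interval_set(intervals))
  }
  genes <- rep(list(character()), nrow(intervals))
  for (ch in unique(intervals$chr)) {
    ii <- which(intervals$chr == ch)
    gi <- which(annotation$chr == ch)
    if (length(gi) == 0L) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(intervals$start[ii], intervals$stop[ii]),
      IRanges::IRanges(pmax(annotation$start[gi] - margin, 1L),
                       annotation$stop[gi] + margin))
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    for (j in seq_along(ii)) {
      genes[[ii[j]]] <- annotation$gene[gi[sh[qh == j]]]
    }
  }
  intervals$genes <- genes
  intervals$n_genes <- lengths(genes)
  new_interval_set(intervals[lengths(genes) > 0L, , drop = FALSE])
}

#' Merge overlapping genomic intervals
#'
#' Sweep-line union per chromosome: overlapping (or touching, since bounds
#' are inclusive) intervals are merged; member SNPs, p-values and overlapped
#' genes are unioned; the merged index SNP is the member with the smallest
#' p-value. Output is sorted and pairwise non-overlapping.
#'
#' @param intervals An `interval_set`.
#' @return An `interval_set` of disjoint intervals.
#' @export
merge_overlapping <- function(intervals) {
  if (nrow(intervals) <= 1L) return(new_interval_set(intervals))
  has_genes <- "genes" %in% names(intervals)
  out <- list()
  for (ch in sort(unique(intervals$chr))) {
    ii <- which(intervals$chr == ch)
    ir <- IRanges::IRanges(intervals$start[ii], intervals$stop[ii])
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(ir, red)
    grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
    for (g in seq_along(red)) {
      src <- ii[grp == g]
      snps <- unlist(intervals$snps[src])
      ps <- unlist(intervals$snp_p[src])
      dup <- duplicated(snps)
      snps <- snps[!dup]
      ps <- ps[!dup]
      best <- which.min(ps)
      row <- tibble(
        chr = ch,
        start = IRanges::start(red)[g],
        stop = IRanges::end(red)[g],
        index_snp = snps[best],
        index_p = ps[best],
        n_snps = length(snps),
        snps = list(snps),
        snp_p = list(ps)
      )
      if (has_genes) {
        gg <- sort(unique(unlist(intervals$genes[src])))
        row$genes <- list(gg)
        row$n_genes <- length(gg)
      }
      out[[length(out) + 1L]] <- row
    }
  }
  new_interval_set(arrange(bind_rows(out), .data$chr, .data$start))
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set> %d interval(s)\n", nrow(x)))
  NextMethod()
}

#' @export
tidy.interval_set <- function(x, ...) {
  tibble(chr = x$chr, start = x$start, stop = x$stop,
         index_snp = x$index_snp, index_p = x$index_p, n_snps = x$n_snps,
         n_genes = if ("n_genes" %in% names(x)) x$n_genes else NA_integer_)
}
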