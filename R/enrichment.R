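# per-chromosome lookup tables used by the permutation hot path
genome_index <- function(snp_map, annotation, margin = 20000L) {
  chrs <- sort(unique(snp_map$chr))
  idx <- map(chrs, function(ch) {
    gi <- annotation$chr == ch
    list(
      pos = sort(snp_map$pos[snp_map$chr == ch]),
      gene = annotation$gene[gi],
      gstart = pmax(annotation$start[gi] - margin, 1L),
      gstop = annotation$stop[gi] + margin
    )
  })
  names(idx) <- as.character(chrs)
  idx
}

genes_in_span <- function(gidx, chr, a, b) {
  ci <- gidx[[as.character(chr)]]
  if (is.null(ci) || length(ci$gene) == 0L) return(character())
  ci$gene[ci$gstart <= b & ci$gstop >= a]
}

#' Gene-set overlap statistic for a set of genomic intervals
#'
#' The competitive test statistic: the number of (merged, disjoint) genomic
#' intervals that intersect at least one gene of the set, with gene bodies
#' extended by `margin` bp. An interval counts once no matter how many set
#' genes it covers.
#'
#' @param intervals An `interval_set` (merged).
#' @param set_genes Character vector of gene ids in the set.
#' @param annotation Gene annotation tibble.
#' @param margin Overlap margin in bp (default 20,000).
#' @return A list: `n_hit` (the statistic), `assignments` (tibble mapping
#'   each hitting interval to the set genes it covers) and `missing_genes`
#'   (set members absent from the annotation, ignored with this log).
#' @export
overlap_statistic <- function(intervals, set_genes, annotation,
                              margin = 20000L) {
  set_genes <- unique(set_genes)
  missing_genes <- setdiff(set_genes, annotation$gene)
  present <- setdiff(set_genes, missing_genes)
  # only the gene side of the index is consulted here
  gidx <- genome_index(tibble(chr = unique(annotation$chr), pos = 1L),
                       annotation[annotation$gene %in% present, , drop = FALSE],
                       margin = margin)
  hits <- map(seq_len(nrow(intervals)), function(i) {
    genes_in_span(gidx, intervals$chr[i], intervals$start[i], intervals$stop[i])
  })
  hit <- lengths(hits) > 0L
  assignments <- tibble(
    chr = intervals$chr[hit], start = intervals$start[hit],
    stop = intervals$stop[hit],
    genes = map_chr(hits[hit], paste, collapse = ";")
  )
  list(n_hit = sum(hit), assignments = assignments,
       missing_genes = missing_genes)
}

# one matched placement for a cluster of observed intervals that sit close
# together on the same chromosome; the cluster is moved as a rigid body
# (SNP-index offsets preserved) so the permuted set reproduces the observed
# set's between-interval dependence (nearby intervals sharing genes).
# offsets: 0-based SNP-index offset of each interval's first SNP from the
# cluster anchor. Uses the current RNG.
match_cluster <- function(offsets, n_snps_obs, n_genes_obs, gidx, chr_weights,
                          max_attempts = 1000L) {
  k <- length(offsets)
  m_lo <- pmax(1L, as.integer(ceiling(0.8 * n_snps_obs)))
  m_hi <- pmax(m_lo, as.integer(floor(1.2 * n_snps_obs)))
  chrs <- names(gidx)
  for (phase_tol in c(0L, 1L)) {
    for (attempt in seq_len(max_attempts)) {
      m <- ifelse(m_hi > m_lo,
                  m_lo + floor(stats::runif(k) * (m_hi - m_lo + 1L)), m_lo)
      need <- max(offsets + m)
      ch <- sample(chrs, 1L, prob = chr_weights)
      pos <- gidx[[ch]]$pos
      if (length(pos) < need) next
      anchor <- sample.int(length(pos) - need + 1L, 1L)
      s <- anchor + offsets
      a <- pos[s]
      b <- pos[s + m - 1L]
      genes <- lapply(seq_len(k), function(i) genes_in_span(gidx, ch, a[i], b[i]))
      if (all(abs(lengths(genes) - n_genes_obs) <= phase_tol)) {
        return(lapply(seq_len(k), function(i) {
          list(chr = as.integer(ch), start = a[i], stop = b[i],
               n_snps = as.integer(m[i]), n_genes = length(genes[[i]]),
               genes = genes[[i]])
        }))
      }
    }
  }
  NULL
}

#' Generate one permuted interval set matched to the observed intervals
#'
#' For each observed interval, samples a random placement on the SNP-covered
#' genome whose overlapped-gene count equals the observed interval's count
#' (exactly for up to `max_attempts` draws, then within +/- 1 for another
#' `max_attempts`) and whose member-SNP count lies within +/- 20 percent of
#' the observed count. Placements span runs of consecutive panel SNPs, so
#' the permuted intervals inherit the panel's SNP density. Observed
#' intervals lying within `cluster_gap_bp` of each other on one chromosome
#' are placed jointly as a rigid cluster (SNP-index offsets preserved), so
#' the permuted set also reproduces the observed set's between-interval
#' dependence — nearby intervals that overlap the same gene. This is the
#' matched null used by the competitive gene-set test.
#'
#' @param observed An `interval_set` carrying `n_snps` and `n_genes`
#'   columns (i.e. after [filter_to_genes()] and [merge_overlapping()]).
#' @param snp_map SNP map tibble (`snp`, `chr`, `pos`).
#' @param annotation Gene annotation tibble.
#' @param seed Integer seed (the permuted set is deterministic given it).
#' @param margin Gene overlap margin in bp (default 20,000).
#' @param max_attempts Placement attempts per tolerance phase
#'   (default 1000).
#' @param cluster_gap_bp Maximum gap between observed intervals treated as
#'   one rigid cluster (default 250,000, the clumping window).
#' @return A tibble with one matched interval per observed interval:
#'   `chr`, `start`, `stop`, `n_snps`, `n_genes`, `genes` (list-column).
#' @export
generate_matched_intervals <- function(observed, snp_map, annotation,
                                       seed = 1L, margin = 20000L,
                                       max_attempts = 1000L,
                                       cluster_gap_bp = 250000L) {
  gidx <- genome_index(snp_map, annotation, margin = margin)
  chr_weights <- map_dbl(gidx, function(ci) length(ci$pos))
  with_seed(seed, {
    matched_set_impl(observed, gidx, chr_weights, max_attempts, cluster_gap_bp)
  })
}

# group observed intervals into proximity clusters (same chromosome, gaps of
# at most cluster_gap_bp); each cluster is permuted as a unit
interval_clusters <- function(observed, cluster_gap_bp = 250000L) {
  ord <- order(observed$chr, observed$start)
  cl <- integer(nrow(observed))
  cur <- 0L
  last_chr <- NA_integer_
  last_stop <- NA_integer_
  for (i in ord) {
    if (is.na(last_chr) || observed$chr[i] != last_chr ||
        observed$start[i] - last_stop > cluster_gap_bp) {
      cur <- cur + 1L
    }
    cl[i] <- cur
    last_chr <- observed$chr[i]
    last_stop <- max(observed$stop[i], if (is.na(last_stop)) 0L else last_stop)
  }
  cl
}

matched_set_impl <- function(observed, gidx, chr_weights, max_attempts = 1000L,
                             cluster_gap_bp = 250000L) {
  if (!"n_genes" %in% names(observed)) {
    abort_gwaset("observed intervals must carry `n_genes` (run filter_to_genes first)")
  }
  cl <- interval_clusters(observed, cluster_gap_bp)
  rows <- vector("list", nrow(observed))
  for (g in unique(cl)) {
    idx <- which(cl == g)
    idx <- idx[order(observed$start[idx])]
    ch <- as.character(observed$chr[idx[1]])
    pos <- gidx[[ch]]$pos
    start_idx <- findInterval(observed$start[idx], pos)
    start_idx <- pmax(start_idx, 1L)
    offsets <- start_idx - start_idx[1]
    res <- match_cluster(offsets, observed$n_snps[idx], observed$n_genes[idx],
                         gidx, chr_weights, max_attempts)
    if (is.null(res) && length(idx) > 1L) {
      # rigid joint placement infeasible on this genome: fall back to
      # independent per-interval placement
      res <- lapply(idx, function(i) {
        one <- match_cluster(0L, observed$n_snps[i], observed$n_genes[i],
                             gidx, chr_weights, max_attempts)
        if (is.null(one)) NULL else one[[1]]
      })
      if (any(vapply(res, is.null, logical(1)))) res <- NULL
    }
    if (is.null(res)) {
      i <- idx[1]
      abort_gwaset(sprintf(
        "no eligible matched placement for interval %d:%d-%d (%d genes, %d SNPs)",
        observed$chr[i], observed$start[i], observed$stop[i],
        observed$n_genes[i], observed$n_snps[i]))
    }
    rows[idx] <- res
  }
  tibble(
    chr = map_int(rows, "chr"),
    start = map_int(rows, function(r) as.integer(r$start)),
    stop = map_int(rows, function(r) as.integer(r$stop)),
    n_snps = map_int(rows, "n_snps"),
    n_genes = map_int(rows, "n_genes"),
    genes = map(rows, "genes")
  )
}

#' Permutation null for competitive gene-set testing
#'
#' Generates `n_perm` matched interval sets (see
#' [generate_matched_intervals()]) and records, for every gene set, the
#' overlap statistic of each permuted set. The resulting matrix of null
#' statistics supports both the empirical set p-value and the bootstrap
#' multiple-set correction.
#'
#' @param observed Observed merged `interval_set` with `n_genes`.
#' @param snp_map SNP map tibble.
#' @param annotation Gene annotation tibble.
#' @param gene_sets Tibble with columns `set` and `genes` (list-column), as
#'   from [simulate_gene_sets()] or [read_gmt()].
#' @param n_perm Number of permutations (default 10,000).
#' @param seed Integer seed.
#' @param margin Gene overlap margin in bp (default 20,000).
#' @param max_attempts Placement attempts per interval and phase.
#' @param cluster_gap_bp Rigid-cluster gap, see
#'   [generate_matched_intervals()].
#' @return An object of class `perm_null`: list with `stats` (n_perm x
#'   n_sets integer matrix), `sets`, `n_perm`, `seed`, `margin`.
#' @export
permutation_null <- function(observed, snp_map, annotation, gene_sets,
                             n_perm = 10000L, seed = 1L, margin = 20000L,
                             max_attempts = 1000L, cluster_gap_bp = 250000L) {
  n_perm <- check_count(n_perm, "n_perm")
  gidx <- genome_index(snp_map, annotation, margin = margin)
  chr_weights <- map_dbl(gidx, function(ci) length(ci$pos))
  K <- nrow(gene_sets)
  incidence <- matrix(FALSE, nrow = nrow(annotation), ncol = K,
                      dimnames = list(annotation$gene, gene_sets$set))
  for (k in seq_len(K)) {
    gk <- intersect(gene_sets$genes[[k]], annotation$gene)
    incidence[gk, k] <- TRUE
  }
  stats_mat <- matrix(0L, nrow = n_perm, ncol = K,
                      dimnames = list(NULL, gene_sets$set))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- matched_set_impl(observed, gidx, chr_weights, max_attempts,
                               cluster_gap_bp)
      acc <- integer(K)
      for (i in seq_len(nrow(perm))) {
        g <- perm$genes[[i]]
        if (length(g) == 0L) next
        acc <- acc + (colSums(incidence[g, , drop = FALSE]) > 0L)
      }
      stats_mat[b, ] <- acc
    }
  })
  structure(list(stats = stats_mat, sets = gene_sets$set,
                 n_perm = n_perm, seed = seed, margin = margin),
            class = "perm_null")
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("<perm_null> %d permutations x %d gene set(s)\n",
              x$n_perm, length(x$sets)))
  invisible(x)
}

#' @export
tidy.perm_null <- function(x, ...) {
  as_tibble(x$stats) |>
    mutate(perm = row_number()) |>
    tidyr::pivot_longer(-"perm", names_to = "set", values_to = "statistic")
}

#' Empirical p-value of a gene-set overlap statistic
#'
#' `p = #\{permuted statistics >= observed\} / n_perm` (ties count as
#' exceedances). A zero exceedance count is reported censored at the
#' resolution floor `1 / n_perm` with `censored = TRUE`, meaning
#' "p < 1/n_perm".
#'
#' @param observed Observed overlap statistic (count).
#' @param null A `perm_null`.
#' @param set Name of the gene set within `null`.
#' @return A one-row tibble: `set`, `observed`, `n_perm`, `p`, `censored`.
#' @export
empirical_set_p <- function(observed, null, set) {
  stopifnot(inherits(null, "perm_null"))
  if (!set %in% colnames(null$stats)) {
    abort_gwaset(sprintf("no permutation null stored for set '%s'", set))
  }
  count <- sum(null$stats[, set] >= observed)
  tibble(set = set, observed = observed, n_perm = null$n_perm,
         p = max(count, 1L) / null$n_perm, censored = count == 0L)
}

#' Bootstrap correction for testing many correlated gene sets
#'
#' Family-wise correction that respects the correlation between gene sets:
#' in each of `B` bootstrap rounds one permuted interval set is drawn (with
#' replacement) and promoted to pseudo-observed; its empirical p-value
#' against the remaining permutations is computed for every gene set and the
#' minimum over sets is taken. The corrected p-value for a target set is the
#' proportion of rounds in which that minimum is at least as significant as
#' (less than or equal to) the target's empirical p-value. With a single
#' set, or with perfectly correlated duplicate sets, the corrected value
#' stays close to the empirical one — unlike a Bonferroni adjustment.
#'
#' @param null A `perm_null` with statistics stored for every set.
#' @param target_p Named (by set) or unnamed numeric vector of empirical
#'   p-values to correct.
#' @param B Number of bootstrap rounds (default 1000).
#' @param seed Integer seed.
#' @return Numeric vector of corrected p-values, same order/names as
#'   `target_p`.
#' @export
bootstrap_correction <- function(null, target_p, B = 1000L, seed = 1L) {
  stopifnot(inherits(null, "perm_null"))
  B <- check_count(B, "B")
  S <- null$stats
  n <- nrow(S)
  if (n < 2L) abort_gwaset("need at least 2 permutations for the bootstrap")
  K <- ncol(S)
  sorted <- apply(S, 2L, sort)
  if (!is.matrix(sorted)) sorted <- matrix(sorted, nrow = n)
  minp <- with_seed(seed, {
    r <- sample.int(n, B, replace = TRUE)
    pmat <- matrix(NA_real_, nrow = B, ncol = K)
    for (k in seq_len(K)) {
      v <- S[r, k]
      # exceedances among the other n-1 permutations (own draw excluded);
      # findInterval with left.open counts strictly smaller values
      cnt <- n - findInterval(v, sorted[, k], left.open = TRUE) - 1L
      pmat[, k] <- pmax(cnt, 1L) / (n - 1L)
    }
    apply(pmat, 1L, min)
  })
  vapply(target_p, function(tp) mean(minp <= tp + 1e-12), numeric(1))
}

#' Competitive gene-set enrichment test with bootstrap correction
#'
#' End-to-end enrichment analysis of a collection of gene sets against a set
#' of merged LD-independent genomic intervals: computes the observed overlap
#' statistic for every set, a matched-interval permutation null, empirical
#' p-values, and bootstrap-corrected p-values accounting for the correlation
#' between sets.
#'
#' @param intervals Merged `interval_set` with `n_genes`.
#' @param gene_sets Tibble with `set` and `genes` (list-column).
#' @param annotation Gene annotation tibble.
#' @param snp_map SNP map tibble.
#' @param n_perm Number of permutations (default 10,000).
#' @param B Bootstrap rounds for the multiple-set correction
#'   (default 1000).
#' @param margin Gene overlap margin in bp (default 20,000).
#' @param seed Integer seed.
#' @param correct Compute corrected p-values (default TRUE; set FALSE when
#'   only a single set is of interest).
#' @return A tibble of class `enrichment_result`: `set`, `n_genes_total`,
#'   `n_hit`, `empirical_p`, `censored`, `corrected_p`, `hit_genes`
#'   (semicolon-joined), with the `perm_null` attached as attribute
#'   `"null"`.
#' @export
enrichment_test <- function(intervals, gene_sets, annotation, snp_map,
                            n_perm = 10000L, B = 1000L, margin = 20000L,
                            seed = 1L, correct = TRUE) {
  obs <- map(gene_sets$genes, function(gs) {
    overlap_statistic(intervals, gs, annotation, margin = margin)
  })
  null <- permutation_null(intervals, snp_map, annotation, gene_sets,
                           n_perm = n_perm, seed = seed, margin = margin)
  emp <- bind_rows(map2(map_int(obs, "n_hit"), gene_sets$set,
                        function(o, s) empirical_set_p(o, null, s)))
  corrected <- if (correct) {
    bootstrap_correction(null, setNames(emp$p, emp$set), B = B,
                         seed = seed + 1L)
  } else {
    rep(NA_real_, nrow(emp))
  }
  out <- tibble(
    set = gene_sets$set,
    n_genes_total = lengths(gene_sets$genes),
    n_hit = map_int(obs, "n_hit"),
    empirical_p = emp$p,
    censored = emp$censored,
    corrected_p = as.numeric(corrected),
    hit_genes = map_chr(obs, function(o) {
      paste(sort(unique(unlist(strsplit(o$assignments$genes, ";")))),
            collapse = ";")
    })
  )
  attr(out, "null") <- null
  class(out) <- c("enrichment_result", class(out))
  out
}

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(n_sets = nrow(x),
         n_perm = attr(x, "null")$n_perm,
         min_empirical_p = min(x$empirical_p),
         min_corrected_p = suppressWarnings(min(x$corrected_p, na.rm = TRUE)))
}

#' @export
tidy.enrichment_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "enrichment_result")
  attr(out, "null") <- NULL
  out
}

#' Plot gene-set enrichment results
#'
#' -log10 empirical p-value per set, ordered by significance; sets whose
#' corrected p-value stays below 0.05 are highlighted.
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- object |> arrange(.data$empirical_p) |>
    mutate(set = factor(.data$set, levels = rev(.data$set)),
           significant = !is.na(.data$corrected_p) & .data$corrected_p < 0.05)
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$empirical_p), y = .data$set,
                                   fill = .data$significant)) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::labs(x = expression(-log[10](empirical ~ p)), y = NULL,
                  fill = "corrected p < 0.05") +
    ggplot2::theme_minimal()
}
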