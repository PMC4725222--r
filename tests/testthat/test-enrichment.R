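# tiny genome: 2 chromosomes of evenly spaced SNPs with regularly spaced genes
tiny_genome <- function(n_snps_per_chr = 200L, n_genes_per_chr = 10L,
                        spacing = 1000L) {
  snp_map <- dplyr::bind_rows(lapply(1:2, function(ch) {
    tibble::tibble(snp = sprintf("c%ds%d", ch, seq_len(n_snps_per_chr)),
                   chr = ch, pos = as.integer(seq_len(n_snps_per_chr) * spacing))
  }))
  span <- n_snps_per_chr * spacing
  step <- span %/% n_genes_per_chr
  annotation <- dplyr::bind_rows(lapply(1:2, function(ch) {
    start <- as.integer((seq_len(n_genes_per_chr) - 1L) * step + 1L)
    tibble::tibble(gene = sprintf("c%dg%d", ch, seq_len(n_genes_per_chr)),
                   chr = ch, start = start,
                   stop = as.integer(start + step %/% 3L))
  }))
  list(snp_map = snp_map, annotation = annotation)
}

observed_intervals <- function(chr, start, stop, n_snps, n_genes) {
  gwaset:::new_interval_set(tibble::tibble(
    chr = chr, start = start, stop = stop,
    index_snp = sprintf("ix%d", seq_along(chr)), index_p = 1e-4,
    n_snps = n_snps, snps = as.list(sprintf("ix%d", seq_along(chr))),
    snp_p = as.list(rep(1e-4, length(chr))), genes = as.list(rep("", length(chr))),
    n_genes = n_genes))
}

test_that("overlap statistic counts intervals, not genes, with brute-force parity", {
  gen <- tiny_genome()
  iv <- observed_intervals(chr = c(1L, 1L, 2L),
                           start = c(1L, 150001L, 45001L),
                           stop = c(45000L, 160000L, 52000L),
                           n_snps = c(10L, 5L, 3L), n_genes = c(3L, 1L, 1L))
  # one interval covering two set genes counts once
  res <- overlap_statistic(iv, c("c1g1", "c1g2"), gen$annotation, margin = 0L)
  expect_identical(res$n_hit, 1L)
  expect_identical(res$assignments$genes, "c1g1;c1g2")
  # empty set after the annotation join
  res0 <- overlap_statistic(iv, c("unknown_a", "unknown_b"), gen$annotation)
  expect_identical(res0$n_hit, 0L)
  expect_setequal(res0$missing_genes, c("unknown_a", "unknown_b"))
  # a single interval overlapping a single set gene scores exactly 1
  res1 <- overlap_statistic(iv, "c2g3", gen$annotation, margin = 0L)
  expect_identical(res1$n_hit, 1L)
  # brute-force parity over random sets
  sets <- withr::with_seed(5, replicate(10, sample(gen$annotation$gene, 4),
                                        simplify = FALSE))
  for (s in sets) {
    got <- overlap_statistic(iv, s, gen$annotation, margin = 20000L)$n_hit
    ann_s <- gen$annotation[gen$annotation$gene %in% s, ]
    oracle <- sum(brute_interval_gene_overlap(iv, ann_s, margin = 20000L))
    expect_identical(got, as.integer(oracle))
  }
})

test_that("matched intervals honour gene counts and the SNP-count band", {
  gen <- tiny_genome()
  iv <- observed_intervals(chr = c(1L, 2L), start = c(1L, 1L),
                           stop = c(30000L, 60000L),
                           n_snps = c(30L, 60L), n_genes = c(2L, 4L))
  perm <- generate_matched_intervals(iv, gen$snp_map, gen$annotation,
                                     seed = 3L, margin = 0L)
  expect_identical(perm$n_genes, iv$n_genes)
  expect_true(all(perm$n_snps >= ceiling(0.8 * iv$n_snps) &
                    perm$n_snps <= floor(1.2 * iv$n_snps)))
  expect_identical(perm,
                   generate_matched_intervals(iv, gen$snp_map, gen$annotation,
                                              seed = 3L, margin = 0L))
  expect_false(identical(perm,
                         generate_matched_intervals(iv, gen$snp_map,
                                                    gen$annotation,
                                                    seed = 4L, margin = 0L)))
})

test_that("matching fails loudly when no placement can satisfy the constraints", {
  gen <- tiny_genome(n_genes_per_chr = 1L)
  iv <- observed_intervals(chr = 1L, start = 1L, stop = 10000L,
                           n_snps = 5L, n_genes = 8L)
  expect_error(generate_matched_intervals(iv, gen$snp_map, gen$annotation,
                                          seed = 1L, max_attempts = 50L),
               "no eligible matched placement")
})

test_that("matched placements visit every eligible window over many seeds", {
  # genome with exactly two 2-gene clusters: both must appear across seeds
  snp_map <- tibble::tibble(snp = sprintf("s%d", 1:100), chr = 1L,
                            pos = as.integer(1:100 * 1000L))
  annotation <- tibble::tibble(
    gene = c("a1", "a2", "b1", "b2"),
    chr = 1L,
    start = c(10000L, 12000L, 80000L, 82000L),
    stop = c(11000L, 13000L, 81000L, 83000L))
  iv <- observed_intervals(chr = 1L, start = 10000L, stop = 13000L,
                           n_snps = 5L, n_genes = 2L)
  placements <- vapply(1:60, function(s) {
    p <- generate_matched_intervals(iv, snp_map, annotation, seed = s,
                                    margin = 0L)
    paste(sort(p$genes[[1]]), collapse = ",")
  }, character(1))
  expect_identical(sort(unique(placements)), c("a1,a2", "b1,b2"))
})

test_that("empirical set p is the tie-inclusive exceedance proportion", {
  null <- fake_null(matrix(1:10, ncol = 1, dimnames = list(NULL, "s1")))
  res <- empirical_set_p(5L, null, "s1")
  expect_equal(res$p, 0.6)        # 6 of 10 permuted stats are >= 5
  expect_false(res$censored)
  res0 <- empirical_set_p(0L, null, "s1")
  expect_equal(res0$p, 1)         # every permutation >= 0
  resc <- empirical_set_p(99L, null, "s1")
  expect_true(resc$censored)      # reported as "< 1/n_perm"
  expect_equal(resc$p, 1 / 10)
  expect_error(empirical_set_p(1L, null, "nope"), "no permutation null")
})

test_that("permutation null is reproducible and respects set structure", {
  gen <- tiny_genome()
  iv <- observed_intervals(chr = c(1L, 2L), start = c(1L, 40001L),
                           stop = c(25000L, 65000L),
                           n_snps = c(25L, 25L), n_genes = c(2L, 2L))
  sets <- tibble::tibble(set = c("all_genes", "half"),
                         genes = list(gen$annotation$gene,
                                      gen$annotation$gene[1:10]))
  null <- permutation_null(iv, gen$snp_map, gen$annotation, sets,
                           n_perm = 50L, seed = 8L, margin = 0L)
  null2 <- permutation_null(iv, gen$snp_map, gen$annotation, sets,
                            n_perm = 50L, seed = 8L, margin = 0L)
  expect_identical(null$stats, null2$stats)
  # every matched interval overlaps >= 1 gene (counts matched at 2), so the
  # all-gene set is always hit by both intervals
  expect_true(all(null$stats[, "all_genes"] == 2L))
  expect_true(all(null$stats[, "half"] <= 2L))
})

test_that("bootstrap correction: single set stays at its empirical p", {
  stats <- matrix(withr::with_seed(10, rbinom(2000, 40, 0.3)), ncol = 1)
  null <- fake_null(stats)
  obs <- 18L
  p_emp <- empirical_set_p(obs, null, "set1")$p
  p_corr <- bootstrap_correction(null, setNames(p_emp, "set1"), B = 1000L,
                                 seed = 11L)
  expect_lt(abs(p_corr - p_emp), 0.05)
})

test_that("bootstrap correction: duplicated sets do not inflate", {
  base <- withr::with_seed(12, rbinom(2000, 40, 0.3))
  stats <- matrix(rep(base, 6), ncol = 6)
  null <- fake_null(stats)
  p_emp <- empirical_set_p(18L, null, "set1")$p
  p_corr <- bootstrap_correction(null, setNames(p_emp, "set1"), B = 1000L,
                                 seed = 13L)
  expect_lt(abs(p_corr - p_emp), 0.05)       # not 6 * p_emp
})

test_that("bootstrap correction: independent sets approach the Sidak limit", {
  K <- 5
  stats <- withr::with_seed(14, matrix(rnorm(2000 * K), ncol = K))
  null <- fake_null(stats)
  p_star <- 0.1
  p_corr <- bootstrap_correction(null, p_star, B = 1000L, seed = 15L)
  expect_lt(abs(p_corr - (1 - (1 - p_star)^K)), 0.05)
})

test_that("corrected p is monotone in the target empirical p", {
  stats <- withr::with_seed(16, matrix(rnorm(1000 * 3), ncol = 3))
  null <- fake_null(stats)
  targets <- c(0.01, 0.05, 0.2, 0.5, 0.9)
  out <- bootstrap_correction(null, targets, B = 500L, seed = 17L)
  expect_true(all(diff(out) >= 0))
})

test_that("enrichment_test assembles the full report", {
  gen <- tiny_genome()
  iv <- observed_intervals(chr = c(1L, 2L), start = c(1L, 40001L),
                           stop = c(25000L, 65000L),
                           n_snps = c(25L, 25L), n_genes = c(2L, 2L))
  sets <- tibble::tibble(set = c("s1", "s2"),
                         genes = list(gen$annotation$gene[c(1, 2)],
                                      gen$annotation$gene[15:18]))
  er <- enrichment_test(iv, sets, gen$annotation, gen$snp_map,
                        n_perm = 100L, B = 200L, margin = 0L, seed = 19L)
  expect_s3_class(er, "enrichment_result")
  expect_identical(er$n_genes_total, c(2L, 4L))
  expect_true(all(er$empirical_p > 0 & er$empirical_p <= 1))
  expect_true(all(er$corrected_p >= 0 & er$corrected_p <= 1))
  expect_s3_class(attr(er, "null"), "perm_null")
  expect_identical(glance(er)$n_perm, 100L)
})
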