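make_assoc <- function(snp, chr, pos, p) {
  a <- tibble::tibble(snp = snp, chr = chr, pos = pos, a1 = "A",
                      beta = 0, se = 1, p = p, n = 100L)
  class(a) <- c("assoc_table", class(a))
  a
}

# five SNPs within 250 kb; 1-2 and 4-5 in strong LD, everything else unlinked
toy_clump_fixture <- function() {
  n <- 200L
  d <- withr::with_seed(77, {
    x1 <- rbinom(n, 2L, 0.4)
    x3 <- rbinom(n, 2L, 0.4)
    x4 <- rbinom(n, 2L, 0.4)
    cbind(s1 = x1, s2 = correlated_dosage(x1, 10L), s3 = x3,
          s4 = x4, s5 = correlated_dosage(x4, 10L))
  })
  geno <- make_geno(d, pos = as.integer(c(1e5, 1.5e5, 2e5, 2.5e5, 3e5)))
  assoc <- make_assoc(colnames(d), 1L, geno$snp_map$pos,
                      c(1e-5, 0.01, 0.2, 1e-4, 0.03))
  list(geno = geno, assoc = assoc)
}

test_that("the LD fixture has the intended correlation structure", {
  fx <- toy_clump_fixture()
  r2 <- cor(fx$geno$dosages)^2
  expect_gt(r2["s1", "s2"], 0.5)
  expect_gt(r2["s4", "s5"], 0.5)
  off <- r2[cbind(c("s1", "s1", "s2", "s3"), c("s3", "s4", "s5", "s5"))]
  expect_true(all(off < 0.5))
})

test_that("greedy clumping matches the hand-traced five-SNP oracle", {
  fx <- toy_clump_fixture()
  iv <- clump(fx$assoc, fx$geno, clump_params())
  expect_identical(nrow(iv), 2L)
  expect_identical(iv$index_snp, c("s1", "s4"))
  expect_setequal(iv$snps[[1]], c("s1", "s2"))
  expect_setequal(iv$snps[[2]], c("s4", "s5"))   # s3 unclaimed: p > 0.05
  expect_identical(iv$start, c(100000L, 250000L))
  expect_identical(iv$stop, c(150000L, 300000L))
})

test_that("no eligible index SNP yields an empty interval list", {
  fx <- toy_clump_fixture()
  a <- fx$assoc
  a$p <- rep(0.01, 5)
  expect_identical(nrow(clump(a, fx$geno)), 0L)
})

test_that("index ties break to the lower chromosome and position", {
  d <- withr::with_seed(78, matrix(rbinom(400, 2L, 0.4), 100))
  g <- make_geno(d, chr = c(2L, 2L, 1L, 1L), pos = c(500L, 100L, 900L, 100L))
  a <- make_assoc(colnames(g$dosages), g$snp_map$chr, g$snp_map$pos,
                  rep(1e-5, 4))
  iv <- clump(a, g, clump_params())
  expect_identical(iv$index_snp[1], "s4")  # chr 1, pos 100
})

test_that("no SNP is claimed by two clumps", {
  cfg <- tiny_config(n_individuals = 500L, n_chromosomes = 2L,
                     snps_per_chromosome = 200L, seed = 91L)
  g <- simulate_genotypes(cfg)
  a <- make_assoc(g$snp_map$snp, g$snp_map$chr, g$snp_map$pos,
                  withr::with_seed(92, runif(400)^3))
  iv <- clump(a, g, clump_params(index_p_max = 0.05))
  members <- unlist(iv$snps)
  expect_identical(anyDuplicated(members), 0L)
})

test_that("SNPs absent from the LD panel are treated as uncorrelated and logged", {
  fx <- toy_clump_fixture()
  g_small <- subset_geno(fx$geno, snps = c("s1", "s3", "s4", "s5"))
  iv <- clump(fx$assoc, g_small, clump_params())
  expect_false("s2" %in% unlist(iv$snps))
  expect_true("s2" %in% attr(iv, "missing_ld"))
})

test_that("gene-overlap filter honours the inclusive 20 kb margin", {
  ann <- tibble::tibble(gene = "g1", chr = 1L, start = 50000L, stop = 60000L)
  iv <- gwaset:::new_interval_set(tibble::tibble(
    chr = 1L, start = c(80000L, 80001L, 1000L), stop = c(90000L, 90001L, 2000L),
    index_snp = c("a", "b", "c"), index_p = 1e-5, n_snps = 1L,
    snps = list("a", "b", "c"), snp_p = list(1e-5, 1e-5, 1e-5)))
  kept <- filter_to_genes(iv, ann, margin = 20000L)
  expect_identical(kept$index_snp, "a")   # start = stop + 20000 retained
  expect_identical(kept$genes[[1]], "g1")
})

test_that("intervals on gene-free chromosomes are dropped", {
  ann <- tibble::tibble(gene = "g1", chr = 2L, start = 1L, stop = 100L)
  iv <- gwaset:::new_interval_set(tibble::tibble(
    chr = 1L, start = 1L, stop = 100L, index_snp = "a", index_p = 1e-5,
    n_snps = 1L, snps = list("a"), snp_p = list(1e-5)))
  expect_identical(nrow(filter_to_genes(iv, ann)), 0L)
})

test_that("gene-overlap filtering equals a brute-force all-pairs scan", {
  dat <- withr::with_seed(93, {
    s <- sample.int(4e5, 30)
    g <- sample.int(4e5, 12)
    list(iv = tibble::tibble(chr = sample(1:2, 30, replace = TRUE),
                             start = s, stop = s + sample.int(3e4, 30)),
         ann = tibble::tibble(gene = sprintf("g%d", 1:12),
                              chr = sample(1:2, 12, replace = TRUE),
                              start = g, stop = g + sample.int(5e4, 12)))
  })
  iv <- gwaset:::new_interval_set(dplyr::mutate(dat$iv, index_snp = "x",
                                                index_p = 1e-5, n_snps = 1L,
                                                snps = list("x"),
                                                snp_p = list(1e-5)))
  kept <- filter_to_genes(iv, dat$ann, margin = 20000L)
  oracle <- brute_interval_gene_overlap(dat$iv, dat$ann, margin = 20000L)
  expect_identical(paste(kept$chr, kept$start),
                   paste(dat$iv$chr[oracle], dat$iv$start[oracle]))
})

test_that("merging is a sweep-line union with smallest-p index selection", {
  iv <- gwaset:::new_interval_set(tibble::tibble(
    chr = c(1L, 1L, 1L, 2L),
    start = c(100L, 500L, 900L, 100L),
    stop = c(600L, 1000L, 1500L, 200L),
    index_snp = c("a", "b", "c", "d"),
    index_p = c(1e-4, 1e-6, 1e-5, 1e-4),
    n_snps = 1L,
    snps = list("a", "b", "c", "d"),
    snp_p = list(1e-4, 1e-6, 1e-5, 1e-4)))
  m <- merge_overlapping(iv)
  expect_identical(nrow(m), 2L)                      # chain a-b-c merges
  expect_identical(m$start, c(100L, 100L))
  expect_identical(m$stop, c(1500L, 200L))
  expect_identical(m$index_snp[1], "b")              # smallest member p
  expect_setequal(m$snps[[1]], c("a", "b", "c"))
  # disjoint input is unchanged; merge is idempotent
  expect_identical(nrow(merge_overlapping(m)), 2L)
  expect_equal(merge_overlapping(m)$start, m$start)
})

test_that("merged union length equals a bp-occupancy brute force", {
  iv <- withr::with_seed(94, {
    s <- sample.int(5e4, 100)
    gwaset:::new_interval_set(tibble::tibble(
      chr = sample(1:3, 100, replace = TRUE),
      start = s, stop = s + sample.int(2e3, 100),
      index_snp = sprintf("s%d", 1:100), index_p = runif(100),
      n_snps = 1L, snps = as.list(sprintf("s%d", 1:100)),
      snp_p = as.list(runif(100))))
  })
  m <- merge_overlapping(iv)
  union_len <- sum(m$stop - m$start + 1L)
  occupancy <- sum(vapply(1:3, function(ch) {
    occ <- logical(6e4)
    rows <- which(iv$chr == ch)
    for (i in rows) occ[iv$start[i]:iv$stop[i]] <- TRUE
    sum(occ)
  }, numeric(1)))
  expect_identical(as.numeric(union_len), occupancy)
  # output is pairwise non-overlapping per chromosome
  for (ch in unique(m$chr)) {
    mm <- m[m$chr == ch, ]
    if (nrow(mm) > 1) expect_true(all(mm$start[-1] > mm$stop[-nrow(mm)]))
  }
})
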