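# shared builders for small in-memory fixtures; everything is generated in
# code so tests carry no data files

tiny_config <- function(..., seed = 42L) {
  args <- utils::modifyList(
    list(n_individuals = 200L, n_chromosomes = 2L, snps_per_chromosome = 60L,
         ld_block_size = 6L, within_block_rho = 0.6, n_genes = 20L,
         gene_length_range = c(1e3, 3e4), snp_spacing_bp = 3000L,
         seed = seed),
    list(...))
  do.call(sim_config, args)
}

# genotype object built directly from a dosage matrix (bypasses simulation)
make_geno <- function(dosages, chr = NULL, pos = NULL, age = NULL, sex = NULL) {
  n <- nrow(dosages)
  s <- ncol(dosages)
  snp <- colnames(dosages) %||% sprintf("s%d", seq_len(s))
  colnames(dosages) <- snp
  gwaset:::new_geno_data(
    dosages,
    tibble::tibble(snp = snp, chr = chr %||% rep(1L, s),
                   pos = pos %||% as.integer(seq_len(s) * 1000L),
                   a1 = "A", a2 = "B"),
    tibble::tibble(iid = sprintf("i%d", seq_len(n)),
                   age = age %||% rep(70, n),
                   sex = sex %||% rep(0L, n))
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# dosage vector correlated with x: flip a few entries
correlated_dosage <- function(x, n_flip) {
  y <- x
  idx <- seq_len(n_flip)
  y[idx] <- (y[idx] + 1L) %% 3L
  y
}

# brute-force interval/point overlap scans used as oracles
brute_snp_in_window <- function(snp_map, windows) {
  hits <- list()
  for (i in seq_len(nrow(snp_map))) {
    for (j in seq_len(nrow(windows))) {
      if (snp_map$chr[i] == windows$chr[j] &&
          snp_map$pos[i] >= windows$window_start[j] &&
          snp_map$pos[i] <= windows$window_stop[j]) {
        hits[[length(hits) + 1L]] <- c(i, j)
      }
    }
  }
  do.call(rbind, hits)
}

brute_interval_gene_overlap <- function(intervals, annotation, margin) {
  keep <- logical(nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    for (j in seq_len(nrow(annotation))) {
      if (intervals$chr[i] == annotation$chr[j] &&
          intervals$start[i] <= annotation$stop[j] + margin &&
          intervals$stop[i] >= annotation$start[j] - margin) {
        keep[i] <- TRUE
      }
    }
  }
  keep
}

# a perm_null object built directly from a statistic matrix
fake_null <- function(stats) {
  if (is.null(colnames(stats))) colnames(stats) <- sprintf("set%d", seq_len(ncol(stats)))
  structure(list(stats = stats, sets = colnames(stats),
                 n_perm = nrow(stats), seed = NA_integer_, margin = 20000L),
            class = "perm_null")
}
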