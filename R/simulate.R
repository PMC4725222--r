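#' Simulation configuration for a synthetic GWAS cohort
#'
#' Bundles every parameter of the synthetic genotype/phenotype generator.
#' Defaults describe the cohort structure the analysis pipeline was designed
#' around: roughly 3,500 unrelated older adults, a dense biallelic SNP panel
#' with common variants (MAF > 0.01) in Hardy-Weinberg equilibrium, block-wise
#' linkage disequilibrium, and a battery of cognitive tests loading on a
#' single latent general factor with additive age and sex effects.
#'
#' @param n_individuals Number of unrelated individuals (default 3500).
#' @param n_chromosomes Number of chromosomes to simulate (default 22).
#' @param snps_per_chromosome SNPs per chromosome (default 250).
#' @param ld_block_size Number of consecutive SNPs forming one LD block
#'   (default 10). Adjacent SNPs within a block are correlated; SNPs in
#'   different blocks are independent.
#' @param within_block_rho Latent AR(1) correlation between adjacent SNPs in
#'   a block, in `[0, 1)` (default 0.8). Genotype (dosage) correlation is an
#'   increasing function of this value but attenuated by the threshold model.
#' @param maf_range Range of per-SNP minor allele frequencies, drawn
#'   uniformly, within `(0, 0.5]` (default `c(0.05, 0.5)`).
#' @param n_genes Number of non-overlapping gene bodies to place
#'   (default 200).
#' @param gene_length_range Gene body lengths in bp (default `c(1e3, 1e5)`).
#' @param snp_spacing_bp Mean inter-SNP spacing in bp (default 5000);
#'   spacings are exponential, so positions form a Poisson-like process.
#' @param n_tests Number of observed cognitive tests (default 6).
#' @param loading_range Factor loadings of the tests on latent g, drawn
#'   uniformly, within `(0, 1]` (default `c(0.5, 0.8)`).
#' @param causal_spec Optional tibble/data.frame with columns `snp` and
#'   `effect` (phenotype SD per minor allele) giving causal SNPs for the
#'   latent factor. `NULL` (default) simulates a fully null cohort.
#' @param age_range Age range in years, uniform (default `c(64, 80)`).
#' @param age_slope Effect of one year of age on latent g, in SD units
#'   (default -0.03, mild cognitive ageing).
#' @param sex_effect Mean difference (SD units) between sex = 1 and sex = 0
#'   on latent g (default 0.1).
#' @param missing_rate Probability that any single genotype call is missing
#'   (default 0; raise it to exercise call-rate QC).
#' @param seed Integer seed; every generator operation is deterministic
#'   given the config.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_individuals = 3500,
                       n_chromosomes = 22,
                       snps_per_chromosome = 250,
                       ld_block_size = 10,
                       within_block_rho = 0.8,
                       maf_range = c(0.05, 0.5),
                       n_genes = 200,
                       gene_length_range = c(1e3, 1e5),
                       snp_spacing_bp = 5000,
                       n_tests = 6,
                       loading_range = c(0.5, 0.8),
                       causal_spec = NULL,
                       age_range = c(64, 80),
                       age_slope = -0.03,
                       sex_effect = 0.1,
                       missing_rate = 0,
                       seed = 1L) {
  cfg <- list(
    n_individuals = check_count(n_individuals, "n_individuals"),
    n_chromosomes = check_count(n_chromosomes, "n_chromosomes"),
    snps_per_chromosome = check_count(snps_per_chromosome, "snps_per_chromosome"),
    ld_block_size = check_count(ld_block_size, "ld_block_size"),
    within_block_rho = check_prob(within_block_rho, "within_block_rho",
                                  lo = 0, hi = 1, lo_open = FALSE),
    maf_range = check_range(maf_range, "maf_range", 0, 0.5, lo_open = TRUE),
    n_genes = check_count(n_genes, "n_genes", min = 0L),
    gene_length_range = check_range(gene_length_range, "gene_length_range", 1, Inf),
    snp_spacing_bp = check_count(snp_spacing_bp, "snp_spacing_bp"),
    n_tests = check_count(n_tests, "n_tests"),
    loading_range = check_range(loading_range, "loading_range", 0, 1, lo_open = TRUE),
    causal_spec = causal_spec,
    age_range = check_range(age_range, "age_range", 0, Inf),
    age_slope = as.numeric(age_slope),
    sex_effect = as.numeric(sex_effect),
    missing_rate = check_prob(missing_rate, "missing_rate",
                              lo = 0, hi = 1, lo_open = FALSE),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$ld_block_size > cfg$snps_per_chromosome) {
    abort_gwaset("`ld_block_size` cannot exceed `snps_per_chromosome`")
  }
  if (!is.null(causal_spec)) {
    if (!is.data.frame(causal_spec) || !all(c("snp", "effect") %in% names(causal_spec))) {
      abort_gwaset("`causal_spec` must be a data frame with columns `snp` and `effect`")
    }
    cfg$causal_spec <- as_tibble(causal_spec)
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d individuals, %d chr x %d SNPs (blocks of %d, rho = %.2f)\n",
              x$n_individuals, x$n_chromosomes, x$snps_per_chromosome,
              x$ld_block_size, x$within_block_rho))
  cat(sprintf("  %d genes, %d tests, %s causal SNPs, seed %d\n",
              x$n_genes, x$n_tests,
              if (is.null(x$causal_spec)) "no" else nrow(x$causal_spec),
              x$seed))
  invisible(x)
}

new_geno_data <- function(dosages, snp_map, samples) {
  stopifnot(nrow(dosages) == nrow(samples), ncol(dosages) == nrow(snp_map))
  structure(list(dosages = dosages, snp_map = snp_map, samples = samples),
            class = "geno_data")
}

#' @export
print.geno_data <- function(x, ...) {
  cat(sprintf("<geno_data> %d individuals x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$snp_map$chr))))
  invisible(x)
}

#' Number of samples / SNPs in a genotype object
#' @param geno A `geno_data` object.
#' @return Integer count.
#' @export
n_samples <- function(geno) nrow(geno$dosages)

#' @rdname n_samples
#' @export
n_snps <- function(geno) ncol(geno$dosages)

#' Subset a genotype object by samples and/or SNPs
#'
#' @param geno A `geno_data` object.
#' @param samples Character ids (or logical/integer index) of individuals to
#'   keep; `NULL` keeps all.
#' @param snps Character ids (or logical/integer index) of SNPs to keep;
#'   `NULL` keeps all.
#' @return A `geno_data` object.
#' @export
subset_geno <- function(geno, samples = NULL, snps = NULL) {
  ri <- seq_len(nrow(geno$dosages))
  ci <- seq_len(ncol(geno$dosages))
  if (!is.null(samples)) {
    ri <- if (is.character(samples)) match(samples, geno$samples$iid) else ri[samples]
    if (anyNA(ri)) abort_gwaset("unknown sample id in `samples`")
  }
  if (!is.null(snps)) {
    ci <- if (is.character(snps)) match(snps, geno$snp_map$snp) else ci[snps]
    if (anyNA(ci)) abort_gwaset("unknown SNP id in `snps`")
  }
  new_geno_data(geno$dosages[ri, ci, drop = FALSE],
                geno$snp_map[ci, , drop = FALSE],
                geno$samples[ri, , drop = FALSE])
}

#' Simulate genotypes with block-wise linkage disequilibrium
#'
#' Draws per-SNP minor allele frequencies uniformly from `maf_range` and
#' generates two haplotypes per individual from a latent Gaussian threshold
#' model: within an LD block latent values follow an AR(1) process with
#' correlation `within_block_rho`, and an allele is the minor allele when its
#' latent value falls below the MAF quantile. Marginally every SNP is in
#' Hardy-Weinberg equilibrium; adjacent SNPs within a block are correlated,
#' SNPs in different blocks are independent.
#'
#' @param config A [sim_config()].
#' @return A `geno_data` object: `dosages` (individuals x SNPs minor-allele
#'   counts in \{0, 1, 2\}, `NA` = missing), `snp_map` (snp, chr, pos, a1,
#'   a2; positions strictly increasing within chromosome; a1 is the minor
#'   allele), and `samples` (iid, age, sex).
#' @examples
#' g <- simulate_genotypes(sim_config(n_individuals = 50, n_chromosomes = 2,
#'                                    snps_per_chromosome = 20, seed = 7))
#' g
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  s_chr <- config$snps_per_chromosome
  rho <- config$within_block_rho
  with_seed(config$seed, {
    maps <- vector("list", config$n_chromosomes)
    dos <- vector("list", config$n_chromosomes)
    for (chr in seq_len(config$n_chromosomes)) {
      maf <- runif(s_chr, config$maf_range[1], config$maf_range[2])
      gaps <- pmax(1, round(stats::rexp(s_chr, 1 / config$snp_spacing_bp)))
      pos <- cumsum(gaps)
      # two haplotypes per individual share the AR(1) block structure but are
      # independent of each other, giving HWE marginals
      z <- matrix(rnorm(2L * n * s_chr), nrow = 2L * n, ncol = s_chr)
      if (rho > 0) {
        w <- sqrt(1 - rho^2)
        block_start <- (seq_len(s_chr) - 1L) %% config$ld_block_size == 0L
        for (j in seq_len(s_chr)[-1]) {
          if (!block_start[j]) z[, j] <- rho * z[, j - 1L] + w * z[, j]
        }
      }
      thr <- qnorm(maf)
      hap <- sweep(z, 2L, thr, `<`)
      d <- hap[seq_len(n), , drop = FALSE] + hap[n + seq_len(n), , drop = FALSE]
      storage.mode(d) <- "integer"
      dos[[chr]] <- d
      maps[[chr]] <- tibble(
        snp = sprintf("rs%d_%d", chr, seq_len(s_chr)),
        chr = chr, pos = as.integer(pos), a1 = "A", a2 = "B",
        maf_true = maf
      )
    }
    dosages <- do.call(cbind, dos)
    snp_map <- bind_rows(maps)
    colnames(dosages) <- snp_map$snp
    if (config$missing_rate > 0) {
      miss <- runif(length(dosages)) < config$missing_rate
      dosages[miss] <- NA_integer_
    }
    samples <- tibble(
      iid = sprintf("ind_%05d", seq_len(n)),
      age = runif(n, config$age_range[1], config$age_range[2]),
      sex = rbinom(n, 1L, 0.5)
    )
    rownames(dosages) <- samples$iid
    new_geno_data(dosages, snp_map, samples)
  })
}

#' Simulate a cognitive test battery from a one-factor model
#'
#' Builds a latent general factor g as the sum of causal-SNP effects
#' (phenotype SD per minor allele), a linear age trend, a sex effect, and
#' Gaussian noise, scaled to unit variance; each observed test is
#' `loading * g + unique noise` with unit marginal variance.
#'
#' @param geno A `geno_data` from [simulate_genotypes()].
#' @param config The same [sim_config()]; `causal_spec` SNP ids must exist
#'   in `geno`.
#' @return A tibble with columns `iid`, `age`, `sex`, `g_true` (the latent
#'   factor) and one `test_*` column per observed test.
#' @export
simulate_phenotypes <- function(geno, config) {
  stopifnot(inherits(config, "sim_config"), inherits(geno, "geno_data"))
  n <- n_samples(geno)
  with_seed(config$seed + 1L, {
    genetic <- numeric(n)
    if (!is.null(config$causal_spec) && nrow(config$causal_spec) > 0) {
      missing_ids <- setdiff(config$causal_spec$snp, geno$snp_map$snp)
      if (length(missing_ids) > 0) {
        abort_gwaset(paste0("unknown causal SNP id(s): ",
                            paste(missing_ids, collapse = ", ")))
      }
      d <- geno$dosages[, config$causal_spec$snp, drop = FALSE]
      # mean-impute the rare missing call so effects stay additive
      if (anyNA(d)) {
        d <- apply(d, 2L, function(x) {
          x[is.na(x)] <- mean(x, na.rm = TRUE)
          x
        })
      }
      genetic <- as.numeric(d %*% config$causal_spec$effect)
    }
    res_sd <- sqrt(max(0.05, 1 - var(genetic)))
    core <- genetic + rnorm(n, 0, res_sd)
    g <- as.numeric(scale(core)) +
      config$age_slope * (geno$samples$age - mean(geno$samples$age)) +
      config$sex_effect * (geno$samples$sex - mean(geno$samples$sex))
    g <- as.numeric(scale(g))
    loadings <- runif(config$n_tests, config$loading_range[1], config$loading_range[2])
    tests <- vapply(loadings, function(l) l * g + rnorm(n, 0, sqrt(1 - l^2)),
                    numeric(n))
    colnames(tests) <- sprintf("test_%d", seq_len(config$n_tests))
    out <- bind_cols(geno$samples, as_tibble(tests))
    out$g_true <- g
    attr(out, "loadings") <- loadings
    out
  })
}

#' Simulate non-overlapping gene annotation over the SNP panel
#'
#' Places `n_genes` non-overlapping gene bodies on the simulated chromosomes
#' (1-based, inclusive coordinates), with lengths drawn uniformly from
#' `gene_length_range`, and records the number of panel SNPs falling inside
#' each gene body.
#'
#' @param geno A `geno_data`; defines the coordinate space (each chromosome
#'   spans from 1 to its last SNP position plus one mean spacing).
#' @param config The same [sim_config()].
#' @param max_tries Resampling attempts per chromosome before failing
#'   (default 100).
#' @return A tibble: `gene`, `chr`, `start`, `stop`, `n_snps`.
#' @export
simulate_annotation <- function(geno, config, max_tries = 100L) {
  stopifnot(inherits(config, "sim_config"), inherits(geno, "geno_data"))
  if (config$n_genes == 0L) {
    return(tibble(gene = character(), chr = integer(), start = integer(),
                  stop = integer(), n_snps = integer()))
  }
  with_seed(config$seed + 2L, {
    chrs <- sort(unique(geno$snp_map$chr))
    chr_len <- vapply(chrs, function(ch) {
      max(geno$snp_map$pos[geno$snp_map$chr == ch]) + config$snp_spacing_bp
    }, numeric(1))
    # allocate genes across chromosomes proportional to length
    alloc <- as.integer(stats::rmultinom(1, config$n_genes, chr_len / sum(chr_len)))
    out <- vector("list", length(chrs))
    for (i in seq_along(chrs)) {
      k <- alloc[i]
      if (k == 0L) next
      L <- chr_len[i]
      placed <- NULL
      for (try in seq_len(max_tries)) {
        lens <- round(runif(k, config$gene_length_range[1], config$gene_length_range[2]))
        free <- L - sum(lens) - k
        if (free < 0) next
        gaps <- diff(c(0, sort(runif(k, 0, free))))
        starts <- cumsum(gaps) + cumsum(c(0, head(lens, -1) + 1)) + 1
        placed <- tibble(chr = chrs[i],
                         start = as.integer(round(starts)),
                         stop = as.integer(round(starts) + lens - 1))
        break
      }
      if (is.null(placed)) {
        abort_gwaset(sprintf(
          "could not place %d genes on chromosome %d after %d attempts",
          k, chrs[i], max_tries))
      }
      out[[i]] <- placed
    }
    ann <- bind_rows(out) |> arrange(.data$chr, .data$start)
    ann$gene <- sprintf("gene_%04d", seq_len(nrow(ann)))
    ann$n_snps <- map_int(seq_len(nrow(ann)), function(j) {
      sum(geno$snp_map$chr == ann$chr[j] &
            geno$snp_map$pos >= ann$start[j] &
            geno$snp_map$pos <= ann$stop[j])
    })
    select(ann, "gene", "chr", "start", "stop", "n_snps")
  })
}

#' Simulate a collection of gene sets
#'
#' Samples gene sets of the requested sizes without replacement from the
#' annotation. Optionally the first set is forced to contain designated
#' causal genes, producing a truly enriched set for positive-control runs.
#'
#' @param annotation A gene annotation tibble (from [simulate_annotation()]
#'   or [read_annotation()]).
#' @param sizes Integer vector of set sizes.
#' @param causal_genes Character vector of gene ids that must appear in the
#'   first (enriched) set; default none.
#' @param seed Integer seed.
#' @return A tibble: `set`, `description`, `genes` (list-column of gene ids).
#' @export
simulate_gene_sets <- function(annotation, sizes, causal_genes = character(),
                               seed = 1L) {
  sizes <- vapply(sizes, check_count, integer(1), name = "sizes")
  if (any(sizes > nrow(annotation))) {
    abort_gwaset("a requested set size exceeds the number of annotated genes")
  }
  if (!all(causal_genes %in% annotation$gene)) {
    abort_gwaset("`causal_genes` must all be present in the annotation")
  }
  with_seed(seed, {
    genes <- annotation$gene
    members <- map(seq_along(sizes), function(i) {
      if (i == 1L && length(causal_genes) > 0) {
        if (sizes[i] < length(causal_genes)) {
          abort_gwaset("first set size is smaller than the number of causal genes")
        }
        extra <- sample(setdiff(genes, causal_genes),
                        sizes[i] - length(causal_genes))
        sort(c(causal_genes, extra))
      } else {
        sort(sample(genes, sizes[i]))
      }
    })
    tibble(
      set = sprintf("set_%03d", seq_along(sizes)),
      description = ifelse(seq_along(sizes) == 1L & length(causal_genes) > 0,
                           "enriched", "random"),
      genes = members
    )
  })
}
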