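#' Run the full gene-set enrichment pipeline on a synthetic cohort
#'
#' Orchestrates every analysis level end-to-end: cohort simulation,
#' phenotype derivation (first unrotated principal component of the test
#' battery, age/sex residualisation), sample and marker QC, ancestry
#' principal components, the additive single-marker scan, greedy LD clumping
#' into genomic intervals with gene-overlap filtering and merging (the three
#' interval counts — raw, gene-overlapping, merged — are reported per run),
#' optional gene-based testing, and the competitive gene-set test with
#' bootstrap multiple-set correction.
#'
#' When `out_dir` is given every interchange table is written as TSV along
#' with a JSON manifest of all parameter values and seeds, sufficient to
#' re-execute the run bit-identically via [run_from_manifest()].
#'
#' @param config A [sim_config()] describing the cohort (its `seed` drives
#'   every stage).
#' @param gene_sets Tibble (`set`, `genes`) of sets to test; `NULL`
#'   simulates `n_sets` random sets of sizes drawn from `set_size_range`.
#' @param n_sets,set_size_range Used only when `gene_sets` is `NULL`
#'   (defaults 20 sets of 5-80 genes).
#' @param causal_set_genes Character vector of gene ids forced into the
#'   first simulated set (positive-control runs); default none.
#' @param qc A [qc_thresholds()].
#' @param params A [clump_params()].
#' @param k_pcs Number of ancestry PCs used as covariates (default 4).
#' @param n_perm Permutations for the set test (default 1000 at simulation
#'   scale; raise to 10,000 for production-size runs).
#' @param B Bootstrap rounds for the multiple-set correction (default 1000).
#' @param do_gene_test Also run the per-gene sum-of-chi-squares test
#'   (default FALSE; it is the slowest stage).
#' @param out_dir Optional output directory for TSV artifacts + manifest.
#' @return A list: `geno`, `pheno`, `annotation`, `gene_sets`, `assoc`,
#'   `gene_scores` (or NULL), `intervals_raw`, `intervals_gene`,
#'   `intervals_merged`, `interval_counts` (tibble raw/gene_overlap/merged),
#'   `enrichment`, `qc_log`, `manifest`.
#' @export
run_pipeline <- function(config,
                         gene_sets = NULL,
                         n_sets = 20L,
                         set_size_range = c(5L, 80L),
                         causal_set_genes = character(),
                         qc = qc_thresholds(),
                         params = clump_params(),
                         k_pcs = 4L,
                         n_perm = 1000L,
                         B = 1000L,
                         do_gene_test = FALSE,
                         out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  geno <- simulate_genotypes(config)
  pheno <- simulate_phenotypes(geno, config)
  annotation <- simulate_annotation(geno, config)

  qc_res <- apply_qc(geno, qc)
  geno_qc <- qc_res$geno
  pheno <- pheno[match(geno_qc$samples$iid, pheno$iid), , drop = FALSE]
  pheno <- derive_general_factor(pheno)

  pcs <- genotype_pcs(geno_qc, k = k_pcs)
  assoc <- run_gwas(geno_qc, pheno$g, covariates = pcs)

  if (is.null(gene_sets)) {
    sizes <- with_seed(config$seed + 3L, {
      sample(set_size_range[1]:min(set_size_range[2], nrow(annotation)),
             n_sets, replace = TRUE)
    })
    if (length(causal_set_genes) > 0) {
      sizes[1] <- max(sizes[1], length(causal_set_genes))
    }
    gene_sets <- simulate_gene_sets(annotation, sizes,
                                    causal_genes = causal_set_genes,
                                    seed = config$seed + 4L)
  }

  gene_scores <- NULL
  if (do_gene_test) {
    gene_scores <- gene_test(assoc, geno_qc, annotation,
                             seed = config$seed + 5L)
  }

  raw <- clump(assoc, geno_qc, params)
  gene_ov <- filter_to_genes(raw, annotation, margin = params$gene_margin_bp)
  merged <- merge_overlapping(gene_ov)
  interval_counts <- tibble(stage = c("raw", "gene_overlap", "merged"),
                            n = c(nrow(raw), nrow(gene_ov), nrow(merged)))

  enrich <- if (nrow(merged) > 0L) {
    enrichment_test(merged, gene_sets, annotation, geno_qc$snp_map,
                    n_perm = n_perm, B = B, margin = params$gene_margin_bp,
                    seed = config$seed + 6L)
  } else {
    NULL
  }

  manifest <- list(
    package = "gwaset",
    version = as.character(utils::packageVersion("gwaset")),
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    qc = unclass(qc),
    clump_params = unclass(params),
    k_pcs = k_pcs, n_perm = n_perm, B = B,
    n_sets = n_sets, set_size_range = set_size_range,
    causal_set_genes = causal_set_genes,
    do_gene_test = do_gene_test,
    interval_counts = setNames(interval_counts$n, interval_counts$stage)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_geno(geno, file.path(out_dir, "cohort"))
    write_phenotypes(pheno, file.path(out_dir, "phenotypes.tsv"))
    write_annotation(annotation, file.path(out_dir, "annotation.tsv"))
    write_gmt(gene_sets, file.path(out_dir, "gene_sets.gmt"))
    write_assoc(assoc, file.path(out_dir, "assoc.tsv"))
    write_intervals(merged, file.path(out_dir, "intervals_merged.tsv"))
    if (!is.null(enrich)) {
      write_enrichment(enrich, file.path(out_dir, "enrichment.tsv"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(geno = geno, pheno = pheno, annotation = annotation,
       gene_sets = gene_sets, assoc = assoc, gene_scores = gene_scores,
       intervals_raw = raw, intervals_gene = gene_ov,
       intervals_merged = merged, interval_counts = interval_counts,
       enrichment = enrich, qc_log = qc_res[c("snp_log", "sample_log")],
       manifest = manifest)
}

#' Re-execute a pipeline run from its manifest
#'
#' Reads a manifest written by [run_pipeline()] and re-runs the pipeline
#' with the identical configuration and seeds; outputs are bit-identical to
#' the original run.
#'
#' @param path Path to a `manifest.json`.
#' @param out_dir Optional output directory for the re-run's artifacts.
#' @return The [run_pipeline()] result list.
#' @export
run_from_manifest <- function(path, out_dir = NULL) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg_args <- m$config
  if (!is.null(cfg_args$causal_spec)) {
    cfg_args$causal_spec <- as_tibble(cfg_args$causal_spec)
  }
  config <- do.call(sim_config, cfg_args)
  run_pipeline(config,
               n_sets = m$n_sets,
               set_size_range = m$set_size_range,
               causal_set_genes = m$causal_set_genes %||% character(),
               qc = do.call(qc_thresholds, m$qc),
               params = do.call(clump_params, m$clump_params),
               k_pcs = m$k_pcs, n_perm = m$n_perm, B = m$B,
               do_gene_test = isTRUE(m$do_gene_test),
               out_dir = out_dir)
}
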