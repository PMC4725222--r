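#' The 40-gene NS-ARID candidate set
#'
#' The packaged reference list of 40 genes implicated in non-syndromic
#' autosomal recessive intellectual disability (NS-ARID) — genes in which
#' recessive mutations produce a large (30+ IQ point) deficit without other
#' neurological pathology — together with their hg18 spans, the number of
#' chip SNPs falling in each gene's 50 kb-flanked window, the discovery
#' route (microsatellite homozygosity mapping of consanguineous families for
#' 8 genes, next-generation/whole-exome sequencing for 32), and published
#' gene-based p-values for three cognitive phenotypes.
#'
#' Two gene-symbol systems circulate for five of the genes; the fixture
#' carries both: `gene` (the symbol used in the coordinate table) and
#' `alt_symbol` (the synonym used in the prose list — PRMT10 for LOC90826,
#' TRAPPC9 for NIBP, RABL6 for C9orf86, TECR for GPSN2, TTI2 for C8orf41).
#' Neither column is authoritative; joins should try both.
#'
#' @return A tibble with 40 rows: `gene`, `alt_symbol`, `chr`, `n_snps`,
#'   `start`, `stop` (1-based inclusive, without the 50 kb flank),
#'   `discovery`, `fluid_p`, `cryst_p`, `general_p`.
#' @examples
#' nrow(load_nsarid_genes())  # 40
#' @export
load_nsarid_genes <- function() {
  path <- system.file("extdata", "nsarid_genes.tsv", package = "gwaset",
                      mustWork = TRUE)
  out <- readr::read_tsv(path,
                         col_types = readr::cols(gene = "c", alt_symbol = "c",
                                                 chr = "i", n_snps = "i",
                                                 start = "i", stop = "i",
                                                 discovery = "c",
                                                 .default = "d"),
                         progress = FALSE)
  if (nrow(out) != 40L || anyDuplicated(out$gene) ||
      any(out$stop <= out$start) || !all(out$chr %in% 1:22)) {
    abort_gwaset("corrupted NS-ARID fixture file")
  }
  out
}

#' Literature-derived keywords linking the NS-ARID genes
#'
#' The packaged table of 18 statistically significant keywords describing
#' the shared biological functions of the NS-ARID genes, as produced by a
#' text-mining scan of PubMed abstracts, with the gene symbols each keyword
#' is attached to. The symbol printed as "ECR" in the source table matches
#' no NS-ARID gene and is stored here as its resolved reading PECR (TECR
#' already appears separately in the same keyword's list).
#'
#' @return A tibble with 18 rows: `keyword`, `genes` (list-column of gene
#'   symbols, each resolvable against either symbol column of
#'   [load_nsarid_genes()]).
#' @examples
#' nrow(load_grail_keywords())  # 18
#' @export
load_grail_keywords <- function() {
  path <- system.file("extdata", "grail_keywords.tsv", package = "gwaset",
                      mustWork = TRUE)
  raw <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  out <- tibble(keyword = raw$keyword,
                genes = strsplit(raw$genes, ";", fixed = TRUE))
  nsarid <- load_nsarid_genes()
  known <- union(nsarid$gene, nsarid$alt_symbol)
  unresolved <- setdiff(unique(unlist(out$genes)), known)
  if (nrow(out) != 18L || length(unresolved) > 0) {
    abort_gwaset("corrupted keyword fixture file")
  }
  out
}

#' NS-ARID genes as a gene-set tibble
#'
#' Convenience wrapper returning the 40 NS-ARID genes in the same shape as
#' [read_gmt()] output, ready for [enrichment_test()]. Symbols follow the
#' coordinate-table column.
#'
#' @return A one-row tibble: `set`, `description`, `genes`.
#' @export
nsarid_gene_set <- function() {
  g <- load_nsarid_genes()
  tibble(set = "NS-ARID",
         description = "genes implicated in non-syndromic autosomal recessive intellectual disability",
         genes = list(g$gene))
}
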