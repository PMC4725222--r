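# Readers and writers for the plain-text interchange formats. Coordinates
# are 1-based inclusive everywhere except the explicit BED export.

#' Write a genotype object as PLINK-style text files
#'
#' Writes `<prefix>.bim` (chr, snp, cM = 0, pos, a1, a2), `<prefix>.fam`
#' (fid, iid, 0, 0, sex coded 1/2, -9) and `<prefix>.dosage.tsv` (one row
#' per individual: `iid` then one minor-allele-count column per SNP, `NA`
#' for missing calls).
#'
#' @param geno A `geno_data` object.
#' @param prefix File path prefix.
#' @return `prefix`, invisibly.
#' @export
write_geno <- function(geno, prefix) {
  bim <- tibble(chr = geno$snp_map$chr, snp = geno$snp_map$snp, cm = 0L,
                pos = geno$snp_map$pos, a1 = geno$snp_map$a1,
                a2 = geno$snp_map$a2)
  readr::write_tsv(bim, paste0(prefix, ".bim"), col_names = FALSE)
  fam <- tibble(fid = geno$samples$iid, iid = geno$samples$iid,
                pat = 0L, mat = 0L, sex = geno$samples$sex + 1L, phe = -9L)
  readr::write_tsv(fam, paste0(prefix, ".fam"), col_names = FALSE)
  dos <- as_tibble(geno$dosages)
  dos <- bind_cols(tibble(iid = geno$samples$iid), dos)
  readr::write_tsv(dos, paste0(prefix, ".dosage.tsv"))
  invisible(prefix)
}

#' Read a genotype object from PLINK-style text files
#'
#' Inverse of [write_geno()]. Ages are not part of the genotype files and
#' come back as `NA`; join a phenotype table for them.
#'
#' @param prefix File path prefix used by [write_geno()].
#' @return A `geno_data` object.
#' @export
read_geno <- function(prefix) {
  bim <- readr::read_tsv(paste0(prefix, ".bim"),
                         col_names = c("chr", "snp", "cm", "pos", "a1", "a2"),
                         col_types = "iciicc", progress = FALSE)
  fam <- readr::read_tsv(paste0(prefix, ".fam"),
                         col_names = c("fid", "iid", "pat", "mat", "sex", "phe"),
                         col_types = "cciiii", progress = FALSE)
  dos <- readr::read_tsv(paste0(prefix, ".dosage.tsv"),
                         col_types = readr::cols(iid = "c", .default = "i"),
                         progress = FALSE)
  if (!identical(dos$iid, fam$iid)) {
    abort_gwaset("dosage and .fam files disagree on individual order")
  }
  m <- as.matrix(dos[, -1L, drop = FALSE])
  rownames(m) <- fam$iid
  if (!identical(colnames(m), bim$snp)) {
    abort_gwaset("dosage and .bim files disagree on SNP order")
  }
  new_geno_data(m,
                tibble(snp = bim$snp, chr = bim$chr, pos = bim$pos,
                       a1 = bim$a1, a2 = bim$a2),
                tibble(iid = fam$iid, age = NA_real_, sex = fam$sex - 1L))
}

#' Read / write a phenotype table
#'
#' @param pheno Tibble with `iid`, `age`, `sex` and score columns.
#' @param path File path (TSV).
#' @return `read_phenotypes()` returns a tibble; `write_phenotypes()`
#'   returns `path` invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  readr::write_tsv(pheno, path)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(iid = "c", sex = "i",
                                                .default = "d"),
                  progress = FALSE)
}

#' Read / write gene annotation (1-based inclusive TSV)
#'
#' @param annotation Tibble with `gene`, `chr`, `start`, `stop` (and
#'   optionally `n_snps`).
#' @param path File path.
#' @return `read_annotation()` returns a tibble.
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(annotation, path)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(gene = "c", chr = "i",
                                                start = "i", stop = "i",
                                                .default = "i"),
                  progress = FALSE)
}

#' Read / write gene sets in GMT format
#'
#' GMT lines are `name TAB description TAB gene1 TAB gene2 ...`. Duplicate
#' genes within a set are removed with a warning; malformed lines (fewer
#' than three fields) are reported with their line numbers.
#'
#' @param gene_sets Tibble with `set`, `description`, `genes` (list-column).
#' @param path File path.
#' @return `read_gmt()` returns a tibble with `set`, `description`, `genes`.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- pmap(list(gene_sets$set,
                     gene_sets$description %||% rep("", nrow(gene_sets)),
                     gene_sets$genes),
                function(s, d, g) paste(c(s, d, g), collapse = "\t"))
  writeLines(unlist(lines), path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0) {
    abort_gwaset(paste0("malformed GMT line(s): ",
                        paste(head(bad, 10), collapse = ", ")))
  }
  genes <- map(seq_along(parts), function(i) {
    g <- parts[[i]][-(1:2)]
    g <- g[nzchar(g)]
    if (anyDuplicated(g)) {
      warning(sprintf("duplicate gene(s) in set '%s' (line %d); deduplicated",
                      parts[[i]][1], i), call. = FALSE)
      g <- unique(g)
    }
    g
  })
  tibble(set = map_chr(parts, 1L),
         description = map_chr(parts, 2L),
         genes = genes)
}

#' Read / write single-marker association results
#'
#' The interchange TSV uses the fixed column order `snp`, `chr`, `pos`,
#' `a1`, `beta`, `se`, `p`, `n`.
#'
#' @param assoc An `assoc_table`.
#' @param path File path.
#' @return `read_assoc()` returns an `assoc_table` tibble.
#' @export
write_assoc <- function(assoc, path) {
  readr::write_tsv(select(as_tibble(assoc),
                          "snp", "chr", "pos", "a1", "beta", "se", "p", "n"),
                   path)
  invisible(path)
}

#' @rdname write_assoc
#' @export
read_assoc <- function(path) {
  out <- readr::read_tsv(path,
                         col_types = readr::cols(snp = "c", chr = "i",
                                                 pos = "i", a1 = "c",
                                                 beta = "d", se = "d",
                                                 p = "d", n = "i"),
                         progress = FALSE)
  class(out) <- c("assoc_table", class(out))
  out
}

#' Read / write genomic intervals
#'
#' List-columns (`snps`, `snp_p`, `genes`) are serialised semicolon-joined.
#'
#' @param intervals An `interval_set`.
#' @param path File path.
#' @return `read_intervals()` returns an `interval_set` tibble.
#' @export
write_intervals <- function(intervals, path) {
  flat <- tibble(
    chr = intervals$chr, start = intervals$start, stop = intervals$stop,
    index_snp = intervals$index_snp, index_p = intervals$index_p,
    n_snps = intervals$n_snps,
    snps = map_chr(intervals$snps, paste, collapse = ";"),
    snp_p = map_chr(intervals$snp_p, function(p) {
      paste(formatC(p, format = "g", digits = 17), collapse = ";")
    }),
    genes = if ("genes" %in% names(intervals)) {
      map_chr(intervals$genes, paste, collapse = ";")
    } else NA_character_
  )
  readr::write_tsv(flat, path)
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  flat <- readr::read_tsv(path,
                          col_types = readr::cols(chr = "i", start = "i",
                                                  stop = "i", index_snp = "c",
                                                  index_p = "d", n_snps = "i",
                                                  snps = "c", snp_p = "c",
                                                  genes = "c"),
                          progress = FALSE)
  out <- tibble(
    chr = flat$chr, start = flat$start, stop = flat$stop,
    index_snp = flat$index_snp, index_p = flat$index_p,
    n_snps = flat$n_snps,
    snps = strsplit(flat$snps, ";", fixed = TRUE),
    snp_p = map(strsplit(flat$snp_p, ";", fixed = TRUE), as.numeric)
  )
  if (!all(is.na(flat$genes))) {
    out$genes <- map(flat$genes, function(g) {
      if (is.na(g) || !nzchar(g)) character() else strsplit(g, ";", fixed = TRUE)[[1]]
    })
    out$n_genes <- lengths(out$genes)
  }
  new_interval_set(out)
}

#' Write an enrichment report
#'
#' Columns: `set`, `n_genes_total`, `n_hit`, `empirical_p`, `corrected_p`,
#' `hit_genes` (semicolon-joined).
#'
#' @param result An `enrichment_result`.
#' @param path File path.
#' @export
write_enrichment <- function(result, path) {
  readr::write_tsv(select(as_tibble(result), "set", "n_genes_total", "n_hit",
                          "empirical_p", "corrected_p", "hit_genes"),
                   path)
  invisible(path)
}

#' @rdname write_enrichment
#' @export
read_enrichment <- function(path) {
  readr::read_tsv(path,
                  col_types = readr::cols(set = "c", n_genes_total = "i",
                                          n_hit = "i", empirical_p = "d",
                                          corrected_p = "d", hit_genes = "c"),
                  progress = FALSE)
}

#' Convert 1-based inclusive intervals to BED (0-based, half-open)
#'
#' The only 0-based surface in the package: BED start = start - 1,
#' BED end = stop.
#'
#' @param x Tibble with `chr`, `start`, `stop` (1-based inclusive) and
#'   optionally a name column.
#' @param name_col Column to use for the BED name field (default none).
#' @return A tibble with `chrom`, `chromStart` (0-based), `chromEnd` and
#'   optionally `name`; attribute `"zero_based"` is `TRUE`.
#' @export
as_bed <- function(x, name_col = NULL) {
  out <- tibble(chrom = x$chr, chromStart = x$start - 1L, chromEnd = x$stop)
  if (!is.null(name_col)) out$name <- x[[name_col]]
  attr(out, "zero_based") <- TRUE
  out
}
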