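#' Read and write pipeline tables
#'
#' Plain-TSV serialization used for all pipeline intermediates: dosage
#' matrices (samples in rows, first column `sample_id`), kinship matrices
#' (square, header row of sample ids), SNP-set definitions (one line per
#' gene: `gene_id TAB comma-separated variant ids TAB comma-separated
#' weights`, the classic set-definition format of SNP-set testing tools),
#' gene models as GFF3 and regulatory elements as BED (0-based half-open on
#' disk, converted to 1-based inclusive on read).
#'
#' @param x object to write.
#' @param path file path.
#' @name genagg-io
NULL

#' @rdname genagg-io
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname genagg-io
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @rdname genagg-io
#' @export
write_dosages <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname genagg-io
#' @export
read_dosages <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  m
}

#' @rdname genagg-io
#' @export
write_kinship <- function(x, path) {
  K <- if (inherits(x, "kinship_matrix")) x$K else x
  df <- data.frame(sample_id = rownames(K), K, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname genagg-io
#' @export
read_kinship <- function(path) {
  m <- read_dosages(path)
  colnames(m) <- rownames(m)
  m
}

#' @rdname genagg-io
#' @param sets named list of `gene_snpset` objects.
#' @export
write_snpsets <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(s$gene_id, paste(s$variant_id, collapse = ","),
          paste(format(s$weight, trim = TRUE, scientific = FALSE),
                collapse = ","),
          sep = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname genagg-io
#' @export
read_snpsets <- function(path) {
  lines <- readLines(path)
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    vid <- strsplit(f[2], ",", fixed = TRUE)[[1]]
    structure(list(gene_id = f[1], variant_id = vid,
                   weight = as.numeric(strsplit(f[3], ",", fixed = TRUE)[[1]]),
                   source = rep(NA_character_, length(vid))),
              class = "gene_snpset")
  })
  names(sets) <- vapply(sets, `[[`, "", "gene_id")
  sets
}

#' @rdname genagg-io
#' @param gene_models gene-model interval table.
#' @export
write_gff3 <- function(gene_models, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = gene_models$chrom,
    ranges = IRanges::IRanges(start = gene_models$start,
                              end = gene_models$end),
    strand = gene_models$strand %||% "*",
    type = gene_models$type,
    ID = paste0(gene_models$gene_id, ":", gene_models$type, ":",
                seq_len(nrow(gene_models))),
    gene_id = gene_models$gene_id
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname genagg-io
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(gene_id = gr$gene_id,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             type = as.character(gr$type),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' @rdname genagg-io
#' @param elements regulatory-element table (1-based inclusive intervals).
#' @export
write_elements_bed <- function(elements, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = elements$chrom,
    ranges = IRanges::IRanges(start = elements$start, end = elements$end),
    name = paste(elements$element_id, elements$class, sep = "|")
  )
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname genagg-io
#' @export
read_elements_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  nm <- strsplit(gr$name, "|", fixed = TRUE)
  data.frame(element_id = vapply(nm, `[`, "", 1L),
             class = vapply(nm, `[`, "", 2L),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),   # rtracklayer restores 1-based
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Published worked example: consortium meta-analysis hits and composition
#'
#' The printed gene-level results and ancestry composition of a large
#' breast cancer case-control consortium analysis (83,471 cases and 59,199
#' controls in 15 study cohorts), bundled as a worked example for the FDR and
#' composition operations: 14 genome-wide significant genes with their
#' unadjusted meta-analysis p-values, published q-values and single-marker
#' GWAS overlap status, plus the per-ancestry sample counts. The published
#' q-values correspond to a step-up BH adjustment with a total test count of
#' m = 17,960 (implied exactly by the rank-1 gene's p/q pair).
#'
#' @return list with `hits` (data.frame: gene, p, q_published, gwas_overlap),
#'   `ancestry_counts` (named integer vector), `m_tests` (17960),
#'   `n_cases`, `n_controls`.
#' @export
consortium_example <- function() {
  path <- system.file("extdata", "eur_meta_hits.tsv", package = "genagg",
                      mustWork = TRUE)
  hits <- read_tsv(path)
  list(hits = hits,
       ancestry_counts = c(European = 119014L, Asian = 15321L,
                           African = 5784L, LatinAmerican_Hispanic = 2551L),
       m_tests = 17960L, n_cases = 83471L, n_controls = 59199L)
}
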