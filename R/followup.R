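#' Follow-up region of a significant gene
#'
#' The union span of the gene's actually-used intervals (coding/UTR plus
#' linked regulatory elements, as recorded in its SNP set provenance) extended
#' by `flank_bp` on both sides and floored at position 1.
#'
#' @param intervals data.frame of the gene's source intervals (`chrom`,
#'   `start`, `end`; one chromosome).
#' @param gene_id identifier copied into the region.
#' @param flank_bp flank size in bp (default 100 kb, chosen to cover the bulk
#'   of cis-eQTL to TSS distances).
#' @return list of class `locus_region`: `gene_id`, `chrom`, `start`, `end`.
#' @export
gene_region <- function(intervals, gene_id = NA_character_, flank_bp = 1e5) {
  if (nrow(intervals) == 0L) .stopf("gene has no source intervals")
  if (length(unique(intervals$chrom)) != 1L)
    .stopf("gene intervals span multiple chromosomes")
  structure(list(gene_id = gene_id, chrom = intervals$chrom[1],
                 start = max(1, min(intervals$start) - flank_bp),
                 end = max(intervals$end) + flank_bp),
            class = "locus_region")
}

#' Classify a gene region against single-marker GWAS results
#'
#' A region is called previously identified (`known = TRUE`) iff it contains
#' at least one marker with a single-marker p-value strictly below
#' `threshold` (default the genome-wide significance level 5e-8).
#'
#' @param region a [gene_region()].
#' @param gwas data.frame with `chrom`, `pos`, `p`.
#' @param threshold strict significance cutoff.
#' @return list of class `overlap_call`: `gene_id`, `known`, `best_p`
#'   (`NA` when the region holds no markers).
#' @export
classify_overlap <- function(region, gwas, threshold = 5e-8) {
  inside <- gwas$chrom == region$chrom &
    gwas$pos >= region$start & gwas$pos <= region$end
  best <- if (any(inside)) min(gwas$p[inside]) else NA_real_
  structure(list(gene_id = region$gene_id,
                 known = isTRUE(best < threshold), best_p = best),
            class = "overlap_call")
}

#' Cohort ancestry composition
#'
#' Percentages per ancestry group, rounded to one decimal, with the total
#' echoed; used for the study-composition summary.
#'
#' @param counts named non-negative counts per group (total > 0).
#' @return data.frame `group`, `n`, `pct`; attribute `total`.
#' @export
cohort_composition <- function(counts) {
  if (any(counts < 0)) .stopf("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) .stopf("total count must be positive")
  out <- data.frame(group = names(counts) %||% as.character(seq_along(counts)),
                    n = as.integer(counts),
                    pct = round(100 * counts / total, 1),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "total") <- as.integer(total)
  out
}

#' Locus follow-up for a table of significant genes
#'
#' Builds each gene's flanked region from its SNP-set provenance and
#' classifies it against a GWAS summary table.
#'
#' @param meta significant rows of a [run_meta()] result (or any table with
#'   `gene_id`).
#' @param provenance data.frame of source intervals per gene (`gene_id`,
#'   `chrom`, `start`, `end`), e.g. from [snpset_provenance()].
#' @param gwas GWAS summary table (`chrom`, `pos`, `p`).
#' @param flank_bp,threshold see [gene_region()] and [classify_overlap()].
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `known`, `best_p`.
#' @export
locus_followup <- function(meta, provenance, gwas, flank_bp = 1e5,
                           threshold = 5e-8) {
  rows <- lapply(meta$gene_id, function(g) {
    iv <- provenance[provenance$gene_id == g, , drop = FALSE]
    if (nrow(iv) == 0L)
      return(data.frame(gene_id = g, chrom = NA_character_, start = NA_real_,
                        end = NA_real_, known = NA, best_p = NA_real_,
                        stringsAsFactors = FALSE))
    reg <- gene_region(iv, gene_id = g, flank_bp = flank_bp)
    cl <- classify_overlap(reg, gwas, threshold = threshold)
    data.frame(gene_id = g, chrom = reg$chrom, start = reg$start,
               end = reg$end, known = cl$known, best_p = cl$best_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Source intervals used by each SNP set
#'
#' Collects, per gene, the union of interval sources that contributed
#' variants: the gene's exon/UTR intervals plus its linked regulatory
#' elements. This is the provenance consumed by [locus_followup()].
#'
#' @param gene_models gene-model interval table (see [build_snpsets()]).
#' @param elements regulatory element table.
#' @param eqtls eQTL table.
#' @param sets named list of `gene_snpset` objects.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `source`.
#' @export
snpset_provenance <- function(gene_models, elements, eqtls, sets) {
  rows <- lapply(sets, function(s) {
    gi <- gene_models[gene_models$gene_id == s$gene_id &
                        gene_models$type != "gene", , drop = FALSE]
    out <- data.frame(gene_id = s$gene_id, chrom = gi$chrom,
                      start = gi$start, end = gi$end, source = "coding",
                      stringsAsFactors = FALSE)
    used_cls <- setdiff(unique(s$source), "exon/UTR")
    if (length(used_cls)) {
      linked <- link_elements(gi, elements, eqtls)
      linked <- linked[linked$class %in% used_cls, , drop = FALSE]
      if (nrow(linked))
        out <- rbind(out, data.frame(gene_id = s$gene_id,
                                     chrom = linked$chrom,
                                     start = linked$start, end = linked$end,
                                     source = linked$class,
                                     stringsAsFactors = FALSE))
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
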