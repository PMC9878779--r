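#' Link regulatory elements to a gene
#'
#' An element is linked to a gene if it physically overlaps the gene's span
#' (the interval from the smallest exon/UTR start to the largest end) by at
#' least one base pair, or if it contains at least one significant eQTL record
#' for that gene. Elements on another chromosome are silently skipped. Each
#' linked element is annotated with its link reason; physical overlap takes
#' precedence when both apply.
#'
#' @param gene_intervals data.frame of one gene's exon/UTR intervals
#'   (`gene_id`, `chrom`, `start`, `end`, 1-based inclusive; rows with
#'   `type == "gene"` are ignored if a `type` column is present).
#' @param elements data.frame of regulatory elements (`element_id`, `class`
#'   in promoter/enhancer/TFBS, `chrom`, `start`, `end`, 1-based inclusive).
#' @param eqtls data.frame of eQTL records (`gene_id`, `chrom`, `pos`,
#'   `significant`).
#' @return the linked subset of `elements` with an extra `link` column
#'   (`"overlap"` or `"eqtl"`).
#' @export
link_elements <- function(gene_intervals, elements, eqtls = NULL) {
  gi <- gene_intervals
  if (!is.null(gi$type)) gi <- gi[gi$type != "gene", , drop = FALSE]
  if (nrow(gi) == 0L) .stopf("gene has no exon/UTR intervals")
  if (length(unique(gi$chrom)) != 1L)
    .stopf("gene intervals span multiple chromosomes")
  gene_id <- unique(gi$gene_id)
  stopifnot(length(gene_id) == 1L)
  span <- c(min(gi$start), max(gi$end))

  if (is.null(elements) || nrow(elements) == 0L) {
    out <- elements[integer(0), , drop = FALSE]
    out$link <- character(0)
    return(out)
  }
  bad_class <- setdiff(unique(elements$class),
                       c("promoter", "enhancer", "TFBS"))
  if (length(bad_class))
    .stopf("unknown regulatory element class: %s",
           paste(bad_class, collapse = ", "))

  same_chr <- elements$chrom == gi$chrom[1]
  by_overlap <- same_chr & elements$start <= span[2] & elements$end >= span[1]

  by_eqtl <- rep(FALSE, nrow(elements))
  if (!is.null(eqtls) && nrow(eqtls) > 0L) {
    sig <- eqtls[eqtls$gene_id == gene_id & eqtls$significant, , drop = FALSE]
    if (nrow(sig) > 0L) {
      for (i in which(same_chr & !by_overlap)) {
        by_eqtl[i] <- any(sig$chrom == elements$chrom[i] &
                            sig$pos >= elements$start[i] &
                            sig$pos <= elements$end[i])
      }
    }
  }
  keep <- by_overlap | by_eqtl
  out <- elements[keep, , drop = FALSE]
  out$link <- ifelse(by_overlap[keep], "overlap", "eqtl")
  rownames(out) <- NULL
  out
}

#' Select a gene's low-frequency variant set
#'
#' Applies the variant and gene filters: a variant is kept iff its MAF is
#' strictly below `maf_max`, its imputation info score is at least `info_min`
#' (a score of exactly `info_min` is retained), and its position falls inside
#' an exon/UTR interval extended by `coding_flank` bp or inside a linked
#' regulatory element. Genes whose filtered set has fewer than `set_size[1]`
#' or more than `set_size[2]` variants are excluded; exclusions are data, not
#' errors. Each kept variant records a single source, with documented
#' precedence exon/UTR > promoter > enhancer > TFBS, and the set is sorted by
#' position then variant id, so output is invariant to input ordering.
#'
#' @param gene_intervals one gene's exon/UTR intervals (see [link_elements()]).
#' @param linked_elements output of [link_elements()] for this gene.
#' @param variants variant table (`variant_id`, `chrom`, `pos`, `maf`, `info`).
#' @param coding_flank bp extension of exon/UTR intervals (default 0).
#' @param maf_max MAF upper bound, exclusive (default 0.05).
#' @param info_min info-score lower bound, inclusive (default 0.7).
#' @param set_size eligible set size range (default `c(3, 5000)`).
#' @return a list of class `gene_snpset` (fields `gene_id`, `variant_id`,
#'   `weight`, `source`) or of class `gene_exclusion` (fields `gene_id`,
#'   `reason` = `"too_few"`/`"too_many"`, `n`).
#' @export
select_variants <- function(gene_intervals, linked_elements, variants,
                            coding_flank = 0, maf_max = 0.05, info_min = 0.7,
                            set_size = c(3L, 5000L)) {
  stopifnot(coding_flank >= 0)
  gi <- gene_intervals
  if (!is.null(gi$type)) gi <- gi[gi$type != "gene", , drop = FALSE]
  gene_id <- unique(gi$gene_id)
  stopifnot(length(gene_id) == 1L)

  v <- variants[variants$chrom == gi$chrom[1] &
                  variants$maf < maf_max & variants$info >= info_min, ,
                drop = FALSE]

  in_coding <- .in_intervals(v$pos, pmax(gi$start - coding_flank, 1),
                             gi$end + coding_flank)
  src <- ifelse(in_coding, "exon/UTR", NA_character_)
  if (!is.null(linked_elements) && nrow(linked_elements) > 0L) {
    for (cls in c("promoter", "enhancer", "TFBS")) {   # source precedence
      le <- linked_elements[linked_elements$class == cls &
                              linked_elements$chrom == gi$chrom[1], ,
                            drop = FALSE]
      if (nrow(le) == 0L) next
      hit <- .in_intervals(v$pos, le$start, le$end)
      src[is.na(src) & hit] <- cls
    }
  }
  keep <- !is.na(src)
  v <- v[keep, , drop = FALSE]
  src <- src[keep]
  o <- order(v$pos, v$variant_id)
  v <- v[o, , drop = FALSE]
  src <- src[o]
  dup <- duplicated(v$variant_id)
  v <- v[!dup, , drop = FALSE]
  src <- src[!dup]

  n <- nrow(v)
  if (n < set_size[1])
    return(structure(list(gene_id = gene_id, reason = "too_few", n = n),
                     class = "gene_exclusion"))
  if (n > set_size[2])
    return(structure(list(gene_id = gene_id, reason = "too_many", n = n),
                     class = "gene_exclusion"))
  structure(list(gene_id = gene_id, variant_id = v$variant_id,
                 weight = rep(NA_real_, n), source = src),
            class = "gene_snpset")
}

#' Attach Phred-scaled pathogenicity weights to a SNP set
#'
#' Sets each variant's weight to its score from the score table; variants
#' absent from the table receive `default`. Negative scores are rejected.
#'
#' @param snpset a `gene_snpset` from [select_variants()].
#' @param scores data.frame with `variant_id` and non-negative `score`.
#' @param default weight for variants with no score (default 0: the variant
#'   then contributes nothing to the test statistic).
#' @return the SNP set with weights filled in.
#' @export
assign_weights <- function(snpset, scores, default = 0) {
  stopifnot(inherits(snpset, "gene_snpset"))
  if (any(scores$score < 0, na.rm = TRUE))
    .stopf("score table contains negative scores; Phred-scaled scores must be >= 0")
  idx <- match(snpset$variant_id, scores$variant_id)
  w <- scores$score[idx]
  w[is.na(w)] <- default
  snpset$weight <- w
  snpset
}

#' @export
print.gene_snpset <- function(x, ...) {
  cat(sprintf("SNP set %s: %d variants (%s)\n", x$gene_id,
              length(x$variant_id),
              paste(sprintf("%s:%d", names(table(x$source)), table(x$source)),
                    collapse = ", ")))
  invisible(x)
}

#' Build weighted SNP sets for all genes
#'
#' Runs [link_elements()], [select_variants()] and [assign_weights()] over
#' every gene in a gene-model table.
#'
#' @param gene_models data.frame of gene models with columns `gene_id`,
#'   `chrom`, `type` (`gene` rows optional, `exon`/`UTR` rows required),
#'   `start`, `end` (1-based inclusive).
#' @param elements,eqtls,variants,scores see the individual operations.
#' @param coding_flank,maf_max,info_min,set_size filter settings, see
#'   [select_variants()].
#' @param default_weight weight for unscored variants.
#' @return list with `sets` (named list of `gene_snpset`) and `exclusions`
#'   (data.frame `gene_id`, `reason`, `n`).
#' @export
build_snpsets <- function(gene_models, elements, eqtls, variants, scores,
                          coding_flank = 0, maf_max = 0.05, info_min = 0.7,
                          set_size = c(3L, 5000L), default_weight = 0) {
  gene_ids <- unique(gene_models$gene_id)
  sets <- list()
  excl <- list()
  for (g in gene_ids) {
    gi <- gene_models[gene_models$gene_id == g, , drop = FALSE]
    linked <- link_elements(gi, elements, eqtls)
    res <- select_variants(gi, linked, variants, coding_flank = coding_flank,
                           maf_max = maf_max, info_min = info_min,
                           set_size = set_size)
    if (inherits(res, "gene_exclusion")) {
      excl[[length(excl) + 1L]] <-
        data.frame(gene_id = res$gene_id, reason = res$reason, n = res$n,
                   stringsAsFactors = FALSE)
    } else {
      sets[[g]] <- assign_weights(res, scores, default = default_weight)
    }
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(gene_id = character(0), reason = character(0), n = integer(0))
  list(sets = sets, exclusions = exclusions)
}
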