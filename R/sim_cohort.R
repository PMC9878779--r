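## Deterministic study layout shared by simulate_cohort() and
## simulate_annotations(): gene coordinates, exon/UTR structure and variant
## positions are all drawn from a stream seeded by spec$seed only, so the two
## generators agree without sharing state.
.study_layout <- function(spec) {
  .with_seed(spec$seed, {
    ng <- spec$n_genes
    chrom <- as.character(((seq_len(ng) - 1L) %% 22L) + 1L)
    slot <- (seq_len(ng) - 1L) %/% 22L
    glen <- as.integer(round(runif(ng, 2e4, 1e5)))
    gstart <- as.integer(1e6 + slot * 2e6 + round(runif(ng, 0, 5e5)))
    genes <- data.frame(
      gene_id = sprintf("G%04d", seq_len(ng)),
      symbol = sprintf("GENE%d", seq_len(ng)),
      chrom = chrom, strand = sample(c("+", "-"), ng, replace = TRUE),
      start = gstart, end = gstart + glen,
      stringsAsFactors = FALSE
    )

    ## exon/UTR structure: first and last feature are UTRs, interior exons
    feats <- lapply(seq_len(ng), function(i) {
      nex <- sample(3:8, 1L)
      cuts <- sort(sample(seq(genes$start[i] + 200L, genes$end[i] - 200L),
                          2L * nex))
      st <- cuts[seq(1L, length(cuts), 2L)]
      en <- cuts[seq(2L, length(cuts), 2L)]
      type <- c("UTR", rep("exon", nex - 2L), "UTR")
      data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
                 type = type, start = st, end = en,
                 strand = genes$strand[i], stringsAsFactors = FALSE)
    })
    features <- do.call(rbind, feats)

    ## variant positions: most inside coding features, the rest anywhere in
    ## the gene body (intronic; only reachable through a linked element)
    vpg <- spec$variants_per_gene
    vrows <- lapply(seq_len(ng), function(i) {
      m <- if (vpg[1] == vpg[2]) vpg[1] else sample(vpg[1]:vpg[2], 1L)
      fi <- feats[[i]]
      in_feat <- runif(m) < 0.85
      pos <- integer(m)
      if (any(in_feat)) {
        w <- fi$end - fi$start + 1L
        pick <- sample(nrow(fi), sum(in_feat), replace = TRUE, prob = w)
        pos[in_feat] <- fi$start[pick] +
          as.integer(floor(runif(sum(in_feat)) * (fi$end[pick] - fi$start[pick] + 1L)))
      }
      if (any(!in_feat))
        pos[!in_feat] <- as.integer(round(runif(sum(!in_feat),
                                                genes$start[i], genes$end[i])))
      pos <- sort(unique(pos))
      data.frame(chrom = genes$chrom[i], pos = pos,
                 gene_id = genes$gene_id[i], stringsAsFactors = FALSE)
    })
    variants <- do.call(rbind, vrows)

    nb <- spec$n_background_variants
    if (nb > 0L) {
      bg <- data.frame(
        chrom = as.character(sample(1:22, nb, replace = TRUE)),
        pos = as.integer(round(runif(nb, 5e7, 1.5e8))),
        gene_id = NA_character_, stringsAsFactors = FALSE
      )
      bg <- bg[!duplicated(bg[c("chrom", "pos")]), , drop = FALSE]
      bg <- bg[order(bg$chrom, bg$pos), , drop = FALSE]
      variants <- rbind(variants, bg)
    }
    variants$variant_id <- sprintf("v%05d", seq_len(nrow(variants)))
    rownames(variants) <- NULL
    list(genes = genes, features = features, variants = variants)
  })
}

#' Simulate a case-control cohort with relatedness and ancestry structure
#'
#' Generates imputed-style dosage genotypes, a variant table, phenotypes and a
#' pedigree table from a [cohort_spec()]. Hard genotypes are drawn per ancestry
#' group under the Balding-Nichols model (group allele frequencies diverge from
#' the ancestral frequency with variance governed by `fst`), full-sib pairs are
#' produced by gene-dropping from simulated parents, and dosages are obtained
#' by shrinking hard genotypes toward twice the group allele frequency so that
#' the realized dosage variance matches the recorded imputation info score.
#' Case-control status follows a logistic model combining the spec's causal
#' gene effects (per causal minor allele) with age and study covariate effects;
#' the intercept is set so the expected case fraction matches the spec.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `synthetic_cohort` with elements
#'   \describe{
#'     \item{dosages}{numeric sample x variant matrix, entries in `[0, 2]`.}
#'     \item{variants}{data.frame: variant_id, chrom, pos, ref, alt, maf
#'       (realized, dosage-estimated), info, gene_id (`NA` for background
#'       kinship markers).}
#'     \item{phenotypes}{data.frame: sample_id, status (0/1), age, study,
#'       ancestry.}
#'     \item{pedigree}{data.frame of annotated full-sib pairs.}
#'     \item{causal_variants}{character vector of causal variant ids.}
#'   }
#' @export
simulate_cohort <- function(spec) {
  spec <- validate_cohort_spec(spec)
  layout <- .study_layout(spec)
  .with_seed(.sub_seed(spec$seed, 1L), {
    vt <- layout$variants
    nv <- nrow(vt)
    n <- spec$n_samples
    ngrp <- spec$n_ancestry_groups

    is_bg <- is.na(vt$gene_id)
    p_anc <- numeric(nv)
    p_anc[!is_bg] <- runif(sum(!is_bg), spec$maf_range[1], spec$maf_range[2])
    p_anc[is_bg] <- runif(sum(is_bg), spec$background_maf_range[1],
                          spec$background_maf_range[2])

    ## Balding-Nichols group frequencies
    pg <- matrix(p_anc, nrow = nv, ncol = ngrp)
    if (ngrp > 1L && spec$fst > 0) {
      a <- p_anc * (1 - spec$fst) / spec$fst
      b <- (1 - p_anc) * (1 - spec$fst) / spec$fst
      for (k in seq_len(ngrp))
        pg[, k] <- pmin(pmax(rbeta(nv, a, b), 1e-4), 0.9999)
    }

    sample_id <- sprintf("S%04d", seq_len(n))
    nsib <- 2L * spec$n_sib_pairs
    group <- integer(n)
    if (spec$n_sib_pairs > 0L)
      group[seq_len(nsib)] <- rep(sample(rep_len(seq_len(ngrp),
                                                 spec$n_sib_pairs)), each = 2L)
    if (n > nsib)
      group[(nsib + 1L):n] <- sample(rep_len(seq_len(ngrp), n - nsib))

    G <- matrix(0L, nrow = n, ncol = nv,
                dimnames = list(sample_id, vt$variant_id))
    ## unrelated individuals: binomial draws at their group frequency
    if (n > nsib) {
      for (k in seq_len(ngrp)) {
        idx <- which(group == k & seq_len(n) > nsib)
        if (length(idx))
          G[idx, ] <- matrix(rbinom(length(idx) * nv, 2L,
                                    rep(pg[, k], each = length(idx))),
                             nrow = length(idx))
      }
    }
    ## sib pairs: gene-drop two children from the same simulated parents
    if (spec$n_sib_pairs > 0L) {
      for (j in seq_len(spec$n_sib_pairs)) {
        k <- group[2L * j - 1L]
        gF <- rbinom(nv, 2L, pg[, k])
        gM <- rbinom(nv, 2L, pg[, k])
        for (child in c(2L * j - 1L, 2L * j))
          G[child, ] <- rbinom(nv, 1L, gF / 2) + rbinom(nv, 1L, gM / 2)
      }
    }

    ## imputation-style dosages: blur hard genotypes toward 2p so that
    ## var(dosage) = info * var(genotype); mean allele frequency is preserved
    info <- runif(nv, spec$info_range[1], spec$info_range[2])
    p_self <- t(pg)[group, , drop = FALSE]          # n x nv group frequency
    D <- 2 * p_self + sweep(G - 2 * p_self, 2L, sqrt(info), `*`)
    D <- pmin(pmax(D, 0), 2)
    dimnames(D) <- dimnames(G)

    pg_hat <- colMeans(D) / 2
    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, nv, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), "")
    variants <- data.frame(
      variant_id = vt$variant_id, chrom = vt$chrom, pos = vt$pos,
      ref = ref, alt = alt,
      maf = pmin(pg_hat, 1 - pg_hat), info = info,
      gene_id = vt$gene_id, stringsAsFactors = FALSE
    )

    ## phenotype: logistic model with causal burden + covariates
    age <- runif(n, 30, 80)
    study <- sample(LETTERS[seq_len(spec$n_studies)], n, replace = TRUE)
    lp <- spec$covariate_effects$age * (age - 55) / (50 / sqrt(12)) +
      spec$covariate_effects$study * (match(study, LETTERS) - 1)
    causal_variants <- character(0)
    if (!is.null(spec$causal_genes)) {
      for (r in seq_len(nrow(spec$causal_genes))) {
        gid <- layout$genes$gene_id[spec$causal_genes$gene[r]]
        vids <- variants$variant_id[!is.na(variants$gene_id) &
                                      variants$gene_id == gid]
        ncausal <- max(1L, ceiling(spec$causal_genes$frac_causal[r] *
                                     length(vids)))
        cv <- vids[seq_len(ncausal)]
        causal_variants <- c(causal_variants, cv)
        lp <- lp + spec$causal_genes$effect[r] *
          rowSums(D[, cv, drop = FALSE])
      }
    }
    b0 <- stats::qlogis(spec$case_fraction) - mean(lp)
    status <- rbinom(n, 1L, stats::plogis(b0 + lp))

    phenotypes <- data.frame(
      sample_id = sample_id, status = status, age = age, study = study,
      ancestry = sprintf("anc%d", group), stringsAsFactors = FALSE
    )
    pedigree <- if (spec$n_sib_pairs > 0L)
      data.frame(pair_id = sprintf("fam%03d", seq_len(spec$n_sib_pairs)),
                 sample_id1 = sample_id[2L * seq_len(spec$n_sib_pairs) - 1L],
                 sample_id2 = sample_id[2L * seq_len(spec$n_sib_pairs)],
                 relation = "full_sib", stringsAsFactors = FALSE)
    else
      data.frame(pair_id = character(0), sample_id1 = character(0),
                 sample_id2 = character(0), relation = character(0))

    structure(list(dosages = D, variants = variants, phenotypes = phenotypes,
                   pedigree = pedigree, causal_variants = causal_variants,
                   spec = spec),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d samples x %d variants (%d gene, %d background), %d cases\n",
              nrow(x$dosages), ncol(x$dosages),
              sum(!is.na(x$variants$gene_id)), sum(is.na(x$variants$gene_id)),
              sum(x$phenotypes$status)))
  invisible(x)
}

#' Simulate gene models, regulatory elements, eQTL links and variant scores
#'
#' Produces the annotation inputs consumed by the SNP-set mapper for the same
#' study layout as [simulate_cohort()] run on `spec` (gene coordinates,
#' exon/UTR structure and variant ids are identical). Each gene receives
#' between `elements_per_gene[1]` and `elements_per_gene[2]` regulatory
#' elements (promoter, enhancer or TFBS); roughly half are placed inside the
#' gene body (linkable by physical overlap), the rest are distal, of which a
#' subset receives a significant eQTL record for the gene (linkable by eQTL
#' evidence) and some only a non-significant record (not linkable). Every
#' variant gets a non-negative Phred-scaled pathogenicity score.
#'
#' @param spec the [cohort_spec()] the cohort was generated from.
#' @param seed integer seed for the annotation-specific draws.
#' @param elements_per_gene integer range of regulatory elements per gene.
#' @return list with data.frames `gene_models` (GFF3-like 1-based inclusive
#'   intervals), `elements` (1-based inclusive), `eqtls`, `scores`.
#' @export
simulate_annotations <- function(spec, seed = spec$seed,
                                 elements_per_gene = c(0L, 3L)) {
  spec <- validate_cohort_spec(spec)
  layout <- .study_layout(spec)
  .with_seed(.sub_seed(seed, 2L), {
    genes <- layout$genes
    el <- list(); eq <- list()
    classes <- c("promoter", "enhancer", "TFBS")
    eid <- 0L
    for (i in seq_len(nrow(genes))) {
      ne <- if (elements_per_gene[1] == elements_per_gene[2])
        elements_per_gene[1]
      else sample(elements_per_gene[1]:elements_per_gene[2], 1L)
      if (ne == 0L) next
      for (j in seq_len(ne)) {
        eid <- eid + 1L
        w <- as.integer(round(runif(1, 500, 5000)))
        if (runif(1) < 0.5) {          # inside the gene body
          st <- as.integer(round(runif(1, genes$start[i],
                                       max(genes$start[i], genes$end[i] - w))))
        } else {                        # distal, 10-250 kb away
          off <- as.integer(round(runif(1, 1e4, 2.5e5)))
          st <- if (runif(1) < 0.5) genes$start[i] - off - w
                else genes$end[i] + off
          st <- max(1L, st)
        }
        el[[eid]] <- data.frame(
          element_id = sprintf("E%04d", eid),
          class = sample(classes, 1L), chrom = genes$chrom[i],
          start = st, end = st + w, stringsAsFactors = FALSE
        )
        distal <- st > genes$end[i] || (st + w) < genes$start[i]
        if (distal) {
          u <- runif(1)
          if (u < 0.7) {               # significant eQTL -> linkable
            eq[[length(eq) + 1L]] <- data.frame(
              gene_id = genes$gene_id[i], chrom = genes$chrom[i],
              pos = st + sample.int(w, 1L),
              tissue = sample(c("breast", "adipose", "blood"), 1L),
              significant = TRUE, stringsAsFactors = FALSE
            )
          } else if (u < 0.85) {       # sub-threshold eQTL -> not linkable
            eq[[length(eq) + 1L]] <- data.frame(
              gene_id = genes$gene_id[i], chrom = genes$chrom[i],
              pos = st + sample.int(w, 1L),
              tissue = sample(c("breast", "adipose", "blood"), 1L),
              significant = FALSE, stringsAsFactors = FALSE
            )
          }
        }
      }
    }
    elements <- if (length(el)) do.call(rbind, el) else
      data.frame(element_id = character(0), class = character(0),
                 chrom = character(0), start = integer(0), end = integer(0))
    eqtls <- if (length(eq)) do.call(rbind, eq) else
      data.frame(gene_id = character(0), chrom = character(0),
                 pos = integer(0), tissue = character(0),
                 significant = logical(0))

    ## Phred-scaled pathogenicity scores, CADD/Eigen-like right-skewed scale
    vt <- layout$variants
    scores <- data.frame(
      variant_id = vt$variant_id,
      score = round(pmin(stats::rexp(nrow(vt), rate = 1 / 6), 60), 3),
      stringsAsFactors = FALSE
    )
    list(gene_models = rbind(
           data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                      type = "gene", start = genes$start, end = genes$end,
                      strand = genes$strand, stringsAsFactors = FALSE),
           layout$features[c("gene_id", "chrom", "type", "start", "end",
                             "strand")]),
         elements = elements, eqtls = eqtls, scores = scores)
  })
}

#' Simulate single-marker GWAS summary statistics
#'
#' Per-variant association p-values for use by the locus follow-up stage.
#' Variants inside `known_regions` receive genome-wide significant p-values
#' (below 5e-8, drawn log-uniform down to 1e-12); all other variants receive
#' null p-values bounded away from the significance threshold so that, absent
#' designated regions, no marker is spuriously genome-wide significant.
#'
#' @param variants variant table (`variant_id`, `chrom`, `pos`).
#' @param known_regions `NULL` or data.frame with `chrom`, `start`, `end`.
#' @param seed integer seed.
#' @return data.frame `variant_id`, `chrom`, `pos`, `p`.
#' @export
simulate_gwas_summary <- function(variants, known_regions = NULL, seed = 1L) {
  stopifnot(nrow(variants) > 0)
  .with_seed(.sub_seed(seed, 3L), {
    p <- runif(nrow(variants), min = 1e-6, max = 1)
    if (!is.null(known_regions) && nrow(known_regions) > 0) {
      for (r in seq_len(nrow(known_regions))) {
        inside <- variants$chrom == known_regions$chrom[r] &
          variants$pos >= known_regions$start[r] &
          variants$pos <= known_regions$end[r]
        if (any(inside))
          p[inside] <- 10^runif(sum(inside), -12, log10(5e-8) - 0.01)
      }
    }
    data.frame(variant_id = variants$variant_id, chrom = variants$chrom,
               pos = variants$pos, p = p, stringsAsFactors = FALSE)
  })
}
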