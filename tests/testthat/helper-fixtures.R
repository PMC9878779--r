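## shared fixture builders; everything is generated in code at test time

identity_kinship <- function(ids) {
  K <- diag(length(ids))
  dimnames(K) <- list(ids, ids)
  K
}

## one gene with two exons and a UTR on chr1
toy_gene <- function(gene_id = "G1", chrom = "1") {
  data.frame(gene_id = gene_id, chrom = chrom,
             type = c("UTR", "exon", "exon"),
             start = c(1000L, 2000L, 5000L),
             end = c(1500L, 3000L, 6000L),
             strand = "+", stringsAsFactors = FALSE)
}

toy_variants <- function(pos, maf = 0.01, info = 0.9, chrom = "1") {
  n <- length(pos)
  data.frame(variant_id = sprintf("v%03d", seq_len(n)), chrom = chrom,
             pos = as.integer(pos), ref = "A", alt = "G",
             maf = rep_len(maf, n), info = rep_len(info, n),
             stringsAsFactors = FALSE)
}

## small genotype fixture with named dims and a fitted identity-kinship null
toy_null_fixture <- function(seed = 1, n = 60, m = 8, maf = c(0.1, 0.4),
                             trait = c("gaussian", "binary"), beta = 0) {
  trait <- match.arg(trait)
  set.seed(seed)
  G <- matrix(rbinom(n * m, 2, runif(m, maf[1], maf[2])), n, m,
              dimnames = list(sprintf("S%03d", seq_len(n)),
                              sprintf("v%d", seq_len(m))))
  w <- runif(m, 1, 10)
  lp <- if (beta != 0) beta * as.numeric(scale(G %*% w)) else numeric(n)
  y <- if (trait == "binary") rbinom(n, 1, stats::plogis(lp))
       else lp + rnorm(n)
  ph <- data.frame(sample_id = rownames(G), status = as.numeric(y),
                   stringsAsFactors = FALSE)
  K <- identity_kinship(rownames(G))
  list(G = G, w = w, phenotypes = ph, K = K,
       null = fit_null_lmm(ph, NULL, K))
}

## cached small synthetic cohort reused across test files
.toy_cohort_cache <- new.env(parent = emptyenv())
toy_cohort <- function() {
  if (is.null(.toy_cohort_cache$co)) {
    sp <- cohort_spec(seed = 7, n_samples = 120, n_genes = 12,
                      variants_per_gene = c(6, 15), n_sib_pairs = 20,
                      n_ancestry_groups = 2, fst = 0.05,
                      n_background_variants = 600)
    .toy_cohort_cache$sp <- sp
    .toy_cohort_cache$co <- simulate_cohort(sp)
    .toy_cohort_cache$ann <- simulate_annotations(sp)
  }
  list(spec = .toy_cohort_cache$sp, cohort = .toy_cohort_cache$co,
       ann = .toy_cohort_cache$ann)
}
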