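test_that("cohort spec validation names the offending field", {
  expect_error(cohort_spec(case_fraction = 1.2), "case_fraction")
  expect_error(cohort_spec(variants_per_gene = c(2, 10)), "variants_per_gene")
  expect_error(cohort_spec(variants_per_gene = c(10, 6000)),
               "variants_per_gene")
  expect_error(cohort_spec(maf_range = c(0.01, 0.2)), "maf_range")
  expect_error(cohort_spec(fst = 0.5), "fst")
  expect_error(cohort_spec(n_sib_pairs = 300, n_samples = 100), "n_sib_pairs")
  expect_error(cohort_spec(n_genes = 5,
                           causal_genes = data.frame(gene = 9, effect = 1,
                                                     frac_causal = 0.5)),
               "causal_genes")
})

test_that("identical spec regenerates bit-identical outputs", {
  sp <- cohort_spec(seed = 31, n_samples = 60, n_genes = 5,
                    variants_per_gene = c(5, 9), n_sib_pairs = 5,
                    n_background_variants = 100)
  a <- simulate_cohort(sp)
  b <- simulate_cohort(sp)
  expect_identical(a$dosages, b$dosages)
  expect_identical(a$variants, b$variants)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(simulate_annotations(sp), simulate_annotations(sp))
})

test_that("dosages, MAFs, info scores and pedigree honour the spec", {
  fx <- toy_cohort()
  co <- fx$cohort
  sp <- fx$spec
  expect_true(all(co$dosages >= 0 & co$dosages <= 2))
  gene_v <- !is.na(co$variants$gene_id)
  ## with ancestry divergence the realized MAF scatters by Balding-Nichols
  ## variance p(1-p)*fst/groups on top of binomial noise
  p2 <- sp$maf_range[2]
  tol <- 3 * sqrt(p2 * (1 - p2) * (sp$fst / sp$n_ancestry_groups +
                                     1 / (2 * sp$n_samples)))
  expect_true(all(co$variants$maf[gene_v] < p2 + tol))
  expect_true(all(co$variants$info >= sp$info_range[1] &
                    co$variants$info <= sp$info_range[2]))
  ## background markers are common and unassigned
  expect_gt(median(co$variants$maf[!gene_v]), 0.1)
  expect_gt(mean(co$variants$maf[!gene_v] > 0.05), 0.9)

  ## unstructured world: the binomial-tolerance invariant holds as stated
  sp0 <- cohort_spec(seed = 17, n_samples = 300, n_genes = 8,
                     variants_per_gene = c(5, 10), fst = 0,
                     n_background_variants = 0)
  co0 <- simulate_cohort(sp0)
  tol0 <- 3 * sqrt(p2 * (1 - p2) / (2 * sp0$n_samples))
  expect_true(all(co0$variants$maf < sp0$maf_range[2] + tol0))
  expect_true(all(co0$variants$maf > 0))
  ## sib pairs annotated as pairs
  expect_equal(nrow(co$pedigree), sp$n_sib_pairs)
  expect_true(all(co$pedigree$relation == "full_sib"))
  expect_setequal(c(co$pedigree$sample_id1, co$pedigree$sample_id2),
                  co$phenotypes$sample_id[seq_len(2 * sp$n_sib_pairs)])
})

test_that("realized sib-pair relatedness averages near 0.5", {
  sp <- cohort_spec(seed = 13, n_samples = 200, n_genes = 4,
                    variants_per_gene = c(5, 8), n_sib_pairs = 50,
                    n_background_variants = 3000)
  co <- simulate_cohort(sp)
  bg <- co$variants$variant_id[is.na(co$variants$gene_id)]
  K <- compute_grm(co$dosages[, bg])
  i1 <- match(co$pedigree$sample_id1, rownames(K))
  i2 <- match(co$pedigree$sample_id2, rownames(K))
  expect_lt(abs(mean(K[cbind(i1, i2)]) - 0.5), 0.05)
})

test_that("allele-frequency divergence increases with fst (Hudson estimator)", {
  hudson_fst <- function(co) {
    grp <- co$phenotypes$ancestry
    gid <- sort(unique(grp))[1:2]
    d <- co$dosages[, is.na(co$variants$gene_id)] / 2
    p1 <- colMeans(d[grp == gid[1], , drop = FALSE])
    p2 <- colMeans(d[grp == gid[2], , drop = FALSE])
    n1 <- sum(grp == gid[1]); n2 <- sum(grp == gid[2])
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    sum(num) / sum(den)
  }
  fsts <- vapply(c(0, 0.05, 0.15), function(f) {
    sp <- cohort_spec(seed = 5, n_samples = 200, n_genes = 3,
                      variants_per_gene = c(5, 8), n_ancestry_groups = 2,
                      fst = f, n_background_variants = 1500)
    hudson_fst(simulate_cohort(sp))
  }, numeric(1))
  expect_true(all(diff(fsts) > 0))
  expect_lt(abs(fsts[1]), 0.01)
})

test_that("annotations cover the cohort's genes and variants consistently", {
  fx <- toy_cohort()
  ann <- fx$ann
  co <- fx$cohort
  expect_setequal(unique(ann$gene_models$gene_id),
                  unique(co$variants$gene_id[!is.na(co$variants$gene_id)]))
  ## every variant is scored, non-negatively
  expect_setequal(ann$scores$variant_id, co$variants$variant_id)
  expect_true(all(ann$scores$score >= 0))
  expect_true(all(ann$elements$class %in% c("promoter", "enhancer", "TFBS")))
  ## significant eQTLs point at real genes
  expect_true(all(ann$eqtls$gene_id %in% ann$gene_models$gene_id))
})

test_that("zero regulatory elements yields exon/UTR-only SNP sets", {
  sp <- cohort_spec(seed = 3, n_samples = 50, n_genes = 4,
                    variants_per_gene = c(6, 10), n_background_variants = 0)
  co <- simulate_cohort(sp)
  ann <- simulate_annotations(sp, elements_per_gene = c(0L, 0L))
  expect_equal(nrow(ann$elements), 0)
  snp <- build_snpsets(ann$gene_models, ann$elements, ann$eqtls,
                       co$variants, ann$scores)
  expect_true(all(unlist(lapply(snp$sets, `[[`, "source")) == "exon/UTR"))
})

test_that("simulated GWAS summaries respect known regions and seeds", {
  fx <- toy_cohort()
  v <- fx$cohort$variants
  g0 <- simulate_gwas_summary(v, NULL, seed = 4)
  expect_true(all(g0$p >= 1e-6))           # no spurious genome-wide hits
  region <- data.frame(chrom = v$chrom[1],
                       start = v$pos[1] - 10L, end = v$pos[1] + 10L)
  g1 <- simulate_gwas_summary(v, region, seed = 4)
  inside <- g1$chrom == region$chrom & g1$pos >= region$start &
    g1$pos <= region$end
  expect_true(any(inside))
  expect_true(all(g1$p[inside] < 5e-8))
  expect_identical(g1, simulate_gwas_summary(v, region, seed = 4))
})
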