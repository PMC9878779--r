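make_element <- function(id, start, end, class = "enhancer", chrom = "1") {
  data.frame(element_id = id, class = class, chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

test_that("elements link by intronic overlap or significant eQTL only", {
  gene <- toy_gene()                       # span 1000..6000 on chr1
  intronic <- make_element("E1", 3500, 4000)      # inside the intron
  distal <- make_element("E2", 206000, 207000)    # 200 kb away
  other_chr <- make_element("E3", 1000, 6000, chrom = "2")
  els <- rbind(intronic, distal, other_chr)

  ## no eQTLs: only physical overlap links
  linked <- link_elements(gene, els, NULL)
  expect_equal(linked$element_id, "E1")
  expect_equal(linked$link, "overlap")

  ## significant eQTL inside the distal element links it to this gene only
  eq_sig <- data.frame(gene_id = "G1", chrom = "1", pos = 206500L,
                       tissue = "breast", significant = TRUE)
  linked <- link_elements(gene, els, eq_sig)
  expect_setequal(linked$element_id, c("E1", "E2"))
  expect_equal(linked$link[linked$element_id == "E2"], "eqtl")

  ## non-significant eQTL does not link
  eq_ns <- transform(eq_sig, significant = FALSE)
  expect_equal(link_elements(gene, els, eq_ns)$element_id, "E1")

  ## eQTL for a different gene does not link
  eq_other <- transform(eq_sig, gene_id = "G9")
  expect_equal(link_elements(gene, els, eq_other)$element_id, "E1")

  expect_error(link_elements(gene, make_element("E4", 1, 2, class = "weird")),
               "class")
})

test_that("variant filters use strict MAF < 0.05 and info >= 0.7 boundaries", {
  gene <- toy_gene()
  v <- toy_variants(c(2100, 2200, 2300, 2400))
  v$maf <- c(0.05, 0.049999, 0.01, 0.01)
  v$info <- c(0.9, 0.9, 0.7, 0.699999)
  s <- select_variants(gene, NULL, v, set_size = c(1L, 5000L))
  expect_s3_class(s, "gene_snpset")
  ## maf = 0.05 excluded (strict <); info = 0.7 retained; info < 0.7 excluded
  expect_setequal(s$variant_id, c("v002", "v003"))
  ## the same two survivors fall below the default minimum of 3 -> exclusion
  s2 <- select_variants(gene, NULL, v, set_size = c(3L, 5000L))
  expect_s3_class(s2, "gene_exclusion")
  expect_equal(s2$reason, "too_few")
  expect_equal(s2$n, 2L)
  ## too-large set
  v3 <- toy_variants(seq(2001, 2999, by = 10))
  s3 <- select_variants(gene, NULL, v3, set_size = c(3L, 50L))
  expect_equal(s3$reason, "too_many")
})

test_that("membership combines coding flank and linked elements", {
  gene <- toy_gene()                       # exons/UTR 1000-1500,2000-3000,5000-6000
  el <- make_element("E1", 3500, 4000)
  v <- toy_variants(c(1200, 3600, 4500, 7000, 2050))
  s <- select_variants(gene, link_elements(gene, el, NULL), v)
  expect_setequal(s$variant_id, c("v001", "v002", "v005"))  # 4500/7000 outside
  expect_equal(s$source[s$variant_id == "v002"], "enhancer")
  ## flank rescues a variant just upstream of the UTR
  v2 <- toy_variants(c(960, 1200, 2050))
  s0 <- select_variants(gene, NULL, v2, coding_flank = 0)
  expect_s3_class(s0, "gene_exclusion")
  s50 <- select_variants(gene, NULL, v2, coding_flank = 50,
                         set_size = c(3L, 5000L))
  expect_true("v001" %in% s50$variant_id)
})

test_that("source precedence is exon/UTR > promoter > enhancer > TFBS", {
  gene <- toy_gene()
  els <- rbind(make_element("P", 2000, 2600, class = "promoter"),
               make_element("EN", 2000, 2600, class = "enhancer"),
               make_element("T", 3200, 4000, class = "TFBS"),
               make_element("EN2", 3200, 4000, class = "enhancer"))
  v <- toy_variants(c(2100, 3500, 5500))
  s <- select_variants(gene, link_elements(gene, els, NULL), v)
  expect_equal(s$source, c("exon/UTR", "enhancer", "exon/UTR"))
})

test_that("SNP sets are invariant to input ordering", {
  gene <- toy_gene()
  els <- rbind(make_element("A", 3200, 3600), make_element("B", 3500, 4200))
  v <- toy_variants(c(2100, 3550, 5500, 1200))
  s1 <- select_variants(gene, link_elements(gene, els, NULL), v)
  perm_v <- v[c(3, 1, 4, 2), ]
  perm_e <- els[2:1, ]
  s2 <- select_variants(gene, link_elements(gene, perm_e, NULL), perm_v)
  expect_identical(s1$variant_id, s2$variant_id)
  expect_identical(s1$source, s2$source)
  ## sorted by position
  expect_equal(s1$variant_id,
               v$variant_id[order(v$pos)][v$variant_id[order(v$pos)] %in%
                                            s1$variant_id])
})

test_that("a variant may belong to two genes' sets", {
  g1 <- toy_gene("G1")
  g2 <- data.frame(gene_id = "G2", chrom = "1", type = "exon",
                   start = 2500L, end = 7000L, strand = "-")
  v <- toy_variants(c(2600, 2700, 2800))
  s1 <- select_variants(g1, NULL, v)
  s2 <- select_variants(g2, NULL, v)
  expect_setequal(s1$variant_id, s2$variant_id)
})

test_that("weights come from the score table with a default for misses", {
  gene <- toy_gene()
  v <- toy_variants(c(2100, 2200, 2300))
  s <- select_variants(gene, NULL, v)
  scores <- data.frame(variant_id = c("v001", "v003"), score = c(12.5, 3))
  sw <- assign_weights(s, scores, default = 0)
  expect_equal(sw$weight, c(12.5, 0, 3))
  expect_error(assign_weights(s, data.frame(variant_id = "v001", score = -1)),
               "negative")
})

test_that("build_snpsets returns sets plus an exclusion table", {
  fx <- toy_cohort()
  snp <- build_snpsets(fx$ann$gene_models, fx$ann$elements, fx$ann$eqtls,
                       fx$cohort$variants, fx$ann$scores)
  expect_gt(length(snp$sets), 0)
  expect_true(all(vapply(snp$sets, function(s) length(s$variant_id) >= 3,
                         logical(1))))
  expect_true(all(vapply(snp$sets,
                         function(s) !anyDuplicated(s$variant_id),
                         logical(1))))
  expect_named(snp$exclusions)
  expect_true(all(snp$exclusions$reason %in% c("too_few", "too_many")))
})
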