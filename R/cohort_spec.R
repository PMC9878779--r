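#' Parameterize a synthetic case-control cohort
#'
#' A `cohort_spec` fully determines one simulated genotype-phenotype cohort:
#' the same spec and seed always regenerate bit-identical data. The simulated
#' world mirrors the structure the aggregation analysis assumes: imputed
#' low-frequency dosage genotypes with per-variant info scores, full-sib pairs,
#' discrete ancestry groups with Balding-Nichols allele-frequency divergence,
#' and a logistic case-control phenotype with optional per-gene causal
#' architecture and age/study covariate effects.
#'
#' @param seed integer seed (< 2^31) controlling every random draw.
#' @param n_samples number of samples (sib-pair members included).
#' @param case_fraction target case fraction in (0,1).
#' @param n_genes number of genes carrying low-frequency variants.
#' @param variants_per_gene integer range `c(lo, hi)` of variants per gene;
#'   must lie within `[3, 5000]`, the eligible aggregation set size.
#' @param maf_range ancestral minor-allele-frequency range, within (0, 0.05):
#'   only low-frequency variants enter gene sets.
#' @param info_range imputation-accuracy (info score) range in (0, 1].
#' @param n_sib_pairs number of full-sib pairs (2 samples each) generated by
#'   gene-dropping from simulated parents.
#' @param n_ancestry_groups number of discrete ancestry groups.
#' @param fst between-group allele-frequency divergence in `[0, 0.3]`
#'   (Balding-Nichols beta model).
#' @param causal_genes `NULL` or a data.frame with columns `gene` (1-based
#'   gene index), `effect` (log-odds increase per causal minor allele) and
#'   `frac_causal` (fraction of the gene's variants that are causal, in (0,1]).
#' @param covariate_effects list with elements `age` (log-odds per SD of age)
#'   and `study` (log-odds step between consecutive recruitment studies).
#' @param n_studies number of recruitment-study labels.
#' @param n_background_variants number of common background markers
#'   (MAF in `background_maf_range`, not assigned to any gene) used for
#'   kinship estimation, emulating genome-wide array content.
#' @param background_maf_range MAF range of the background markers.
#'
#' @return An object of class `cohort_spec` (a validated list).
#' @seealso [simulate_cohort()], [simulate_annotations()]
#' @export
cohort_spec <- function(seed = 1L,
                        n_samples = 500L,
                        case_fraction = 0.5,
                        n_genes = 50L,
                        variants_per_gene = c(8L, 25L),
                        maf_range = c(0.005, 0.05),
                        info_range = c(0.75, 1),
                        n_sib_pairs = 0L,
                        n_ancestry_groups = 1L,
                        fst = 0,
                        causal_genes = NULL,
                        covariate_effects = list(age = 0, study = 0),
                        n_studies = 3L,
                        n_background_variants = 2000L,
                        background_maf_range = c(0.1, 0.5)) {
  spec <- list(
    seed = seed, n_samples = n_samples, case_fraction = case_fraction,
    n_genes = n_genes, variants_per_gene = variants_per_gene,
    maf_range = maf_range, info_range = info_range,
    n_sib_pairs = n_sib_pairs, n_ancestry_groups = n_ancestry_groups,
    fst = fst, causal_genes = causal_genes,
    covariate_effects = covariate_effects, n_studies = n_studies,
    n_background_variants = n_background_variants,
    background_maf_range = background_maf_range
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
}

#' @rdname cohort_spec
#' @param spec a `cohort_spec` to validate.
#' @export
validate_cohort_spec <- function(spec) {
  spec$seed <- .assert_count(spec$seed, "seed", min = 0L)
  if (spec$seed >= 2^31 - 1) .stopf("field 'seed' must be below 2^31")
  spec$n_samples <- .assert_count(spec$n_samples, "n_samples", min = 2L)
  .assert_fraction(spec$case_fraction, "case_fraction")
  spec$n_genes <- .assert_count(spec$n_genes, "n_genes", min = 1L)

  vpg <- spec$variants_per_gene
  if (length(vpg) != 2 || any(!is.finite(vpg)) || vpg[1] > vpg[2])
    .stopf("field 'variants_per_gene' must be a non-empty range c(lo, hi)")
  if (vpg[1] < 3 || vpg[2] > 5000)
    .stopf("field 'variants_per_gene' must lie within [3, 5000]")
  spec$variants_per_gene <- as.integer(vpg)

  .check_range <- function(r, field, lo, hi) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] ||
        r[1] <= lo || r[2] > hi)
      .stopf("field '%s' must be an increasing range within (%s, %s]",
             field, format(lo), format(hi))
  }
  .check_range(spec$maf_range, "maf_range", 0, 0.05)
  .check_range(spec$info_range, "info_range", 0, 1)
  .check_range(spec$background_maf_range, "background_maf_range", 0, 0.5)

  spec$n_sib_pairs <- .assert_count(spec$n_sib_pairs, "n_sib_pairs")
  if (2L * spec$n_sib_pairs > spec$n_samples)
    .stopf("field 'n_sib_pairs': %d pairs need %d samples but n_samples = %d",
           spec$n_sib_pairs, 2L * spec$n_sib_pairs, spec$n_samples)
  spec$n_ancestry_groups <-
    .assert_count(spec$n_ancestry_groups, "n_ancestry_groups", min = 1L)
  if (length(spec$fst) != 1 || !is.finite(spec$fst) ||
      spec$fst < 0 || spec$fst > 0.3)
    .stopf("field 'fst' must lie in [0, 0.3]")

  cg <- spec$causal_genes
  if (!is.null(cg)) {
    if (!is.data.frame(cg) ||
        !all(c("gene", "effect", "frac_causal") %in% names(cg)))
      .stopf("field 'causal_genes' must be a data.frame with columns gene, effect, frac_causal")
    if (any(cg$gene < 1 | cg$gene > spec$n_genes))
      .stopf("field 'causal_genes': gene index out of bounds (1..%d)",
             spec$n_genes)
    if (any(cg$frac_causal <= 0 | cg$frac_causal > 1))
      .stopf("field 'causal_genes': frac_causal must lie in (0, 1]")
  }

  ce <- spec$covariate_effects
  if (!is.list(ce) || !all(c("age", "study") %in% names(ce)))
    .stopf("field 'covariate_effects' must be a list with elements age, study")
  spec$n_studies <- .assert_count(spec$n_studies, "n_studies", min = 1L)
  spec$n_background_variants <-
    .assert_count(spec$n_background_variants, "n_background_variants")
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:",
      sprintf("%d samples (%.0f%% cases), %d genes, %d sib pairs,",
              x$n_samples, 100 * x$case_fraction, x$n_genes, x$n_sib_pairs),
      sprintf("%d ancestry group(s) at Fst=%.3g, seed %d",
              x$n_ancestry_groups, x$fst, x$seed), "\n")
  if (!is.null(x$causal_genes))
    cat(sprintf("  %d causal gene(s)\n", nrow(x$causal_genes)))
  invisible(x)
}
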