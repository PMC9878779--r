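#' Run the full aggregation analysis end-to-end on synthetic cohorts
#'
#' Orchestrates every stage for a set of cohorts: annotation mapping
#' (SNP-set construction), kinship building, per-cohort mixed-model SKAT-O,
#' inflation diagnostics with genomic control where triggered, one
#' meta-analysis per configured cohort subset (e.g. a European-ancestry subset
#' and an all-cohort analysis), BH FDR, and GWAS locus follow-up of the
#' significant genes. Every stage is a pure function of (specs, config,
#' seeds); rerunning with the same arguments reproduces byte-identical tables.
#' When `outdir` is given, each stage writes a TSV and a JSON run manifest
#' records the configuration, seeds and output checksums.
#'
#' @param specs named list of [cohort_spec()]s, one per cohort; names are the
#'   cohort ids (used for subset selection).
#' @param config an [agg_config()].
#' @param ancestry optional named character vector mapping cohort id to an
#'   ancestry label (default: label of the cohort's first ancestry group).
#' @param meta_subsets named list of cohort-id vectors to meta-analyze;
#'   `NULL` entries mean "all cohorts". Default a single `all` analysis.
#' @param known_regions optional data.frame (`chrom`, `start`, `end`) of loci
#'   to spike as genome-wide significant in the simulated GWAS input.
#' @param outdir optional output directory for stage TSVs and the manifest.
#' @return list with per-cohort results (`cohorts`), the `manifest`
#'   data.frame, `meta` (named list of [run_meta()] tables), `followup`
#'   (named list), and `composition`.
#' @export
run_pipeline <- function(specs, config = agg_config(), ancestry = NULL,
                         meta_subsets = list(all = NULL),
                         known_regions = NULL, outdir = NULL) {
  stopifnot(length(specs) >= 1L)
  if (is.null(names(specs)) || any(names(specs) == ""))
    names(specs) <- sprintf("cohort%02d", seq_along(specs))

  cohorts <- list()
  results <- list()
  inflation <- list()
  manifest_rows <- list()
  for (cid in names(specs)) {
    spec <- specs[[cid]]
    cohort <- simulate_cohort(spec)
    ann <- simulate_annotations(spec)
    snp <- build_snpsets(ann$gene_models, ann$elements, ann$eqtls,
                         cohort$variants, ann$scores,
                         coding_flank = config$coding_flank,
                         maf_max = config$maf_max,
                         info_min = config$info_min,
                         set_size = config$set_size,
                         default_weight = config$default_weight)
    kin <- build_kinship(cohort$dosages, cohort$variants)
    res <- run_cohort(snp$sets, cohort$dosages, cohort$phenotypes, kin,
                      config = config)
    n_cases <- sum(cohort$phenotypes$status == 1)
    n_controls <- sum(cohort$phenotypes$status == 0)
    infl <- inflation_report(res, n_cases, n_controls, cohort_id = cid,
                             gc_trigger = config$gc_trigger)
    cohorts[[cid]] <- list(cohort = cohort, annotations = ann, snpsets = snp,
                           kinship = kin)
    results[[cid]] <- res
    inflation[[cid]] <- infl
    manifest_rows[[cid]] <- data.frame(
      cohort_id = cid, n = nrow(cohort$phenotypes),
      n_cases = n_cases, n_controls = n_controls,
      ancestry = ancestry[cid] %||% cohort$phenotypes$ancestry[1],
      lambda = infl$lambda, lambda1000 = infl$lambda1000,
      gc_applied = infl$gc_applied, seed = spec$seed,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, manifest_rows)
  rownames(manifest) <- NULL

  meta <- lapply(meta_subsets, function(sub)
    run_meta(results, manifest, inflation = inflation, subset = sub,
             q_threshold = config$q_threshold))

  ## follow-up against a (simulated) single-marker GWAS of the first cohort
  first <- cohorts[[1L]]
  gwas <- simulate_gwas_summary(first$cohort$variants, known_regions,
                                seed = specs[[1L]]$seed)
  followup <- lapply(meta, function(mt) {
    sig <- mt[mt$significant, , drop = FALSE]
    if (nrow(sig) == 0L) return(NULL)
    prov <- snpset_provenance(first$annotations$gene_models,
                              first$annotations$elements,
                              first$annotations$eqtls,
                              first$snpsets$sets[
                                intersect(sig$gene_id,
                                          names(first$snpsets$sets))])
    locus_followup(sig, prov, gwas, flank_bp = config$followup_flank,
                   threshold = config$gwas_p)
  })

  anc_counts <- tapply(manifest$n, manifest$ancestry, sum)
  composition <- cohort_composition(stats::setNames(as.integer(anc_counts),
                                                    names(anc_counts)))

  out <- list(cohorts = cohorts, results = results, inflation = inflation,
              manifest = manifest, meta = meta, followup = followup,
              composition = composition, config = config)
  if (!is.null(outdir)) .write_pipeline_outputs(out, outdir)
  invisible(out)
}

.write_pipeline_outputs <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(writer, x, f) {
    fp <- file.path(outdir, f)
    writer(x, fp)
    paths <<- c(paths, fp)
  }
  emit(write_tsv, out$manifest, "manifest.tsv")
  for (cid in names(out$results)) {
    emit(write_tsv, out$results[[cid]], sprintf("results_%s.tsv", cid))
    emit(write_snpsets, out$cohorts[[cid]]$snpsets$sets,
         sprintf("snpsets_%s.txt", cid))
    emit(write_tsv, out$cohorts[[cid]]$snpsets$exclusions,
         sprintf("exclusions_%s.tsv", cid))
    emit(write_kinship, out$cohorts[[cid]]$kinship,
         sprintf("kinship_%s.tsv", cid))
    infl <- out$inflation[[cid]]
    emit(write_tsv,
         data.frame(cohort_id = infl$cohort_id, lambda = infl$lambda,
                    lambda1000 = infl$lambda1000, n_cases = infl$n_cases,
                    n_controls = infl$n_controls,
                    gc_applied = infl$gc_applied),
         sprintf("inflation_%s.tsv", cid))
  }
  for (mid in names(out$meta)) {
    emit(write_tsv, out$meta[[mid]], sprintf("meta_%s.tsv", mid))
    if (!is.null(out$followup[[mid]]))
      emit(write_tsv, out$followup[[mid]], sprintf("followup_%s.tsv", mid))
  }
  emit(write_tsv, out$composition, "composition.tsv")
  manifest <- list(
    config = unclass(out$config),
    seeds = vapply(out$manifest$seed, identity, numeric(1)),
    outputs = as.list(tools::md5sum(paths))
  )
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
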