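#' Sample-size-weighted Stouffer combination
#'
#' Combines one gene's per-cohort aggregation p-values: each p-value is
#' converted to a one-sided normal score \eqn{z_i = \Phi^{-1}(1 - p_i)}
#' (aggregation tests carry no effect direction, so the combination is
#' one-sided), weighted by the square root of the cohort sample size, and
#' summed:
#' \deqn{Z = \sum_i \sqrt{n_i}\, z_i \Big/ \sqrt{\sum_i n_i},\qquad
#'       p_{meta} = 1 - \Phi(Z).}
#' P-values are clipped into `[1e-300, 1 - 1e-16]` so the normal quantile
#' stays finite; clipping is reported via the `clipped` field.
#'
#' @param p per-cohort p-values (length >= 1).
#' @param n per-cohort sample sizes (positive, same length).
#' @return list with `Z`, `p_meta`, `z` (per-cohort scores), `clipped`.
#' @export
stouffer_combine <- function(p, n) {
  if (length(p) != length(n) || length(p) < 1L)
    .stopf("p and n must be equally long, non-empty vectors")
  if (any(n <= 0)) .stopf("sample sizes must be positive")
  if (any(!is.finite(p) | p <= 0 | p > 1))
    .stopf("p-values must lie in (0, 1]")
  clipped <- p < 1e-300 | p > 1 - 1e-16
  pc <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  z <- stats::qnorm(pc, lower.tail = FALSE)
  Z <- sum(sqrt(n) * z) / sqrt(sum(n))
  list(Z = Z, p_meta = stats::pnorm(Z, lower.tail = FALSE), z = z,
       clipped = any(clipped))
}

#' Majority-presence filter for meta-analyzed genes
#'
#' A gene is excluded when results are missing for the majority of cohorts,
#' i.e. kept iff it has a result in at least `ceiling(K / 2)` of the `K`
#' cohorts (exactly half present is kept).
#'
#' @param n_present named integer vector: per-gene number of cohorts with a
#'   result.
#' @param n_cohorts total number of cohorts `K`.
#' @return character vector of kept gene ids.
#' @export
missingness_filter <- function(n_present, n_cohorts) {
  stopifnot(n_cohorts >= 1L)
  names(n_present)[n_present >= ceiling(n_cohorts / 2)]
}

#' Benjamini-Hochberg step-up q-values with an explicit total test count
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' \eqn{q_i = \min_{j \ge i} (p_j\, m / j)} capped at 1 and mapped back to the
#' input order; ties share the smaller rank's value through the minimum scan.
#' `m` may exceed the number of observed p-values (genes tested elsewhere but
#' missing here still count toward the multiple-testing burden).
#'
#' @param p p-values in (0, 1].
#' @param m total number of tests (defaults to `length(p)`).
#' @return q-values in input order.
#' @export
bh_fdr <- function(p, m = length(p)) {
  k <- length(p)
  stopifnot(m >= k, k >= 1)
  if (any(!is.finite(p) | p <= 0 | p > 1))
    .stopf("p-values must lie in (0, 1]")
  o <- order(p)
  q_sorted <- pmin(rev(cummin(rev(p[o] * m / seq_len(k)))), 1)
  q <- numeric(k)
  q[o] <- q_sorted
  q
}

#' Meta-analyze per-cohort gene results
#'
#' Applies, per cohort, the genomic-control substitution when the cohort's
#' inflation report asked for it; keeps genes present in at least half the
#' cohorts; combines each gene by [stouffer_combine()]; and adjusts with
#' [bh_fdr()] using `m` = number of genes passing the filter. Significance is
#' flagged at `q < q_threshold`.
#'
#' @param cohort_results named list of `cohort_result` data.frames (one per
#'   cohort; duplicate gene rows within a cohort are rejected).
#' @param manifest data.frame with one row per cohort: `cohort_id`, `n`
#'   (sample size), optionally `ancestry`.
#' @param inflation optional named list of [inflation_report()]s; for cohorts
#'   with `gc_applied = TRUE` the corrected p-values replace the raw ones.
#' @param subset optional character vector of cohort ids to combine (e.g. the
#'   European-ancestry subset); default all.
#' @param q_threshold significance threshold on the q-value.
#' @return data.frame of class `meta_result`: `gene_id`, `n_cohorts`, `Z`,
#'   `p_meta`, `q`, `significant`, ordered by `p_meta`.
#' @export
run_meta <- function(cohort_results, manifest, inflation = NULL,
                     subset = NULL, q_threshold = 0.05) {
  stopifnot(length(cohort_results) >= 1L,
            all(c("cohort_id", "n") %in% names(manifest)))
  ids <- subset %||% manifest$cohort_id
  ids <- intersect(ids, names(cohort_results))
  if (length(ids) == 0L) .stopf("no cohorts selected")
  K <- length(ids)

  tabs <- lapply(ids, function(cid) {
    tb <- cohort_results[[cid]]
    if (anyDuplicated(tb$gene_id))
      .stopf("duplicate gene rows in cohort '%s'", cid)
    p <- tb$p
    rep_i <- inflation[[cid]]
    if (!is.null(rep_i) && isTRUE(rep_i$gc_applied)) {
      idx <- match(tb$gene_id, names(rep_i$p_corrected))
      p <- ifelse(is.na(idx), p, rep_i$p_corrected[idx])
    }
    data.frame(gene_id = tb$gene_id, p = p,
               n = manifest$n[match(cid, manifest$cohort_id)],
               stringsAsFactors = FALSE)
  })
  all_tab <- do.call(rbind, tabs)
  all_tab <- all_tab[is.finite(all_tab$p), , drop = FALSE]

  present <- table(all_tab$gene_id)
  kept <- missingness_filter(
    stats::setNames(as.integer(present), names(present)), K)
  all_tab <- all_tab[all_tab$gene_id %in% kept, , drop = FALSE]
  if (nrow(all_tab) == 0L)
    return(structure(data.frame(gene_id = character(0),
                                n_cohorts = integer(0), Z = numeric(0),
                                p_meta = numeric(0), q = numeric(0),
                                significant = logical(0)),
                     class = c("meta_result", "data.frame")))

  by_gene <- split(all_tab, all_tab$gene_id)
  rows <- lapply(by_gene, function(g) {
    st <- stouffer_combine(g$p, g$n)
    data.frame(gene_id = g$gene_id[1], n_cohorts = nrow(g), Z = st$Z,
               p_meta = max(st$p_meta, 1e-300), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p_meta, m = nrow(out))
  out$significant <- out$q < q_threshold
  out <- out[order(out$p_meta, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("meta_result", class(out))
  out
}
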