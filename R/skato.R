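#' Default configuration of the aggregation pipeline
#'
#' Collects every tunable threshold of the analysis in one object. Defaults
#' are the published analysis constants: MAF < 0.05, info >= 0.7, set size
#' 3-5000, genomic-control trigger lambda1000 >= 1.10, significance q < 0.05,
#' single-marker threshold 5e-8 with a 100-kb follow-up flank. The rho grid of
#' the SKAT-O combination is a convention of the SKAT-O literature (the source
#' engine does not print one) and is configurable.
#'
#' @param maf_max MAF upper bound (exclusive) for gene-set variants.
#' @param info_min imputation info lower bound (inclusive).
#' @param set_size eligible SNP-set size range.
#' @param coding_flank bp extension of exon/UTR intervals during mapping.
#' @param rho_grid SKAT-O correlation grid in `[0, 1]`.
#' @param covariates fixed-effect covariate columns for the null model.
#' @param gc_trigger lambda1000 threshold at/above which genomic control is
#'   applied to a cohort.
#' @param q_threshold FDR significance threshold.
#' @param gwas_p genome-wide single-marker significance threshold.
#' @param followup_flank bp flank around gene regions in locus follow-up.
#' @param acc absolute accuracy of the mixture-distribution inversion.
#' @param default_weight weight assigned to variants missing a score.
#' @return a list of class `agg_config`.
#' @export
agg_config <- function(maf_max = 0.05, info_min = 0.7,
                       set_size = c(3L, 5000L), coding_flank = 0,
                       rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1),
                       covariates = c("age"),
                       gc_trigger = 1.10, q_threshold = 0.05,
                       gwas_p = 5e-8, followup_flank = 1e5,
                       acc = 1e-9, default_weight = 0) {
  stopifnot(maf_max > 0, info_min >= 0, all(set_size > 0),
            coding_flank >= 0, all(rho_grid >= 0 & rho_grid <= 1),
            gc_trigger > 0, q_threshold > 0, gwas_p > 0, followup_flank >= 0)
  structure(list(maf_max = maf_max, info_min = info_min, set_size = set_size,
                 coding_flank = coding_flank, rho_grid = rho_grid,
                 covariates = covariates, gc_trigger = gc_trigger,
                 q_threshold = q_threshold, gwas_p = gwas_p,
                 followup_flank = followup_flank, acc = acc,
                 default_weight = default_weight),
            class = "agg_config")
}

## survival closure for one eigenvalue set (exact series / saddlepoint tiers)
.make_surv <- function(lam, acc) {
  lam <- lam[lam > 1e-10 * max(lam, 0)]
  sv <- .mix_survival_fun(lam, acc = acc)
  sv$degenerate <- sv$method == "degenerate"
  sv
}

#' Gene-level SKAT-O score test under the fitted mixed model
#'
#' Tests one weighted SNP set. With `r` the covariance-whitened null residual
#' and `Z` the covariance-whitened genotype block projected off the fixed
#' effects and scaled by the variant weights `W`, the statistic family is
#' \deqn{Q_\rho = r' Z R_\rho Z' r, \qquad R_\rho = (1-\rho) I + \rho 1 1',}
#' interpolating between the variance-component kernel statistic
#' (\eqn{\rho = 0}) and the squared weighted burden score (\eqn{\rho = 1}).
#' Each \eqn{Q_\rho} is referred to its exact null mixture of 1-df
#' chi-squares; the grid is combined through the minimum-p statistic whose
#' p-value is evaluated by one-dimensional integration over the shared
#' burden-direction component, with a Bonferroni-over-grid fallback (flagged)
#' if the integration fails. A Bonferroni cap `min(1, |grid| * min_p)` is
#' always applied.
#'
#' Missing dosages are mean-imputed per variant; zero-variance columns are
#' dropped and flagged; an all-zero weight vector yields the defined result
#' p = 1 with flag `"null_kernel"`. P-values are invariant to positive
#' rescaling of the weights and to variant order.
#'
#' @param null an [fit_null_lmm()] object.
#' @param G dosage matrix for the gene's variants (samples x variants, rows
#'   aligned with — or named by — the null model's samples).
#' @param weights non-negative per-variant weights, in column order of `G`.
#' @param rho_grid grid of correlation parameters in `[0, 1]`.
#' @param gene_id identifier copied into the result.
#' @param acc absolute accuracy of the mixture inversion.
#' @return list of class `skato_result`: `gene_id`, `p_value`, `rho_opt`,
#'   `p_rho`, `Q_rho`, `n_variants`, `flags` (character vector, possibly
#'   empty).
#' @export
skato_test <- function(null, G, weights,
                       rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1),
                       gene_id = NA_character_, acc = 1e-9) {
  stopifnot(inherits(null, "agg_null_model"), length(rho_grid) >= 1L)
  G <- as.matrix(G)
  if (!is.null(rownames(G))) {
    miss <- setdiff(null$sample_id, rownames(G))
    if (length(miss))
      .stopf("genotype matrix lacks sample(s): %s",
             paste(utils::head(miss, 5), collapse = ", "))
    G <- G[null$sample_id, , drop = FALSE]
  } else if (nrow(G) != null$n) {
    .stopf("genotype matrix has %d rows but the null model has %d samples",
           nrow(G), null$n)
  }
  if (length(weights) != ncol(G))
    .stopf("length(weights) = %d but ncol(G) = %d", length(weights), ncol(G))
  if (any(weights < 0)) .stopf("weights must be non-negative")
  flags <- character(0)

  result <- function(p, rho_opt = NA_real_, p_rho = NULL, Q_rho = NULL, m = 0L)
    structure(list(gene_id = gene_id, p_value = p, rho_opt = rho_opt,
                   p_rho = p_rho, Q_rho = Q_rho, n_variants = m,
                   flags = flags),
              class = "skato_result")

  ## per-variant mean imputation, then drop degenerate columns
  for (j in seq_len(ncol(G))) {
    nas <- is.na(G[, j])
    if (any(nas)) G[nas, j] <- mean(G[, j], na.rm = TRUE)
  }
  keep <- apply(G, 2L, stats::var) > 0 & weights > 0
  if (any(weights == 0) || any(apply(G, 2L, stats::var) <= 0)) {
    nzv <- sum(apply(G, 2L, stats::var) <= 0)
    if (nzv) flags <- c(flags, sprintf("zero_variance_dropped:%d", nzv))
  }
  if (all(weights == 0)) {
    flags <- c(flags, "null_kernel")
    return(result(1))
  }
  G <- G[, keep, drop = FALSE]
  weights <- weights[keep]
  m <- ncol(G)
  if (m == 0L) {
    flags <- c(flags, "null_kernel")
    return(result(1))
  }

  Z <- sweep(.project_geno(null, G), 2L, weights, `*`)
  S <- drop(crossprod(Z, null$rw))
  K0 <- crossprod(Z)

  ## single-variant set: every rho reduces to the same 1-df score test
  if (m == 1L) {
    lam <- K0[1, 1]
    if (lam <= 0) {
      flags <- c(flags, "null_kernel")
      return(result(1, m = 1L))
    }
    p <- stats::pchisq(S^2 / lam, df = 1, lower.tail = FALSE)
    return(result(max(p, .Machine$double.xmin), rho_opt = rho_grid[1],
                  p_rho = stats::setNames(rep(p, length(rho_grid)),
                                          rho_grid),
                  Q_rho = stats::setNames(rep(S^2, length(rho_grid)),
                                          rho_grid),
                  m = 1L))
  }

  rho_eval <- function(rho) {
    a <- sqrt(1 - rho)
    b <- (sqrt(1 - rho + m * rho) - a) / m
    RhK <- a * K0 + b * outer(rep(1, m), colSums(K0))
    M <- a * RhK + b * outer(rowSums(RhK), rep(1, m))   # Rh %*% K0 %*% Rh
    lam <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
    Q <- (1 - rho) * sum(S^2) + rho * sum(S)^2
    sv <- .make_surv(lam, acc)
    list(Q = Q, sv = sv)
  }

  ev <- lapply(rho_grid, rho_eval)
  p_rho <- vapply(seq_along(ev),
                  function(i) ev[[i]]$sv$surv(ev[[i]]$Q), numeric(1))
  Q_rho <- vapply(ev, function(x) x$Q, numeric(1))
  names(p_rho) <- names(Q_rho) <- rho_grid
  Tmin <- max(min(p_rho), .Machine$double.xmin)
  rho_opt <- rho_grid[which.min(p_rho)]

  if (length(rho_grid) == 1L)
    return(result(Tmin, rho_opt = rho_opt, p_rho = p_rho, Q_rho = Q_rho,
                  m = m))

  ## min-p combination: rho = 1 is clamped to 0.999 inside the combination
  grid2 <- pmin(rho_grid, 0.999)
  p_comb <- tryCatch({
    ev2 <- lapply(seq_along(rho_grid), function(i)
      if (grid2[i] == rho_grid[i]) ev[[i]] else rho_eval(grid2[i]))
    q_rho <- vapply(ev2, function(x) {
      if (x$sv$degenerate) return(Inf)
      .mixture_quantile(x$sv$surv, Tmin, x$sv$mu, x$sv$sd)
    }, numeric(1))

    z_mean <- rowMeans(Z)
    sumz2 <- sum(z_mean^2)
    if (sumz2 <= 0) NA_real_ else {
      cof <- drop(crossprod(z_mean, Z)) / sumz2
      Z1 <- outer(z_mean, cof)
      Z2 <- Z - Z1
      lam0 <- eigen(crossprod(Z2), symmetric = TRUE,
                    only.values = TRUE)$values
      sv0 <- .make_surv(lam0, acc)
      MuQ <- sv0$mu
      VarRemain <- 4 * sum(crossprod(Z1) * crossprod(Z2))
      VarQ <- sv0$sd^2 + VarRemain
      tau <- (m^2 * grid2 + (1 - grid2) * sum(cof^2)) * sumz2
      shrink <- if (VarQ > 0) sqrt(max(VarQ - VarRemain, 0) / VarQ) else 1

      ## integrate on the u = sqrt(x) scale (x ~ chisq_1, so x = u^2 with u
      ## half-normal): the integrand is then smooth at 0 and the upper limit
      ## tracks the true support x < min_rho q_rho / tau_rho, which collapses
      ## toward 0 for weak genes and would be missed on the raw x scale
      integrand_u <- function(u) {
        x <- u^2
        mins <- do.call(pmin, lapply(seq_along(grid2), function(i)
          (q_rho[i] - tau[i] * x) / (1 - grid2[i])))
        Fv <- numeric(length(x))
        pos <- mins > 0
        if (any(pos)) {
          st <- (mins[pos] - MuQ) * shrink + MuQ
          Fv[pos] <- 1 - sv0$surv(pmax(st, 0))
        }
        2 * Fv * stats::dnorm(u)
      }
      x_max <- min(q_rho / pmax(tau, .Machine$double.xmin))
      upper_u <- sqrt(min(40, x_max))
      1 - stats::integrate(integrand_u, lower = 0, upper = upper_u,
                           subdivisions = 2000L, abs.tol = 1e-12)$value
    }
  }, error = function(e) NA_real_)

  if (is.na(p_comb)) {
    flags <- c(flags, "fallback_bonferroni")
    p <- min(1, length(rho_grid) * Tmin)
  } else {
    p <- min(p_comb, length(rho_grid) * Tmin, 1)
    p <- max(p, Tmin)
  }
  result(p, rho_opt = rho_opt, p_rho = p_rho, Q_rho = Q_rho, m = m)
}

#' @export
print.skato_result <- function(x, ...) {
  cat(sprintf("SKAT-O %s: p = %.4g (rho_opt = %s, %d variants%s)\n",
              x$gene_id, x$p_value, format(x$rho_opt), x$n_variants,
              if (length(x$flags)) paste0("; ", paste(x$flags, collapse = ","))
              else ""))
  invisible(x)
}

#' Run the aggregation test for every gene of a cohort
#'
#' Fits the null mixed model once, then applies [skato_test()] to each SNP
#' set. Variants referenced by a set but absent from the dosage matrix are
#' dropped with a per-gene flag; genes left without variants are reported with
#' a reason rather than a p-value. Rows are ordered by `gene_id`.
#'
#' @param snpsets named list of `gene_snpset` objects (see [build_snpsets()]).
#' @param dosages sample x variant dosage matrix with ids as dimnames.
#' @param phenotypes phenotype/covariate table with `sample_id`.
#' @param kinship a `kinship_matrix` or plain PSD matrix.
#' @param config an [agg_config()].
#' @param null optionally a prefitted [fit_null_lmm()] (must match samples).
#' @return data.frame of class `cohort_result`: `gene_id`, `p`, `rho_opt`,
#'   `n_variants`, `flags` (`;`-collapsed, `""` when none).
#' @export
run_cohort <- function(snpsets, dosages, phenotypes, kinship,
                       config = agg_config(), null = NULL) {
  miss <- setdiff(phenotypes$sample_id, rownames(dosages))
  if (length(miss))
    .stopf("phenotype/genotype sample mismatch; missing from dosages: %s%s",
           paste(utils::head(miss, 5), collapse = ", "),
           if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5)
           else "")
  if (is.null(null))
    null <- fit_null_lmm(phenotypes, covariates = config$covariates,
                         kinship = kinship)

  gene_ids <- sort(vapply(snpsets, `[[`, "", "gene_id"))
  sets <- snpsets[order(vapply(snpsets, `[[`, "", "gene_id"))]
  rows <- lapply(sets, function(s) {
    present <- s$variant_id %in% colnames(dosages)
    flags <- character(0)
    if (any(!present))
      flags <- sprintf("variants_missing_from_dosages:%d", sum(!present))
    vid <- s$variant_id[present]
    if (length(vid) == 0L)
      return(data.frame(gene_id = s$gene_id, p = NA_real_,
                        rho_opt = NA_real_, n_variants = 0L,
                        flags = paste(c(flags, "no_variants_in_dosages"),
                                      collapse = ";"),
                        stringsAsFactors = FALSE))
    res <- skato_test(null, dosages[null$sample_id, vid, drop = FALSE],
                      weights = s$weight[present],
                      rho_grid = config$rho_grid, gene_id = s$gene_id,
                      acc = config$acc)
    data.frame(gene_id = s$gene_id, p = res$p_value, rho_opt = res$rho_opt,
               n_variants = res$n_variants,
               flags = paste(c(flags, res$flags), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), p = numeric(0), rho_opt = numeric(0),
               n_variants = integer(0), flags = character(0))
  rownames(out) <- NULL
  class(out) <- c("cohort_result", class(out))
  attr(out, "null_model") <- null
  out
}
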