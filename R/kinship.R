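#' Greedy LD pruning of common variants
#'
#' Reproduces the conventional sliding-window pruning recipe used before
#' relationship-matrix estimation: only variants with MAF above `maf_min` are
#' considered; within each window of `window_bp` base pairs the later variant
#' of any pair with squared Pearson correlation above `r2_max` is removed
#' (greedy, left to right along the chromosome); the window then advances by
#' `step` variants.
#'
#' @param dosages sample x variant dosage matrix, columns aligned with
#'   `variants`.
#' @param variants variant table with `variant_id`, `chrom`, `pos`.
#' @param window_bp window size in base pairs (default 50 kb).
#' @param step window advance in number of variants (default 5).
#' @param r2_max squared-correlation threshold above which the later variant
#'   is dropped (default 0.5).
#' @param maf_min minimum MAF (exclusive) for a variant to be considered
#'   (default 0.2).
#' @return character vector of kept variant ids (in genome order).
#' @export
ld_prune <- function(dosages, variants, window_bp = 50000, step = 5L,
                     r2_max = 0.5, maf_min = 0.2) {
  stopifnot(ncol(dosages) == nrow(variants))
  colnames(dosages) <- variants$variant_id
  pbar <- colMeans(dosages) / 2
  maf <- pmin(pbar, 1 - pbar)
  cand <- which(maf > maf_min)
  if (length(cand) < 2L) return(variants$variant_id[cand])

  v <- variants[cand, , drop = FALSE]
  o <- order(v$chrom, v$pos)
  v <- v[o, , drop = FALSE]
  X <- dosages[, cand[o], drop = FALSE]
  n <- nrow(v)
  keep <- rep(TRUE, n)

  i <- 1L
  while (i < n) {
    in_win <- which(v$chrom == v$chrom[i] &
                      v$pos >= v$pos[i] & v$pos <= v$pos[i] + window_bp)
    in_win <- in_win[in_win >= i]
    live <- in_win[keep[in_win]]
    if (length(live) >= 2L) {
      for (a in seq_len(length(live) - 1L)) {
        ia <- live[a]
        if (!keep[ia]) next
        for (b in (a + 1L):length(live)) {
          ib <- live[b]
          if (!keep[ib]) next
          r <- suppressWarnings(stats::cor(X[, ia], X[, ib]))
          if (is.finite(r) && r * r > r2_max) keep[ib] <- FALSE
        }
      }
    }
    i <- i + step
  }
  v$variant_id[keep]
}

#' Genetic relationship matrix from dosages
#'
#' Average over variants of the outer products of mean-centered dosage
#' vectors. With `method = "standardized"` (default) each centered vector is
#' also divided by its standard deviation, giving unit expected diagonal for
#' outbred samples; `method = "centered"` skips the per-variant
#' standardization and rescales by the mean variant variance instead, the
#' convention of centered-GRM tools. Monomorphic (zero-variance) variants are
#' dropped with a warning.
#'
#' @param dosages sample x variant dosage matrix restricted to the
#'   LD-pruned variant set.
#' @param method `"standardized"` or `"centered"`.
#' @return symmetric sample x sample relationship matrix.
#' @export
compute_grm <- function(dosages, method = c("standardized", "centered")) {
  method <- match.arg(method)
  stopifnot(ncol(dosages) >= 1L)
  X <- scale(dosages, center = TRUE, scale = FALSE)
  v <- apply(X, 2L, stats::var)
  mono <- v <= 0 | !is.finite(v)
  if (any(mono)) {
    warning(sprintf("dropping %d monomorphic variant(s) with zero variance",
                    sum(mono)))
    X <- X[, !mono, drop = FALSE]
    v <- v[!mono]
  }
  if (ncol(X) == 0L) .stopf("no polymorphic variants left for the GRM")
  if (method == "standardized") {
    X <- sweep(X, 2L, sqrt(v), `/`)
    K <- tcrossprod(X) / ncol(X)
  } else {
    K <- tcrossprod(X) / ncol(X) / mean(v)
  }
  dimnames(K) <- list(rownames(dosages), rownames(dosages))
  (K + t(K)) / 2
}

#' Method-of-moments inbreeding coefficients
#'
#' Per-sample excess homozygosity relative to Hardy-Weinberg expectation:
#' the mean over variants of
#' \deqn{(g^2 - (1 + 2\tilde p) g + 2 \tilde p^2) / (2 \tilde p (1 - \tilde p))}
#' with \eqn{\tilde p} the sample allele frequency of the variant. Zero in
#' expectation at Hardy-Weinberg equilibrium; 1 for a fully homozygous sample.
#' Monomorphic variants are dropped with a warning.
#'
#' @param dosages sample x variant dosage matrix (pruned variant set).
#' @return named numeric vector of inbreeding coefficients.
#' @export
inbreeding_coefficients <- function(dosages) {
  p <- colMeans(dosages) / 2
  ok <- p > 0 & p < 1
  if (any(!ok)) {
    warning(sprintf("dropping %d monomorphic variant(s)", sum(!ok)))
    dosages <- dosages[, ok, drop = FALSE]
    p <- p[ok]
  }
  if (ncol(dosages) == 0L) .stopf("no polymorphic variants for inbreeding")
  num <- dosages^2 - sweep(dosages, 2L, 1 + 2 * p, `*`) +
    matrix(2 * p^2, nrow(dosages), ncol(dosages), byrow = TRUE)
  den <- 2 * p * (1 - p)
  F <- rowMeans(sweep(num, 2L, den, `/`))
  names(F) <- rownames(dosages)
  F
}

#' Assemble the kinship matrix for the mixed-model random effect
#'
#' Off-diagonal entries come from the relationship matrix; the diagonal is
#' replaced by `1 + F` per sample. Symmetry is enforced and, if the result has
#' negative eigenvalues, they are floored at zero by spectral reconstruction
#' (the applied shift, i.e. the magnitude of the most negative eigenvalue, is
#' recorded) so the output is always a valid covariance.
#'
#' @param grm relationship matrix from [compute_grm()].
#' @param F per-sample inbreeding coefficients from
#'   [inbreeding_coefficients()], aligned with `grm`.
#' @return object of class `kinship_matrix`: list with `K` (the matrix,
#'   dimnames = sample ids), `F`, and `shift` (0 when no repair was needed).
#' @export
assemble_kinship <- function(grm, F) {
  if (nrow(grm) != ncol(grm) || nrow(grm) != length(F))
    .stopf("dimension mismatch: grm is %dx%d but F has length %d",
           nrow(grm), ncol(grm), length(F))
  K <- (grm + t(grm)) / 2
  diag(K) <- 1 + F
  e <- eigen(K, symmetric = TRUE)
  shift <- 0
  if (min(e$values) < -1e-10 * max(abs(e$values))) {
    shift <- abs(min(e$values))
    ev <- pmax(e$values, 0)
    K <- e$vectors %*% (ev * t(e$vectors))
    K <- (K + t(K)) / 2
    message(sprintf("kinship repaired to PSD: eigenvalue shift %.3g applied",
                    shift))
  }
  dimnames(K) <- dimnames(grm)
  structure(list(K = K, F = F, shift = shift), class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("Kinship matrix: %d samples, mean diagonal %.3f, PSD shift %.3g\n",
              nrow(x$K), mean(diag(x$K)), x$shift))
  invisible(x)
}

#' One-call kinship construction from a cohort
#'
#' Convenience wrapper running the full recipe: LD pruning of common markers,
#' relationship matrix, inbreeding coefficients, assembly.
#'
#' @param dosages,variants full cohort dosage matrix and variant table.
#' @param ... passed to [ld_prune()].
#' @param grm_method passed to [compute_grm()].
#' @return a `kinship_matrix`.
#' @export
build_kinship <- function(dosages, variants, grm_method = "standardized",
                          ...) {
  kept <- ld_prune(dosages, variants, ...)
  if (length(kept) < 1L)
    .stopf("LD pruning retained no variants; cannot build a kinship matrix")
  X <- dosages[, kept, drop = FALSE]
  grm <- compute_grm(X, method = grm_method)
  F <- inbreeding_coefficients(X)
  assemble_kinship(grm, F)
}
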