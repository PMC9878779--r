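#' Fit the cohort-level null linear mixed model
#'
#' Fits, once per cohort, the mixed model used by every gene-level score test:
#' case-control status (0/1, treated as a quantitative trait, the convention
#' of mixed-model aggregation engines) regressed on fixed covariates with a
#' kinship random effect,
#' \deqn{y = X\beta + g + e,\quad g \sim N(0, \sigma^2_g K),\quad
#'       e \sim N(0, \sigma^2_e I).}
#' Variance components are estimated by REML through a one-time spectral
#' decomposition of `K` followed by 1-D optimization of the profiled REML
#' criterion over the heritability ratio
#' \eqn{h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e)}. When the profile is
#' flat near the boundary (e.g. `K = I`, where \eqn{\sigma^2_g} is not
#' identifiable), the estimate is tied to the boundary 0 and total variance
#' matches the OLS residual variance.
#'
#' Samples with missing trait or covariate values are dropped (and counted in
#' the returned object); a singular fixed-effect design is rejected naming the
#' collinear columns.
#'
#' @param phenotypes data.frame with `sample_id`, the trait column, and the
#'   covariate columns.
#' @param covariates character vector of covariate column names (fitted via
#'   `model.matrix`, so factors expand to indicators); `NULL` for intercept
#'   only.
#' @param kinship a [assemble_kinship()] result or a symmetric PSD matrix with
#'   sample ids as dimnames.
#' @param trait trait column name (default `"status"`).
#' @param K_eigen optional precomputed `eigen(K, symmetric = TRUE)` for the
#'   aligned kinship (reused across fits on the same samples).
#' @return object of class `agg_null_model` carrying the fixed-effect
#'   estimates, variance components, the whitened residual vector and the
#'   whitened-design QR factorization used to project gene genotypes.
#' @export
fit_null_lmm <- function(phenotypes, covariates = NULL, kinship,
                         trait = "status", K_eigen = NULL) {
  K <- if (inherits(kinship, "kinship_matrix")) kinship$K else kinship
  if (is.null(rownames(K))) .stopf("kinship matrix needs sample ids as dimnames")

  cols <- c(trait, covariates)
  missing_cols <- setdiff(cols, names(phenotypes))
  if (length(missing_cols))
    .stopf("phenotype table lacks column(s): %s",
           paste(missing_cols, collapse = ", "))
  cc <- stats::complete.cases(phenotypes[cols])
  dropped <- sum(!cc)
  ph <- phenotypes[cc, , drop = FALSE]

  miss <- setdiff(ph$sample_id, rownames(K))
  if (length(miss))
    .stopf("samples absent from kinship matrix: %s%s",
           paste(utils::head(miss, 5), collapse = ", "),
           if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5) else "")
  ids <- ph$sample_id
  K <- K[ids, ids]

  y <- as.numeric(ph[[trait]])
  X <- if (is.null(covariates) || length(covariates) == 0L)
    matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  else stats::model.matrix(stats::reformulate(covariates), data = ph)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    .stopf("singular fixed-effect design; collinear column(s): %s",
           paste(bad, collapse = ", "))
  }

  e <- K_eigen %||% eigen(K, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values)))
    .stopf("kinship matrix is not positive semi-definite (min eigenvalue %.3g); run assemble_kinship()",
           min(e$values))
  d <- pmax(e$values, 0)
  U <- e$vectors

  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  n <- length(y); p <- ncol(X)

  reml <- function(h) {
    v <- h * d + (1 - h)
    w <- 1 / v
    fit <- stats::lm.wfit(Xt, yt, w)
    rss <- sum(w * fit$residuals^2)
    XtWX <- crossprod(Xt, Xt * w)
    -0.5 * ((n - p) * log(rss / (n - p)) + sum(log(v)) +
              determinant(XtWX, logarithm = TRUE)$modulus[1])
  }
  opt <- stats::optimize(reml, interval = c(0, 1 - 1e-6), maximum = TRUE,
                         tol = 1e-8)
  h <- opt$maximum
  if (reml(0) >= opt$objective - 1e-6) h <- 0   # boundary tie-break

  v <- h * d + (1 - h)
  w <- 1 / v
  fit <- stats::lm.wfit(Xt, yt, w)
  sigma2 <- sum(w * fit$residuals^2) / (n - p)
  sigma2_g <- h * sigma2
  sigma2_e <- (1 - h) * sigma2

  vinv_half <- 1 / sqrt(v * sigma2)
  Xw <- vinv_half * Xt
  yw <- vinv_half * yt
  qrX <- qr(Xw)
  rw <- qr.resid(qrX, yw)

  structure(list(sample_id = ids, trait = trait, covariates = covariates,
                 beta = stats::setNames(fit$coefficients, colnames(X)),
                 sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 h2 = if (sigma2 > 0) sigma2_g / sigma2 else 0,
                 U = U, vinv_half = vinv_half, qrX = qrX, rw = rw,
                 n = n, n_dropped = dropped, reml = opt$objective),
            class = "agg_null_model")
}

#' @export
print.agg_null_model <- function(x, ...) {
  cat(sprintf("Null LMM: n = %d (%d dropped), sigma2_g = %.4f, sigma2_e = %.4f (h2 = %.3f)\n",
              x$n, x$n_dropped, x$sigma2_g, x$sigma2_e, x$h2))
  cat("fixed effects:", paste(sprintf("%s=%.3g", names(x$beta), x$beta),
                              collapse = ", "), "\n")
  invisible(x)
}

## whiten a genotype block with the fitted covariance and project off the
## fixed-effect design; columns of the result have N(0, crossprod) scores
.project_geno <- function(null, G) {
  stopifnot(nrow(G) == null$n)
  Gw <- null$vinv_half * crossprod(null$U, G)
  qr.resid(null$qrX, Gw)
}
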