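#' Median-based genomic inflation factor
#'
#' Converts p-values to 1-df chi-square quantiles and divides their median by
#' the 1-df chi-square median (0.4549364), the usual lambda statistic. At
#' least 20 finite p-values are required for a stable median.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return lambda (scalar).
#' @export
estimate_lambda <- function(p) {
  p <- p[is.finite(p)]
  if (length(p) < 20L)
    .stopf("need at least 20 finite p-values to estimate lambda (got %d)",
           length(p))
  if (any(p <= 0 | p > 1)) .stopf("p-values must lie in (0, 1]")
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Sample-size-standardized inflation factor lambda1000
#'
#' Rescales lambda to a nominal study of 1000 cases and 1000 controls so that
#' inflation is comparable across cohorts of different size:
#' \deqn{\lambda_{1000} = 1 + (\lambda - 1)
#'   \frac{1/n_{cases} + 1/n_{controls}}{1/1000 + 1/1000}.}
#'
#' @param lambda inflation factor from [estimate_lambda()].
#' @param n_cases,n_controls case and control counts (> 0).
#' @return lambda1000 (scalar).
#' @export
lambda_1000 <- function(lambda, n_cases, n_controls) {
  if (n_cases <= 0 || n_controls <= 0)
    .stopf("case and control counts must be positive")
  if (!is.finite(lambda) || lambda < 1e-3)
    .stopf("lambda must be positive (got %s)", format(lambda))
  1 + (lambda - 1) * (1 / n_cases + 1 / n_controls) / (2 / 1000)
}

#' Genomic-control correction of p-values
#'
#' Divides each p-value's 1-df chi-square quantile by lambda and maps back to
#' a tail probability. The correction never inflates significance: with
#' `lambda < 1` the input is returned unchanged (with a message), and for
#' `lambda > 1` every corrected p-value is at least the raw one. Ranks are
#' preserved.
#'
#' @param p p-values in (0, 1].
#' @param lambda inflation factor.
#' @return corrected p-values.
#' @export
genomic_control <- function(p, lambda) {
  if (any(!is.finite(p) | p <= 0 | p > 1))
    .stopf("p-values must lie in (0, 1]")
  if (lambda <= 1) {
    if (lambda < 1)
      message(sprintf("lambda = %.3f < 1: genomic control not applied",
                      lambda))
    return(p)
  }
  stats::pchisq(stats::qchisq(p, df = 1, lower.tail = FALSE) / lambda,
                df = 1, lower.tail = FALSE)
}

#' Per-cohort inflation report with optional genomic control
#'
#' Computes lambda and lambda1000 for a cohort's gene-level p-values, decides
#' whether genomic control is indicated (`lambda1000 >= gc_trigger`,
#' default 1.10), and returns corrected p-values plus a QQ table of expected
#' versus observed -log10 p quantiles (a data table; plotting is left to the
#' caller).
#'
#' @param results a `cohort_result` data.frame (or any table with `gene_id`
#'   and `p`).
#' @param n_cases,n_controls cohort composition.
#' @param cohort_id label copied into the report.
#' @param gc_trigger lambda1000 threshold at/above which GC is applied.
#' @return list of class `inflation_report`: `cohort_id`, `lambda`,
#'   `lambda1000`, `n_cases`, `n_controls`, `gc_applied`, `p_corrected`
#'   (named by gene), `qq` (data.frame expected/observed).
#' @export
inflation_report <- function(results, n_cases, n_controls,
                             cohort_id = "cohort", gc_trigger = 1.10) {
  ok <- is.finite(results$p)
  p <- results$p[ok]
  if (length(p) < 20L) {
    ## too few genes for a stable median: report NA, never correct
    message(sprintf(
      "cohort %s: only %d p-values; lambda not estimated, GC not applied",
      cohort_id, length(p)))
    lambda <- NA_real_
    l1000 <- NA_real_
    gc_applied <- FALSE
    p_corr <- p
  } else {
    lambda <- estimate_lambda(p)
    l1000 <- lambda_1000(lambda, n_cases, n_controls)
    gc_applied <- l1000 >= gc_trigger
    p_corr <- if (gc_applied) genomic_control(p, lambda) else p
  }
  o <- order(p)
  qq <- data.frame(
    expected = -log10((seq_along(p) - 0.5) / length(p)),
    observed = -log10(p[o])
  )
  structure(list(cohort_id = cohort_id, lambda = lambda, lambda1000 = l1000,
                 n_cases = n_cases, n_controls = n_controls,
                 gc_applied = gc_applied,
                 p_corrected = stats::setNames(p_corr, results$gene_id[ok]),
                 qq = qq),
            class = "inflation_report")
}

#' @export
print.inflation_report <- function(x, ...) {
  cat(sprintf("Inflation %s: lambda = %.3f, lambda1000 = %.3f (%d cases / %d controls)%s\n",
              x$cohort_id, x$lambda, x$lambda1000, x$n_cases, x$n_controls,
              if (x$gc_applied) " [genomic control applied]" else ""))
  invisible(x)
}
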