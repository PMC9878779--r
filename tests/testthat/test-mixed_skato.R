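test_that("chi-square mixture tail probabilities match closed forms", {
  expect_equal(as.numeric(mixture_chisq_pvalue(qchisq(0.95, 1), 1)), 0.05,
               tolerance = 1e-9)
  expect_equal(as.numeric(mixture_chisq_pvalue(qchisq(0.95, 2), c(1, 1))),
               0.05, tolerance = 1e-9)
  expect_equal(as.numeric(mixture_chisq_pvalue(2 * qchisq(0.95, 1), 2)), 0.05,
               tolerance = 1e-9)
  ## degenerate and error cases
  expect_equal(as.numeric(mixture_chisq_pvalue(3, numeric(0))), 1)
  expect_equal(as.numeric(mixture_chisq_pvalue(3, c(0, 0))), 1)
  expect_error(mixture_chisq_pvalue(3, c(1, -0.5)), "non-negative")
  expect_error(mixture_chisq_pvalue(-1, 1))
})

test_that("mixture inversion agrees with Monte Carlo, moderate and wide spread", {
  set.seed(6)
  cases <- list(
    ## Ruben regime: certified accuracy everywhere, checked mid and tail
    list(lam = c(3.2, 1.1, 0.4, 0.05), probs = c(0.5, 0.9, 0.99),
         slack = 1e-4),
    ## wide eigenvalue spread: saddlepoint tier, relative-accurate in the
    ## tails (mid-distribution accuracy is ~0.5% absolute and not asserted)
    list(lam = exp(runif(12, -6, 3)), probs = c(0.9, 0.99, 0.999),
         slack = 5e-4)
  )
  B <- 400000L
  for (cs in cases) {
    draws <- colSums(cs$lam * matrix(rchisq(length(cs$lam) * B, df = 1),
                                     length(cs$lam)))
    for (q in quantile(draws, cs$probs)) {
      mc <- mean(draws >= q)
      se <- sqrt(mc * (1 - mc) / B)
      pv <- as.numeric(mixture_chisq_pvalue(q, cs$lam))
      expect_lt(abs(pv - mc), 3 * se + cs$slack)
    }
  }
})

test_that("mixture survival is monotone decreasing in the statistic", {
  lam <- c(4, 1, 0.2, 0.01)
  qs <- seq(0.1, 60, length.out = 40)
  ps <- vapply(qs, function(q) as.numeric(mixture_chisq_pvalue(q, lam)), 0)
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("null LMM with identity kinship reduces to ordinary least squares", {
  set.seed(31)
  n <- 80
  ph <- data.frame(sample_id = sprintf("S%03d", 1:n),
                   status = rbinom(n, 1, 0.5), age = runif(n, 30, 80))
  nm <- fit_null_lmm(ph, "age", identity_kinship(ph$sample_id))
  ols <- lm(status ~ age, data = ph)
  expect_equal(nm$h2, 0)                      # boundary tie-break
  expect_equal(unname(nm$beta), unname(coef(ols)), tolerance = 1e-6)
  expect_equal(nm$sigma2_g + nm$sigma2_e, summary(ols)$sigma^2,
               tolerance = 1e-6)
})

test_that("null LMM is invariant to sample permutation and validates input", {
  fx <- toy_cohort()
  co <- fx$cohort
  kin <- suppressMessages(build_kinship(co$dosages, co$variants))
  nm1 <- fit_null_lmm(co$phenotypes, c("age", "study"), kin)
  perm <- sample(nrow(co$phenotypes))
  nm2 <- fit_null_lmm(co$phenotypes[perm, ], c("age", "study"), kin)
  expect_equal(nm1$sigma2_g, nm2$sigma2_g, tolerance = 1e-6)
  expect_equal(nm1$sigma2_e, nm2$sigma2_e, tolerance = 1e-6)
  expect_equal(sort(nm1$beta), sort(nm2$beta), tolerance = 1e-5)

  ## collinear design rejected naming the column
  ph <- co$phenotypes
  ph$age2 <- ph$age
  expect_error(fit_null_lmm(ph, c("age", "age2"), kin), "age2")
  ## incomplete covariates dropped
  ph2 <- co$phenotypes
  ph2$age[1:5] <- NA
  nm3 <- fit_null_lmm(ph2, "age", kin)
  expect_equal(nm3$n_dropped, 5L)
  expect_equal(nm3$n, nrow(ph2) - 5L)
  ## unknown samples rejected with ids
  ph3 <- co$phenotypes
  ph3$sample_id[1] <- "GHOST"
  expect_error(fit_null_lmm(ph3, "age", kin), "GHOST")
})

test_that("single-variant sets reduce to the 1-df mixed-model score test", {
  fx <- toy_null_fixture(seed = 11, beta = 0.3)
  g <- fx$G[, 3, drop = FALSE]
  r <- skato_test(fx$null, g, weights = 2.5, gene_id = "g")
  ## closed form from first principles: S = z'r, p = P(chi2_1 >= S^2 / z'z)
  z <- genagg:::.project_geno(fx$null, g) * 2.5
  S <- sum(z * fx$null$rw)
  p_closed <- pchisq(S^2 / sum(z^2), df = 1, lower.tail = FALSE)
  expect_equal(r$p_value, p_closed, tolerance = 1e-12)
  expect_equal(r$n_variants, 1L)
})

test_that("rho = 1 equals the direct weighted-burden score test", {
  fx <- toy_null_fixture(seed = 12, beta = 0.3)
  burden <- fx$G %*% fx$w
  r_set <- skato_test(fx$null, fx$G, fx$w, rho_grid = 1)
  r_burden <- skato_test(fx$null, burden, 1, rho_grid = 1)
  expect_equal(r_set$p_value, r_burden$p_value, tolerance = 1e-9)
})

test_that("p-values are invariant to weight scale and variant order", {
  fx <- toy_null_fixture(seed = 13, beta = 0.25)
  p0 <- skato_test(fx$null, fx$G, fx$w)$p_value
  expect_equal(skato_test(fx$null, fx$G, 7 * fx$w)$p_value, p0,
               tolerance = 1e-8)
  o <- c(5, 2, 8, 1, 3, 7, 4, 6)
  expect_equal(skato_test(fx$null, fx$G[, o], fx$w[o])$p_value, p0,
               tolerance = 1e-10)
})

test_that("degenerate kernels and missing dosages are handled as contracted", {
  fx <- toy_null_fixture(seed = 14)
  ## all-zero weights: defined p = 1 with null_kernel flag
  r0 <- skato_test(fx$null, fx$G, rep(0, ncol(fx$G)))
  expect_equal(r0$p_value, 1)
  expect_true("null_kernel" %in% r0$flags)
  ## zero-variance column dropped and flagged
  G2 <- cbind(fx$G, const = rep(1, nrow(fx$G)))
  r1 <- skato_test(fx$null, G2, c(fx$w, 5))
  expect_true(any(grepl("zero_variance", r1$flags)))
  expect_equal(r1$n_variants, ncol(fx$G))
  ## missing dosages mean-imputed: p finite and close to complete-data p
  G3 <- fx$G
  G3[1:2, 1] <- NA
  r2 <- skato_test(fx$null, G3, fx$w)
  expect_true(is.finite(r2$p_value) && r2$p_value > 0 && r2$p_value <= 1)
})

test_that("run_cohort orders rows, logs missing variants, validates samples", {
  fx <- toy_cohort()
  co <- fx$cohort
  snp <- build_snpsets(fx$ann$gene_models, fx$ann$elements, fx$ann$eqtls,
                       co$variants, fx$ann$scores)
  kin <- suppressMessages(build_kinship(co$dosages, co$variants))
  cfg <- agg_config(covariates = c("age", "study"))
  res <- run_cohort(snp$sets, co$dosages, co$phenotypes, kin, cfg)
  expect_s3_class(res, "cohort_result")
  expect_equal(res$gene_id, sort(res$gene_id))
  expect_true(all(res$p > 0 & res$p <= 1))
  ## rerun is deterministic
  res2 <- run_cohort(snp$sets, co$dosages, co$phenotypes, kin, cfg)
  expect_identical(res$p, res2$p)

  ## a set referencing an unknown variant: dropped with a flag
  s <- snp$sets[[1]]
  s$variant_id[1] <- "ghost_variant"
  res3 <- run_cohort(list(s), co$dosages, co$phenotypes, kin, cfg)
  expect_true(grepl("variants_missing_from_dosages:1", res3$flags[1]))

  ## empty SNP-set list: empty table, success
  res4 <- run_cohort(list(), co$dosages, co$phenotypes, kin, cfg)
  expect_equal(nrow(res4), 0L)

  ## phenotype/genotype mismatch rejected listing ids
  ph <- co$phenotypes
  ph$sample_id[2] <- "MISSING01"
  expect_error(run_cohort(snp$sets, co$dosages, ph, kin, cfg), "MISSING01")
})

test_that("a strongly causal gene dominates a small cohort scan", {
  sp <- cohort_spec(seed = 99, n_samples = 400, n_genes = 15,
                    variants_per_gene = c(8, 15), n_background_variants = 800,
                    causal_genes = data.frame(gene = 4, effect = 0.9,
                                              frac_causal = 0.6))
  co <- simulate_cohort(sp)
  ann <- simulate_annotations(sp)
  snp <- build_snpsets(ann$gene_models, ann$elements, ann$eqtls,
                       co$variants, ann$scores)
  kin <- suppressMessages(build_kinship(co$dosages, co$variants))
  res <- run_cohort(snp$sets, co$dosages, co$phenotypes, kin, agg_config())
  expect_equal(res$gene_id[which.min(res$p)], "G0004")
})
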