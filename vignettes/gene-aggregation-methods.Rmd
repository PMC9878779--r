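---
title: "Gene-based aggregation testing with genagg: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based aggregation testing with genagg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genagg)
```

## The problem and the model

Single-marker association scans leave two gaps that gene-based aggregation
addresses: low-frequency variants (MAF < 0.05) are individually underpowered,
and significant markers rarely identify their target gene. `genagg` tests one
gene at a time by aggregating all low-frequency variants that plausibly act on
that gene — exonic and UTR variants plus variants in regulatory elements
(promoters, enhancers, transcription-factor-binding sites) linked to the gene
either by physical overlap with the gene body or by a significant eQTL — and
weighting each variant by a Phred-scaled pathogenicity score.

The per-gene test is SKAT-O under a linear mixed model. Writing $y$ for the
0/1 case-control status, $X$ for fixed covariates (age, and recruitment study
where used), and $K$ for a genotype-derived kinship matrix,

$$y = X\beta + g + e, \qquad g \sim N(0, \sigma^2_g K), \quad
  e \sim N(0, \sigma^2_e I).$$

The kinship random effect absorbs family structure and, to first order,
ancestry stratification. A binary trait fitted by a *linear* mixed model is a
deliberate choice, matching the engine the analysis design is based on: score
tests under an LMM are robust for common binary outcomes, and the alternative
(penalized quasi-likelihood logistic mixed models) does not admit the same
one-fit-per-cohort score-test architecture.

With $r$ the covariance-whitened null residual and $Z$ the whitened genotype
block projected off the fixed effects and scaled by the weights, the statistic
family is

$$Q_\rho = r' Z R_\rho Z' r, \qquad R_\rho = (1-\rho) I + \rho 1 1',$$

interpolating between the variance-component kernel statistic ($\rho = 0$,
powerful for mixed effect directions) and the squared weighted burden score
($\rho = 1$, powerful for unidirectional effects). Each $Q_\rho$ is referred
to its null distribution — a weighted sum of 1-df chi-squares with weights the
eigenvalues of $R_\rho^{1/2} Z'Z R_\rho^{1/2}$ — and the grid is combined by
the minimum-p statistic, whose p-value is computed by one-dimensional
integration over the shared burden-direction chi-square. The null model is
fitted once per cohort; genes only ever enter through score statistics.

Downstream, per-cohort results are screened for inflation ($\lambda$ and the
sample-size-standardized $\lambda_{1000}$), genomic control is applied where
$\lambda_{1000} \ge 1.10$, cohorts are combined per gene by Stouffer's method
with $\sqrt{N}$ weights, and genes are declared significant at
Benjamini–Hochberg $q < 0.05$. Significant genes are classified against
single-marker GWAS results: a gene region (union of its coding and linked
regulatory intervals, ±100 kb) containing a marker with $p < 5\times10^{-8}$
counts as a previously identified locus.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `maf_max` | 0.05 | low-frequency cutoff, strict `<`, on dosage-estimated MAF |
| `info_min` | 0.7 | imputation accuracy floor, inclusive (`>= 0.7` retained) |
| `set_size` | [3, 5000] | eligible SNP-set size; outside → gene excluded with reason |
| `coding_flank` | 0 bp | extension of exon/UTR intervals during mapping; the upstream analysis used an extended window whose size it does not state, so the flank is configurable and defaults to no extension |
| `rho_grid` | 0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1 | SKAT-O correlation grid; the source engine prints no grid, so the conventional grid of the SKAT-O literature is used |
| LD pruning | 50 kb / 5 / 0.5 / MAF > 0.2 | window, variant step, $r^2$ cut, frequency floor for kinship markers |
| `gc_trigger` | 1.10 | $\lambda_{1000}$ at/above which genomic control is applied (the published analysis corrected exactly its two cohorts with $\lambda_{1000}$ = 1.32 and 1.14) |
| `gwas_p`, `followup_flank` | 5e-8, 100 kb | single-marker significance and follow-up flank |
| `q_threshold` | 0.05 | FDR significance level |

Boundary conventions follow the published filters: MAF exactly 0.05 is
excluded, info exactly 0.7 is retained, a GWAS marker at exactly
$5\times10^{-8}$ does not make a locus "known".

## The synthetic cohort generator

Individual-level data of the motivating study are access-controlled, so the
package ships a generator whose output has the statistical structure the
analysis assumes; all validation runs on it.

* **Genotypes.** Ancestral MAFs are uniform in `maf_range` (default
  0.005–0.05). Discrete ancestry groups diverge under the Balding–Nichols
  model: group frequencies are Beta-distributed around the ancestral frequency
  with divergence `fst`. Full-sib pairs are gene-dropped from simulated
  parents, giving realized relatedness ≈ 0.5.
* **Imputation dosages.** Hard genotypes are shrunk toward twice the group
  frequency, $d = 2p + \sqrt{\text{info}}\,(g - 2p)$, so the dosage variance
  equals `info` times the genotype variance — the operational meaning of an
  info score — while the allele frequency is preserved. Downstream filters
  therefore act on dosage MAF and info exactly as in real imputed data.
* **Background markers.** The kinship recipe needs common markers
  (MAF > 0.2), which low-frequency gene variants cannot supply; each cohort
  therefore carries `n_background_variants` (default 2000) common markers not
  assigned to any gene, mimicking genome-wide array content. They are excluded
  from SNP sets by the MAF filter itself.
* **Phenotype.** Case-control status is logistic: the log-odds add an
  age effect (per SD of age, age uniform 30–80), a recruitment-study effect
  (per study index, studies multinomial), and, for each causal gene, `effect`
  log-odds per causal minor allele, where the causal variants are the stated
  fraction of the gene's variants. The intercept is solved so the expected
  case fraction matches the spec. Weights play no role in the generating
  model — "effect per causal allele" is the unweighted allele count — so
  pathogenicity weighting in the test is a pure analysis choice, as in real
  data.
* **Annotations.** Gene models (exons flanked by UTRs), 0–3 regulatory
  elements per gene (about half inside the gene body, the rest 10–250 kb
  away), eQTL records for a subset of distal elements (significant for ~70%,
  deliberately sub-threshold for some others, so both linking rules and their
  negation are exercised), and a right-skewed Phred-like score
  (Exp(mean 6), capped at 60) for every variant.

What a green test on this world does **not** establish: realistic linkage
disequilibrium within genes (variants are drawn independently given ancestry),
haplotype structure, X-chromosome inheritance, genotyping artifacts, or the
behavior of the test at consortium scale (hundreds of thousands of samples).

## Numerical choices

* **Mixture tail probabilities.** $P(\sum_k \lambda_k \chi^2_1 \ge q)$ is
  computed by Ruben's expansion into central chi-squares with scale
  $\beta = \lambda_{\min}$ — an exact inversion with all-positive terms and a
  certified truncation bound, evaluated to absolute accuracy $10^{-9}$. When
  the eigenvalue spread makes the series impractically long (heavily weighted
  kernels), a Lugannani–Rice saddlepoint approximation of the survival
  function takes over; it is relative-accurate in both tails. Liu-type moment
  matching is used only where the saddlepoint is undefined (statistics at the
  distribution mean) or inputs are degenerate. The tiers were validated
  against closed forms and 400k-draw Monte Carlo.
* **Min-p combination.** The grid is combined as in the SKAT-O literature:
  per-$\rho$ quantiles at the observed minimum p, then one-dimensional
  integration over the shared burden-direction chi-square, with $\rho = 1$
  clamped to 0.999 inside the combination and a Bonferroni-over-grid cap
  applied throughout; if the integration itself fails the Bonferroni value is
  used and flagged. The integral is evaluated on the $u = \sqrt{x}$ scale
  with a support-aware upper limit $x < \min_\rho q_\rho/\tau_\rho$: on the
  raw scale the integrand's support collapses toward 0 for weak genes and
  adaptive quadrature can miss it entirely (this produced an atom of p-values
  at exactly 1 before the reparameterization).
* **REML.** One spectral decomposition of $K$ per cohort, then 1-D
  optimization of the profiled criterion over
  $h^2 = \sigma^2_g/(\sigma^2_g+\sigma^2_e)$ on $[0, 1)$; a flat profile ties
  the estimate to the boundary 0 (e.g. $K = I$, where only the total variance
  is identifiable). A precomputed decomposition can be supplied when many fits
  share one kinship.
* **Kinship assembly.** The relationship matrix uses mean-centered,
  variance-standardized dosages (a centered-GRM variant is available via
  `method = "centered"`); the diagonal is replaced by $1 + \hat F$ with the
  single method-of-moments inbreeding estimator; negative eigenvalues are
  floored at zero by spectral reconstruction with the applied shift reported,
  so the random-effect covariance is always valid. Replacing the diagonal of
  a noisily estimated GRM routinely creates small negative eigenvalues, so
  the repair message is common and benign at simulation scale.
* **Small-sample behavior.** The test is asymptotic, like the engine it
  reimplements. At a few dozen samples the analytic p-value is systematically
  conservative in the deep tail relative to an exact phenotype-permutation
  null, because permutation conditions on the residual norm while the
  chi-square mixture does not (the plug-in-$\hat\sigma^2$
  effect). The permutation-agreement test therefore runs at moderate
  association strength, where the asymptotic null is in force; tail
  calibration at realistic $n$ is covered by the 500-gene type-I test.
* **Clipping.** Meta-analysis p-values are clipped into
  $[10^{-300}, 1 - 10^{-16}]$ before the normal-score transform (flagged when
  it fires); mixture eigenvalues below $10^{-10}\lambda_{\max}$ are dropped.

## Design decisions on open points

* **"Majority" missingness rule.** A gene is excluded when results are
  missing for *strictly more than half* the cohorts; exactly half present is
  kept (`ceil(K/2)` presence required).
* **One-sided Stouffer.** Aggregation p-values carry no direction, so
  $z_i = \Phi^{-1}(1-p_i)$ with $\sqrt{N}$ weights (raw sample size, not
  effective size; configurable input) is the only coherent combination.
* **BH total test count.** $m$ for the FDR step equals the number of genes
  passing the missingness filter in that meta-analysis. In the bundled
  published worked example the total count 17,960 is used; the source prints
  only "~18,500 genes", but the rank-1 row (q = p × m) pins m = 17,960
  exactly.
* **Genomic control.** Correction divides the 1-df chi-square quantile by
  $\lambda$ (the trigger being $\lambda_{1000}$); $\lambda < 1$ is never used
  to shrink p-values.
* **eQTL significance** is consumed as a boolean input column rather than
  re-derived from p-values, matching a pipeline that ingests pre-called
  significance.
* **Strand is ignored** for all interval overlap; elements and eQTLs are
  positional.
* **Multi-allelic sites** are distinct variant records per alt allele.

## Worked example

```{r example, eval = FALSE}
ex <- consortium_example()
q <- bh_fdr(ex$hits$p, m = ex$m_tests)
data.frame(gene = ex$hits$gene, p = ex$hits$p, q = signif(q, 3))
cohort_composition(ex$ancestry_counts)

## end-to-end synthetic study
specs <- list(
  eur1 = cohort_spec(seed = 11, n_samples = 240, n_genes = 12,
                     causal_genes = data.frame(gene = 3, effect = 0.9,
                                               frac_causal = 0.6)),
  eur2 = cohort_spec(seed = 23, n_samples = 240, n_genes = 12,
                     causal_genes = data.frame(gene = 3, effect = 0.9,
                                               frac_causal = 0.6))
)
pl <- run_pipeline(specs, agg_config(covariates = "age"))
head(pl$meta$all)
```

## Known limitations

* No effect sizes or directions are reported — the score-test architecture
  yields p-values only.
* Transcript-level resolution is out of scope; one interval model per gene.
* Variants mapping to several genes are tested in each of them, so
  neighboring genes' results are correlated and loci may contain several
  associated genes; the follow-up stage groups hits by region rather than
  adjudicating the causal gene.
* The LMM score test on a binary trait relies on asymptotics; at a few
  hundred samples, per-cohort inflation estimates ($\lambda_{1000}$) and
  genomic control are the guardrails, exactly as in the original design.
* The simulator draws variants independently within genes; power estimates on
  it will not transfer quantitatively to strongly LD-structured real data.
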