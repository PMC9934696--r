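# pgsdeviate

Most people's height or LDL cholesterol sits close to the value a
common-variant polygenic score predicts for them. The interesting ones are
those who don't: individuals whose measured phenotype deviates sharply from
their genetic prediction are enriched for rare large-effect mutations (e.g.
loss-of-function variants in growth-disorder or lipid genes) and for
environmental or clinical factors the score knows nothing about, making them
prime candidates for follow-up in biobank-scale studies.

`pgsdeviate` is an R package for finding and characterising these
individuals. It is aimed at statistical geneticists and epidemiologists
working with per-individual phenotype tables, GWAS summary-statistic weights
and genotype dosages (delimited text or VCF).

## The model

The polygenic score for individual *i* is the weighted allele-dosage sum

```
PS_i = sum_n beta_n * G_{n,i}
```

over the score variants, with `G` the dosage of the effect allele.
Scores are residualized on principal components and standardized
(mean 0, SD 1); phenotypes are residualized on covariates (age, sex,
assessment centre, ...) and standardized, optionally through a rank-based
inverse-normal transform for skewed traits. Under the additive polygenic
model the standardized pair `(PS, Y)` is bivariate normal with correlation
`rho = sqrt(R^2)`, where `R^2` is the variance explained, and the regression
slope of `Y` on `PS` equals `rho`.

Four classifiers flag individuals inconsistent with that null:

1. **Mahalanobis** (primary): squared distance of `(PS_i, Y_i)` from the
   bivariate mean under a covariance matrix estimated from a cohort
   *simulated* under the additive model at the observed `R^2`;
   `D^2 ~ chi^2(2 df)` gives an outlier p-value. Flagged individuals are
   retained only if the z-score of their residual from regressing `PS` on
   `Y` satisfies `|z| > 2` (discarding points that are extreme in both
   coordinates but consistent with the model); `p > 0.05` and `|z| < 1`
   defines the concordant reference group.
2. **Regression residual**: `|z| > k`, `k` = 2 or 3.
3. **GRS-rank empirical p**: the phenotype observed at score rank *k* is
   compared with the phenotypes at the same rank in 10,000 simulated
   cohorts; `p = (r + 1) / (n_reps + 1)` where `r` counts reference values at
   least as extreme.
4. **GRS-centile IQR fences** (non-parametric): within each score centile,
   Tukey fences at `Q1 - m*IQR` / `Q3 + m*IQR`, `m` = 1.5 or 3.

Deviators are split into `lower` / `higher` groups by the sign of the
standardized phenotype and compared with the concordant group by exact
(Fisher) odds ratios for binary traits and rare-variant carrier sets
(MAF < 0.001, high-confidence LoF), and by covariate-adjusted linear or
logistic regression for quantitative traits and disease outcomes.

## Worked example

```r
library(pgsdeviate)

# a height-like cohort: score explains 31.6% of phenotypic variance
sim <- simulate_cohort(n = 50000, n_variants = 3198, target_r2 = 0.316,
                       seed = 42, keep_genotypes = FALSE)
variance_explained(sim)
#> Polygenic score fit (n = 50000)
#>   slope (SD per SD): 0.5628 [0.5555, 0.5700]
#>   variance explained: 31.7%

# null covariance from an independent simulation at the same R^2
sigma <- estimate_null_covariance(
  simulate_cohort(2e5, 500, 0.316, seed = 43, keep_genotypes = FALSE))
round(unclass(sigma), 3)
#>           ps_std pheno_std
#> ps_std     1.000     0.562
#> pheno_std  0.562     1.000

# primary classifier at the lenient threshold
calls <- classify_mahalanobis(sim, sigma, p_threshold = 0.001)
summary(calls)
#> # A tibble: 1 × 7
#>   method          n n_lower n_higher n_deviators n_concordant n_indeterminate
#> 1 mahalanobis 50000       9       15          24        33524           16452
```

The slope of 0.56 SD per SD is `sqrt(0.316)`: a 1 SD higher score predicts a
0.56 SD taller person. The 24 flagged individuals (~0.05%) are the ones whose
height is statistically inconsistent with that prediction on this pure-null
cohort — the false-positive floor of the lenient threshold. `plot_deviators(calls, sim)`
draws the standard score-vs-phenotype scatter with flagged points
highlighted, and `make_fixture()` / `end_to_end_check()` generate cohorts
with planted deviators and rare-variant carriers to measure
sensitivity, false-discovery proportion and downstream carrier enrichment.

A command-line front-end covering every step is installed as
`exec/pgsdeviate` (subcommands `simulate`, `preprocess`, `score`,
`classify`, `enrich`, `make-fixtures`, `compare-methods`), writing
manifest-headed TSVs.

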