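---
title: "Detecting individuals who deviate from their polygenic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting individuals who deviate from their polygenic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgsdeviate)
```

## The problem and the model

A common-variant polygenic score summarises thousands of small additive
effects into a single genetic prediction of a quantitative trait. For a
well-powered score, the standardized score and the standardized phenotype
are approximately bivariate normal with correlation $\rho = \sqrt{R^2}$,
where $R^2$ is the variance explained. An individual far from this
bivariate ellipse — say 5 SD shorter than their score predicts — is
unlikely under the additive model and plausibly carries a rare large-effect
variant, a clinical condition, or an environmental exposure that the score
cannot see. `pgsdeviate` quantifies "far from the ellipse" four different
ways, because no single rule is uniformly best and the published evidence
shows their flagged sets overlap only partially.

All classifiers consume the same scored-cohort table: one row per
individual with a standardized score `ps_std` (PC-residualized, then
$\mu = 0, \sigma = 1$) and a standardized phenotype `pheno_std`
(residualized on covariates, then scaled; or rank-inverse-normalized for
skewed traits such as LDL cholesterol, optionally within each sex).

## The simulation engine

The Mahalanobis covariance and the GRS-rank reference both come from
cohorts simulated under the additive model. `simulate_cohort()` draws
allele frequencies $f_j \sim U(0.01, 0.5)$ (or takes observed ones),
dosages $G_{ij} \sim \mathrm{Binomial}(2, f_j)$ independently
(Hardy–Weinberg, no linkage disequilibrium), and effects
$\beta_j \sim N(0,1)$ rescaled by the *theoretical* genetic-value SD
$\sqrt{\sum_j \beta_j^2\, 2 f_j (1 - f_j)}$ so that the genetic value has
exactly unit variance in expectation. The phenotype is then
$\sqrt{R^2}\, g + \sqrt{1 - R^2}\, \varepsilon$. Deterministic rescaling
makes the variance decomposition exact rather than approximate, which is
strictly better for calibrating thresholds; it also keeps the score
well-defined at $R^2 = 0$ (the score is standardized anyway, so its scale
is immaterial).

Genotype matrices are kept only while `n * n_variants` stays below a
budget (default 2 million entries); beyond that only the genetic value is
retained, since every classifier needs just the (score, phenotype) pair.

`simulate_rank_reference()` builds the rank-matched null for the empirical
p-value method: each replicate simulates a cohort, ranks it by score, and
stores the phenotypes in score-rank order. Simulating thousands of
variants per replicate for 10,000 replicates is prohibitively slow, and
unnecessary: by the central limit theorem a score summing thousands of
independent variants is normal to far better accuracy than any downstream
test can resolve. The default therefore draws each replicate directly from
the implied bivariate normal with correlation $\sqrt{R^2}$
(`method = "gaussian"`); `method = "genotype"` performs the literal
per-variant simulation, and the test suite checks the two agree
distributionally at small scale. The reference is a dense
`n_reps x n` matrix: 10,000 replicates at $n = 10^4$ is 0.8 GB, which is
the scale the package targets; at $n \ge 10^5$ reduce `n_reps` or
classify a subsample — the per-rank median the extremeness rule needs
(see below) rules out a fully streamed implementation.

## Classifier details and numerical choices

**Mahalanobis (primary).** $D^2 = (x - \mu)^\top \Sigma^{-1} (x - \mu)$
with $\mu$ the sample means of the observed standardized pair and
$\Sigma$ the simulated covariance; $p$-values from the survival function
of $\chi^2_2$ (so $p = e^{-D^2/2}$ when $\Sigma = I$). Default threshold
$p < 0.001$; the stringent alternative is the Bonferroni bound
$p < 0.05/n$ with $n$ the number of individuals actually entering
classification in that stratum. A flagged individual is kept only when the
regression-residual $|z| > 2$ (next paragraph), because a point can have a
large $D^2$ with an extreme score *and* a matching extreme phenotype —
exactly what the additive model predicts. Concordant ("aligned")
individuals — the reference group for all enrichment testing — need
$p > 0.05$ *and* $|z| < 1$; both cut-offs are arguments.

**Regression residual.** The published orientation regresses the *score on
the phenotype*; $z$ is that residual divided by its sample SD, and
$|z| > k$ ($k = 2$ or $3$) flags deviators. This orientation has a real
consequence: a pure phenotype displacement $\delta$ (score untouched)
shifts $z$ by only $\rho\,\delta / \sqrt{1-\rho^2}$, not
$\delta / \sqrt{1-\rho^2}$. At $R^2 = 0.316$ and $\delta = 4$ SD the shift
is $\approx 2.7$, so the power of $|z|>2$ is only about
$\Phi(0.7) \approx 0.76$ — and lower still once re-standardization
shrinks the displacement (below). The phenotype-direct methods (GRS-rank,
GRS-centile) do not pay this penalty; the package's recovery tests
quantify the difference.

**GRS-rank.** Individuals are sorted by score (ties broken by id for
determinism); the phenotype at rank $k$ is compared against reference
column $k$. "As extreme" is made precise as distance from the per-rank
reference *median*: $r = \#\{\,|x_{\mathrm{ref}} - \tilde{x}| \ge
|x_{\mathrm{obs}} - \tilde{x}|\,\}$, a rank-local, two-sided and
symmetric rule, and $p = (r+1)/(n_{\mathrm{reps}}+1)$ — the add-one form
keeps $p \ge 1/(n_{\mathrm{reps}}+1)$ and never 0. Flag at
$p < \alpha$ with $\alpha = 0.001$ (lenient) or $1/n_{\mathrm{reps}}$
(stringent). The replicate count matters at the lenient threshold: with
2,000 replicates the decision rides on the one or two most extreme
reference values per rank, which costs real power relative to the
published 10,000.

**GRS-centile.** Individuals are binned into 100 score-quantile bins by
rank (stable id tie-break); within each bin Q1 and Q3 use the common
type-7 (linear interpolation) definition, and values strictly outside
$[Q1 - m\,\mathrm{IQR},\; Q3 + m\,\mathrm{IQR}]$ are flagged. For a
normal phenotype the $m = 1.5$ fences sit at $\pm 2.698\sigma$, an
expected flag rate of $2\Phi(-2.698) = 0.70\%$, inflated a few relative
percent by quartile estimation noise at ~1,000 individuals per bin. A
zero-IQR bin collapses its fences to $[Q1, Q3]$, so a constant bin flags
nothing.

Direction is always the sign of the standardized phenotype (`lower` /
`higher`); an exact 0 cannot be directed and is labelled indeterminate
with a warning. Negating both axes leaves every p-value unchanged and
swaps the direction labels, which the suite checks as a property.

## Preprocessing choices

Residualization is ordinary least squares on the covariate columns plus an
intercept; factors expand to indicators, constant columns are dropped, and
a rank-deficient design is an error naming the collinear columns.
Residuals are scaled by the $n-1$ SD. The rank-inverse-normal transform
uses Blom fractions $(k - 3/8)/(n + 1/4)$ with average ranks for ties —
the convention in statistical genetics — and the result is rescaled to SD
exactly 1 (raw Blom quantiles have SD slightly below 1 at finite $n$).
Medication adjustment (e.g. statins for LDL-C) enters as an ordinary
binary covariate. Principal components adjust the *score* by default, not
the phenotype; both are just covariate lists, so either choice is a
one-line config change. Sex-stratified runs transform and classify each
stratum independently, with stratum-specific covariance and Bonferroni
$n$.

## Scoring choices

Variants are matched between weights and genotypes by id; when the
genotype source records the other allele the dosage is reflected as
$2 - d$. Strand-ambiguous (A/T, C/G) variants are kept with a warning
count, since a weights table without positions cannot resolve strand.
Missing dosages are skipped without rescaling — rescaling would silently
change the score variance — and individuals missing more than 5% of
weight variants are flagged. Unmatched variants go to a reconciliation
report; only a zero-variant overlap is an error.

## Enrichment choices

The reference group is the *concordant* set, not "everyone unflagged":
indeterminate individuals (moderate $p$ or moderate $|z|$) belong to
neither tail and would dilute both. Binary traits and carrier sets use
`fisher.test`: conditional-MLE odds ratio, exact CI and p-value (the
sample cross-product OR is reported alongside; with a zero cell the exact
CI still yields a finite bound on one side). Quantitative outcomes are
rank-inverse-normalized, so linear-model effects are in SD units;
logistic effects are reported as odds ratios with Wald CIs. No
multiple-testing correction is applied by default — single nominal
p-values mirror how such follow-up batteries are reported — but a
Bonferroni column is emitted. Carrier status requires dosage $\ge 1$
(rounded) at a variant in the gene set with the required consequence
class and annotation MAF strictly below the threshold (default 0.001);
MAF comes from the annotation table, which in practice derives from a
larger reference panel than the analysis cohort.

## The synthetic fixture and what it shows

`make_fixture()` plants a known fraction of deviators (default 1% at
$\pm 4$ SD from their conditional expectation $\rho \cdot ps$), assigns
each a mechanism (`rare_variant` carriers get a qualifying rare LoF
allele in a designated gene with weight 0 in the score; `environment`
deviators get displacement only), draws binary traits with elevated odds
among the planted, and reconstructs a raw phenotype from age/sex/centre
effects so the preprocessing step is exercised. Planted displacements are
*not* re-standardized inside the fixture, keeping them in interpretable SD
units; but any downstream pipeline standardizes, and planting a fraction
$q$ at $d$ SD inflates the scale by $\sqrt{1 + q d^2}$ (7.7% at the
defaults), shrinking the effective displacement to ~3.7 SD. The recovery
tests account for this exactly.

The fixture emulates the statistical structure that matters to the
classifiers — the score–phenotype correlation, rare-carrier enrichment,
trait prevalence differences — and deliberately omits linkage
disequilibrium, relatedness, population structure and ascertainment.
Passing recovery tests therefore demonstrates the statistical machinery,
not robustness to confounding in real cohorts; PC adjustment and unrelated
subsets remain the user's responsibility, as in any biobank analysis.

## Problem sizes and runtime

The package's own checks run at desk scale, chosen to keep Monte-Carlo
error well below the assertion tolerances: slope recovery at
$n = 50{,}000$ (3 MC SEs $\approx 0.011$ on a slope of 0.562), null
calibration at $n = 10^5$ with a $5 \times 10^5$ covariance simulation,
the 10,000-replicate rank reference at $n = 10^4$, and planted-deviator
recovery at $n = 20{,}000$. Full-cohort sizes (~159,000) change nothing
statistically; only the rank-reference memory grows as noted above.

## Known limitations

* No optimal Mahalanobis threshold exists; 0.001 vs Bonferroni can change
  the flagged count by an order of magnitude, which is why four methods
  and two thresholds each are exposed.
* The score-on-phenotype residual orientation caps the power of the
  z-based rules against pure phenotype displacement (see above); with a
  strong score the phenotype-direct methods recover 4 SD deviators with
  sensitivity above 0.9 while the z-based rules plateau near
  $\Phi(\rho\,\delta/\sqrt{1-\rho^2} - 2)$.
* The lenient regression rule ($k = 2$) flags ~4.6% of null individuals;
  with ~1% true deviators its false-discovery proportion cannot drop
  below ~0.8 regardless of sensitivity. It is useful as a sensitivity
  analysis, not as a primary screen.
* Multi-allelic VCF records, BGEN/PLINK binaries, imputation and LD-aware
  weight re-estimation are out of scope; weights are an opaque input.
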