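#' Simulate a cohort under the additive polygenic model
#'
#' Draws per-variant allele frequencies and effect sizes, genotype dosages in
#' Hardy-Weinberg equilibrium (`Binomial(2, f)` per variant, no linkage
#' disequilibrium), and phenotypes in which the genetic value explains a fixed
#' fraction `target_r2` of the variance, with independent Gaussian noise making
#' up the rest. Effects are rescaled deterministically against the theoretical
#' genetic-value variance (`sum(beta^2 * 2 f (1-f))`), so the variance
#' decomposition holds exactly in expectation rather than approximately.
#'
#' The returned score and phenotype are each standardized to mean 0, SD 1, so
#' the population regression slope of phenotype on score equals
#' `sqrt(target_r2)`.
#'
#' @param n Number of individuals (>= 2).
#' @param n_variants Number of independent variants contributing to the score.
#' @param target_r2 Fraction of phenotypic variance explained by the score,
#'   in `[0, 1)`.
#' @param freqs Optional vector of effect-allele frequencies in `(0, 0.5]`,
#'   length `n_variants` (e.g. observed frequencies to match a real panel).
#'   Default: independent `Uniform(0.01, 0.5)` draws.
#' @param seed Integer seed; the same `(n, n_variants, target_r2, seed)` gives
#'   a bit-identical cohort.
#' @param keep_genotypes Keep the integer dosage matrix as an attribute?
#'   Default: only when `n * n_variants <= 2e6`; the classifiers need only the
#'   (score, phenotype) pair.
#' @param block_size Variants simulated per block (memory/speed trade-off).
#'
#' @return A tibble of class `sim_cohort` with columns `id`, `ps_raw`,
#'   `ps_std`, `pheno_std`, and attributes `target_r2`, `freqs`, `betas`
#'   (effect sizes on the unit-variance phenotype scale), `seed`, and
#'   optionally `dosages` (n x m integer matrix, individuals x variants).
#' @examples
#' sim <- simulate_cohort(2000, n_variants = 100, target_r2 = 0.316, seed = 1)
#' cor(sim$ps_std, sim$pheno_std)^2  # close to 0.316
#' @export
simulate_cohort <- function(n, n_variants = 1000, target_r2 = 0.316,
                            freqs = NULL, seed = NULL,
                            keep_genotypes = NULL, block_size = 250L) {
  if (n < 2) abort("`n` must be >= 2.")
  if (n_variants < 1) abort("`n_variants` must be >= 1.")
  if (target_r2 < 0 || target_r2 >= 1) abort("`target_r2` must be in [0, 1).")
  if (!is.null(freqs)) {
    if (length(freqs) != n_variants) {
      abort("`freqs` must have length `n_variants`.")
    }
    if (any(freqs <= 0 | freqs > 0.5)) abort("`freqs` must lie in (0, 0.5].")
  }
  n <- as.integer(n); m <- as.integer(n_variants)
  keep_genotypes <- keep_genotypes %||% (as.double(n) * m <= 2e6)

  with_seed_if(seed, {
    f <- freqs %||% runif(m, 0.01, 0.5)
    beta0 <- rnorm(m)
    # scale effects so the theoretical genetic value has unit variance;
    # the phenotype then mixes sqrt(r2) genetic + sqrt(1-r2) noise exactly
    g_sd <- sqrt(sum(beta0^2 * 2 * f * (1 - f)))
    beta_unit <- beta0 / g_sd

    g <- numeric(n)
    dos <- if (keep_genotypes) matrix(0L, n, m) else NULL
    for (start in seq(1L, m, by = block_size)) {
      idx <- start:min(start + block_size - 1L, m)
      block <- matrix(rbinom(n * length(idx), 2L, rep(f[idx], each = n)),
                      nrow = n)
      g <- g + drop(block %*% beta_unit[idx])
      if (keep_genotypes) dos[, idx] <- block
    }
    g_centred <- g - sum(beta_unit * 2 * f)
    noise <- rnorm(n, sd = sqrt(1 - target_r2))
    pheno <- sqrt(target_r2) * g_centred + noise

    out <- tibble::tibble(
      id = paste0("sim_", seq_len(n)),
      ps_raw = g,
      ps_std = std1(g),
      pheno_std = std1(pheno)
    )
    attr(out, "target_r2") <- target_r2
    attr(out, "freqs") <- f
    attr(out, "betas") <- sqrt(target_r2) * beta_unit
    attr(out, "seed") <- seed
    if (keep_genotypes) {
      dimnames(dos) <- list(out$id, paste0("var_", seq_len(m)))
      attr(out, "dosages") <- dos
    }
    class(out) <- c("sim_cohort", class(out))
    out
  })
}

#' Null covariance of the standardized (score, phenotype) pair
#'
#' Sample 2x2 covariance matrix of `(ps_std, pheno_std)` from a simulated (or
#' observed) cohort. Under the additive model its off-diagonal converges to
#' `sqrt(target_r2)`; it is the plug-in covariance for the Mahalanobis
#' classifier.
#'
#' @param data A data frame with `ps_std` and `pheno_std` columns, typically a
#'   [simulate_cohort()] result.
#' @param source Label recording where the covariance came from.
#' @return A 2x2 matrix of class `null_covariance` with a `source` attribute.
#' @export
estimate_null_covariance <- function(data, source = "simulated") {
  if (nrow(data) < 10) abort("Need at least 10 individuals to estimate the covariance.")
  if (!all(c("ps_std", "pheno_std") %in% names(data))) {
    abort("`data` must contain `ps_std` and `pheno_std` columns.")
  }
  sigma <- cov(cbind(ps_std = data$ps_std, pheno_std = data$pheno_std))
  if (det(sigma) <= 0) abort("Estimated covariance is singular.")
  structure(sigma, class = c("null_covariance", class(sigma)), source = source)
}

#' Rank-matched null reference for the empirical p-value classifier
#'
#' Builds the reference distribution behind the GRS-rank method: in each
#' replicate a cohort of `n` individuals is simulated under the additive model
#' at `target_r2`, scores are ranked, and the phenotypes are stored in score
#' rank order. Row `r` of the result holds replicate `r`'s standardized
#' phenotypes ordered by that replicate's score rank; column `k` is then the
#' null distribution of the phenotype observed at score rank `k`.
#'
#' With thousands of independent variants the score and genetic value are
#' normal to high accuracy, so the default `method = "gaussian"` draws each
#' replicate's (score, phenotype) pair directly from the implied bivariate
#' normal with correlation `sqrt(target_r2)` — orders of magnitude faster and
#' distributionally equivalent at GWAS variant counts. `method = "genotype"`
#' performs the literal per-variant genotype simulation and is practical only
#' for small `n_reps * n_variants`.
#'
#' @param n Cohort size each replicate (must match the cohort to be classified).
#' @param n_reps Number of replicates (the published protocol uses 10,000).
#' @param target_r2 Variance explained by the score.
#' @param method `"gaussian"` (default) or `"genotype"`.
#' @param n_variants,freqs Passed to [simulate_cohort()] when
#'   `method = "genotype"`.
#' @param seed Integer seed (keep independent of the cohort seed).
#' @param chunk Replicates generated per memory chunk (gaussian method).
#' @return An `n_reps` x `n` matrix of class `rank_reference` with attributes
#'   `n`, `n_reps`, `target_r2`, `method`, `seed`. Each row is standardized
#'   (mean 0, SD 1), matching the preprocessing of an observed cohort.
#' @export
simulate_rank_reference <- function(n, n_reps = 10000, target_r2 = 0.316,
                                    method = c("gaussian", "genotype"),
                                    n_variants = 1000, freqs = NULL,
                                    seed = NULL, chunk = 200L) {
  method <- match.arg(method)
  if (n_reps < 1) abort("`n_reps` must be >= 1.")
  n <- as.integer(n); n_reps <- as.integer(n_reps)
  rho <- sqrt(target_r2)

  ref <- with_seed_if(seed, {
    out <- matrix(0, nrow = n_reps, ncol = n)
    if (method == "gaussian") {
      for (start in seq(1L, n_reps, by = chunk)) {
        rows <- start:min(start + chunk - 1L, n_reps)
        ps <- matrix(rnorm(length(rows) * n), nrow = length(rows))
        ph <- rho * ps + sqrt(1 - target_r2) *
          matrix(rnorm(length(rows) * n), nrow = length(rows))
        for (j in seq_along(rows)) {
          row <- ph[j, order(ps[j, ])]
          out[rows[j], ] <- (row - mean(row)) / sd(row)
        }
      }
    } else {
      for (r in seq_len(n_reps)) {
        sim <- simulate_cohort(n, n_variants = n_variants,
                               target_r2 = target_r2, freqs = freqs,
                               keep_genotypes = FALSE)
        out[r, ] <- sim$pheno_std[order(sim$ps_std)]
      }
    }
    out
  })
  structure(ref, class = c("rank_reference", class(ref)),
            n = n, n_reps = n_reps, target_r2 = target_r2,
            method = method, seed = seed)
}

#' @exportS3Method base::print
print.sim_cohort <- function(x, ...) {
  cat(sprintf("# Simulated additive-model cohort: n = %d, target R^2 = %.3f\n",
              nrow(x), attr(x, "target_r2")))
  NextMethod()
}
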