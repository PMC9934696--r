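#' Compute raw polygenic scores from weights and dosages
#'
#' For each individual, sums `beta * dosage-of-effect-allele` over the variants
#' shared between the weights table and the genotype matrix. Variants are
#' matched on `variant_id`; where the genotype matrix counts the weights
#' table's *other* allele, the dosage is reflected as `2 - d` before scoring.
#' Variants present in the weights but absent from the genotypes (or vice
#' versa) are recorded in a reconciliation report, not an error — unless no
#' variant overlaps at all.
#'
#' Missing dosages are skipped (no imputation): the score is the sum over an
#' individual's non-missing reconciled variants, and `n_variants_used` records
#' how many contributed. Individuals missing more than `flag_missing_gt` of
#' the weight variants are flagged.
#'
#' @param genotypes A `genotype_matrix` from [read_genotypes()], or any list
#'   with elements `dosages` (individuals x variants, dimnames set) and
#'   `effect_allele` (named per-variant allele the dosage counts).
#' @param weights A weights tibble from [read_weights()] (columns
#'   `variant_id`, `effect_allele`, `other_allele`, `beta`).
#' @param flag_missing_gt Fraction of weight variants above which an
#'   individual's missingness is flagged.
#' @return Tibble with columns `id`, `ps_raw`, `n_variants_used`,
#'   `high_missingness`; attributes `reconciliation` (tibble of per-variant
#'   dispositions) and `n_ambiguous` (strand-ambiguous A/T, C/G variants kept
#'   with a warning).
#' @export
compute_polygenic_score <- function(genotypes, weights, flag_missing_gt = 0.05) {
  dos <- genotypes$dosages
  eff <- genotypes$effect_allele
  if (is.null(dos) || is.null(rownames(dos)) || is.null(colnames(dos))) {
    abort("`genotypes` must carry a dosage matrix with row (individual) and column (variant) names.")
  }

  recon <- dplyr::full_join(
    tibble::tibble(variant_id = weights$variant_id,
                   w_effect = weights$effect_allele,
                   w_other = weights$other_allele,
                   beta = weights$beta),
    tibble::tibble(variant_id = colnames(dos),
                   g_effect = unname(eff[colnames(dos)]),
                   in_genotypes = TRUE),
    by = "variant_id"
  )
  recon <- dplyr::mutate(
    recon,
    status = dplyr::case_when(
      is.na(.data$in_genotypes) ~ "missing_from_genotypes",
      is.na(.data$beta) ~ "missing_from_weights",
      # orientation not recorded in the genotype source (plain TSV):
      # assume the weights' effect-allele orientation
      is.na(.data$g_effect) ~ "matched_assumed",
      .data$g_effect == .data$w_effect ~ "matched",
      .data$g_effect == .data$w_other ~ "flipped",
      TRUE ~ "allele_mismatch"
    )
  )
  used <- dplyr::filter(recon,
                        .data$status %in% c("matched", "matched_assumed",
                                            "flipped"))
  if (nrow(used) == 0) {
    abort(paste0(
      "No variant shared between weights and genotypes after allele reconciliation.\n",
      "Reconciliation: ",
      paste(utils::capture.output(print(table(recon$status))), collapse = "\n")
    ))
  }
  ambiguous <- is_strand_ambiguous(used$w_effect, used$w_other)
  if (any(ambiguous)) {
    warn(sprintf("%d strand-ambiguous (A/T or C/G) variant(s) kept as-is.",
                 sum(ambiguous)))
  }

  d <- dos[, used$variant_id, drop = FALSE]
  flip <- used$status == "flipped"
  if (any(flip)) {
    d[, flip] <- 2 - d[, flip]
  }
  beta <- used$beta
  miss <- is.na(d)
  d0 <- ifelse(miss, 0, d)
  ps <- unname(drop(d0 %*% beta))
  n_used <- ncol(d) - unname(rowSums(miss))
  miss_frac <- 1 - n_used / nrow(weights)

  out <- tibble::tibble(
    id = rownames(dos),
    ps_raw = ps,
    n_variants_used = as.integer(n_used),
    high_missingness = unname(miss_frac > flag_missing_gt)
  )
  attr(out, "reconciliation") <- tibble::as_tibble(recon)
  attr(out, "n_ambiguous") <- sum(ambiguous)
  out
}

is_strand_ambiguous <- function(a1, a2) {
  p <- paste0(toupper(a1), toupper(a2))
  p %in% c("AT", "TA", "CG", "GC")
}

#' Ancestry-adjust and standardize polygenic scores
#'
#' Residualizes raw scores on principal-component columns (plus an intercept)
#' to remove ancestry gradients, then standardizes the residuals to mean 0,
#' SD 1. With no PC columns (or all-constant ones) this reduces to a plain
#' z-score of the raw scores.
#'
#' @param data Data frame with `id`, a raw-score column, and any PC columns.
#' @param score_col Name of the raw score column.
#' @param pc_cols Character vector of principal-component column names (may be
#'   empty).
#' @return `data` with a `ps_std` column appended (tibble).
#' @export
pc_adjust_and_standardize <- function(data, score_col = "ps_raw",
                                      pc_cols = character()) {
  if (!score_col %in% names(data)) {
    abort(paste0("Score column `", score_col, "` not found."))
  }
  if (!"id" %in% names(data)) {
    abort("`data` must contain an `id` column.")
  }
  res <- residualize_standardize(data, phenotype = score_col,
                                 covariates = pc_cols)
  if (nrow(res) != nrow(data)) {
    abort("Missing values in scores or PCs; remove them before adjustment.")
  }
  dplyr::mutate(tibble::as_tibble(data), ps_std = res$pheno_std)
}

#' Variance in the phenotype explained by the score
#'
#' Ordinary least squares of the standardized phenotype on the standardized
#' score. For a standardized pair the slope equals the Pearson correlation,
#' and `r_squared = slope^2` is the variance explained.
#'
#' @param data Data frame with `ps_std` and `pheno_std` columns (and `id`).
#' @param conf_level Confidence level for the Wald interval on the slope.
#' @return An object of class `pgs_fit` (list with the underlying `lm` fit,
#'   `slope`, `ci_low`, `ci_high`, `r_squared`, `n`). Use [tidy()] /
#'   [glance()] to extract tibbles.
#' @examples
#' sim <- simulate_cohort(5000, 100, 0.316, seed = 42)
#' glance(variance_explained(sim))
#' @export
variance_explained <- function(data, conf_level = 0.95) {
  if (!all(c("ps_std", "pheno_std") %in% names(data))) {
    abort("`data` must contain `ps_std` and `pheno_std` columns.")
  }
  if (nrow(data) < 3) abort("Need at least 3 paired observations.")
  fit <- lm(pheno_std ~ ps_std, data = data)
  slope <- unname(coef(fit)[2])
  n <- nrow(data)
  sxx <- sum((data$ps_std - mean(data$ps_std))^2)
  se <- sqrt(sum(resid(fit)^2) / (n - 2) / sxx)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(fit = fit, slope = slope, se = se,
         ci_low = slope - zq * se, ci_high = slope + zq * se,
         r_squared = slope^2, n = nrow(data), conf_level = conf_level),
    class = "pgs_fit"
  )
}

#' @exportS3Method base::print
print.pgs_fit <- function(x, ...) {
  cat(sprintf(
    "Polygenic score fit (n = %d)\n  slope (SD per SD): %.4f [%.4f, %.4f]\n  variance explained: %.1f%%\n",
    x$n, x$slope, x$ci_low, x$ci_high, 100 * x$r_squared))
  invisible(x)
}

#' @rdname variance_explained
#' @param x A `pgs_fit` object.
#' @param ... Unused.
#' @export
tidy.pgs_fit <- function(x, ...) {
  tibble::tibble(
    term = "ps_std", estimate = x$slope, std.error = x$se,
    conf.low = x$ci_low, conf.high = x$ci_high,
    p.value = 2 * pnorm(-abs(x$slope / x$se))
  )
}

#' @rdname variance_explained
#' @export
glance.pgs_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, slope = x$slope, nobs = x$n)
}
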