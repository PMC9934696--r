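#' Mahalanobis distances and chi-squared p-values for (score, phenotype) pairs
#'
#' Squared Mahalanobis distance of each individual's standardized
#' (score, phenotype) point from the sample mean of the pair, using a supplied
#' covariance matrix (normally estimated from a cohort simulated under the
#' additive model, so that the null reflects the expected score-phenotype
#' correlation). Under bivariate normality the squared distance follows a
#' chi-squared distribution with 2 degrees of freedom, giving a per-individual
#' outlier p-value.
#'
#' @param data Scored cohort: data frame with `id`, `ps_std`, `pheno_std`.
#' @param covariance 2x2 positive-definite covariance over
#'   `(ps_std, pheno_std)`, e.g. from [estimate_null_covariance()].
#' @return Tibble with `id`, `d2`, `p_value`.
#' @examples
#' sim <- simulate_cohort(1000, 50, 0.3, seed = 1)
#' sigma <- estimate_null_covariance(sim)
#' head(mahalanobis_pvalues(sim, sigma))
#' @export
mahalanobis_pvalues <- function(data, covariance) {
  check_scored(data)
  covariance <- unclass(covariance)
  if (!is.matrix(covariance) || any(dim(covariance) != 2)) {
    abort("`covariance` must be a 2x2 matrix.")
  }
  if (det(covariance) <= 0 || covariance[1, 1] <= 0) {
    abort("`covariance` must be positive definite.")
  }
  x <- cbind(data$ps_std, data$pheno_std)
  d2 <- stats::mahalanobis(x, center = colMeans(x), cov = covariance)
  tibble::tibble(id = data$id, d2 = d2,
                 p_value = pchisq(d2, df = 2, lower.tail = FALSE))
}

#' Residual z-scores from regressing the score on the phenotype
#'
#' Fits `ps_std ~ pheno_std` by least squares and returns the residuals
#' divided by their sample SD. Note the orientation: the *score* is the
#' response. A large |z| means the individual's score is far from what their
#' phenotype predicts, i.e. phenotype and score disagree; individuals at the
#' extremes of both (consistent with the additive model) keep small |z|.
#'
#' @inheritParams mahalanobis_pvalues
#' @return Tibble with `id`, `residual_z`.
#' @export
residual_z <- function(data) {
  check_scored(data)
  if (nrow(data) < 3) abort("Need at least 3 individuals.")
  b <- cov(data$ps_std, data$pheno_std) / var(data$pheno_std)
  a <- mean(data$ps_std) - b * mean(data$pheno_std)
  res <- data$ps_std - a - b * data$pheno_std
  s <- sd(res)
  if (!is.finite(s) || s == 0) {
    abort("Regression residuals have zero variance (score and phenotype perfectly correlated); z is undefined.")
  }
  tibble::tibble(id = data$id, residual_z = res / s)
}

new_classification <- function(id, method, statistic, p_value, residual_z,
                               label, threshold_spec) {
  out <- tibble::tibble(
    id = id, method = method, statistic = statistic,
    p_value = p_value, residual_z = residual_z,
    label = factor(label, levels = c("lower", "concordant", "higher",
                                     "indeterminate"))
  )
  attr(out, "threshold_spec") <- threshold_spec
  class(out) <- c("pgs_classification", class(out))
  out
}

#' Assign a deviation direction from the phenotype sign
#'
#' Flagged individuals are split by whether their standardized phenotype lies
#' below the mean (`lower`; e.g. shorter than predicted) or above it
#' (`higher`). A phenotype exactly at 0 cannot be directed and is labelled
#' `indeterminate` with a warning.
#'
#' @param flagged Logical vector: is the individual a deviator?
#' @param pheno_std Standardized phenotype vector, same length.
#' @param otherwise Label for non-flagged individuals (default
#'   `"concordant"`).
#' @return Character vector of labels.
#' @export
assign_direction <- function(flagged, pheno_std, otherwise = "concordant") {
  if (length(flagged) != length(pheno_std)) {
    abort("`flagged` and `pheno_std` must have the same length.")
  }
  lab <- rep(otherwise, length(flagged))
  lab[flagged & pheno_std < 0] <- "lower"
  lab[flagged & pheno_std > 0] <- "higher"
  on_zero <- flagged & pheno_std == 0
  if (any(on_zero)) {
    warn(sprintf("%d flagged individual(s) with phenotype exactly 0: direction indeterminate.",
                 sum(on_zero)))
    lab[on_zero] <- "indeterminate"
  }
  lab
}

#' Primary classifier: Mahalanobis distance with residual-z retention
#'
#' The primary deviator definition: an individual deviates from their
#' polygenic prediction when their Mahalanobis outlier p-value falls below
#' `p_threshold` *and* their residual z (from regressing the score on the
#' phenotype) satisfies `|z| > z_retain`. The second condition discards
#' individuals with an extreme score *and* matching extreme phenotype, which
#' are outliers in distance but consistent with the additive model.
#' Individuals with `p > 0.05` and `|z| < z_concordant` are labelled
#' `concordant` (the reference group for enrichment); everyone else is
#' `indeterminate`.
#'
#' @inheritParams mahalanobis_pvalues
#' @param p_threshold Mahalanobis p-value threshold (default 0.001).
#' @param z_retain Retain flagged individuals only when `|z|` exceeds this
#'   (default 2). Set to 0 to disable retention.
#' @param z_concordant Concordant individuals need `|z|` below this (default
#'   1); set to `Inf` to use the p-value condition alone.
#' @param bonferroni If `TRUE`, override `p_threshold` with `0.05 / n`, `n`
#'   the number of individuals entering classification.
#' @return A `pgs_classification` tibble: `id`, `method`, `statistic` (the
#'   squared distance), `p_value`, `residual_z`, `label`.
#' @examples
#' sim <- simulate_cohort(5000, 100, 0.316, seed = 7)
#' sigma <- estimate_null_covariance(simulate_cohort(5e4, 100, 0.316, seed = 8))
#' table(classify_mahalanobis(sim, sigma)$label)
#' @export
classify_mahalanobis <- function(data, covariance, p_threshold = 0.001,
                                 z_retain = 2, z_concordant = 1,
                                 bonferroni = FALSE) {
  check_scored(data)
  if (bonferroni) p_threshold <- 0.05 / nrow(data)
  if (p_threshold <= 0 || p_threshold >= 1) {
    abort("`p_threshold` must be in (0, 1).")
  }
  if (z_retain < z_concordant && is.finite(z_concordant)) {
    abort("`z_retain` must be >= `z_concordant`.")
  }
  mp <- mahalanobis_pvalues(data, covariance)
  z <- residual_z(data)$residual_z
  dev <- mp$p_value < p_threshold & abs(z) > z_retain
  conc <- !dev & mp$p_value > 0.05 & abs(z) < z_concordant
  lab <- assign_direction(dev, data$pheno_std, otherwise = "indeterminate")
  lab[conc] <- "concordant"
  new_classification(
    data$id, "mahalanobis", mp$d2, mp$p_value, z, lab,
    list(p_threshold = p_threshold, z_retain = z_retain,
         z_concordant = z_concordant, bonferroni = bonferroni)
  )
}

#' Classifier: regression-residual z threshold
#'
#' Flags individuals whose residual z from the score-on-phenotype regression
#' exceeds `k` in absolute value (`k` = 2 or 3 in the published protocol).
#'
#' @inheritParams mahalanobis_pvalues
#' @param k Absolute z threshold.
#' @return A `pgs_classification` tibble (`statistic` = z; no p-value).
#' @export
classify_regression_residual <- function(data, k = 2) {
  check_scored(data)
  if (k <= 0) abort("`k` must be positive.")
  z <- residual_z(data)$residual_z
  dev <- abs(z) > k
  lab <- assign_direction(dev, data$pheno_std)
  new_classification(data$id, "regression_residual", z, NA_real_, z, lab,
                     list(k = k))
}

#' Classifier: rank-matched empirical p-values (GRS-rank method)
#'
#' Individuals are ranked by their standardized score; the phenotype observed
#' at score rank `k` is compared with the reference distribution of simulated
#' phenotypes at the same simulated score rank (see
#' [simulate_rank_reference()]). Extremeness is two-sided, measured as
#' distance from the per-rank reference median: with `r` the number of the
#' `n_reps` reference values at least as extreme as the observation, the
#' empirical p-value is `(r + 1) / (n_reps + 1)` — e.g. `(r + 1) / 10001`
#' with the published 10,000 replicates.
#'
#' @inheritParams mahalanobis_pvalues
#' @param reference A `rank_reference` matrix built with the same `n` and
#'   `target_r2` as the cohort.
#' @param alpha Flagging threshold on the empirical p-value (default 0.001;
#'   the stringent alternative is `1 / n_reps`).
#' @return A `pgs_classification` tibble (`statistic` = `r`, the extremeness
#'   count).
#' @export
classify_grs_rank <- function(data, reference, alpha = 0.001) {
  check_scored(data)
  if (!inherits(reference, "rank_reference")) {
    abort("`reference` must come from simulate_rank_reference().")
  }
  n <- nrow(data)
  if (attr(reference, "n") != n) {
    abort(sprintf("Reference was built for n = %d but the cohort has n = %d.",
                  attr(reference, "n"), n))
  }
  n_reps <- attr(reference, "n_reps")
  if (alpha <= 0 || alpha > 1) abort("`alpha` must be in (0, 1].")

  ord <- order(data$ps_std, data$id)  # stable tie-break on id
  obs <- data$pheno_std[ord]
  r <- integer(n)
  for (k in seq_len(n)) {
    col <- reference[, k]
    med <- median(col)
    r[k] <- sum(abs(col - med) >= abs(obs[k] - med))
  }
  p <- (r + 1) / (n_reps + 1)
  dev <- p < alpha
  lab <- assign_direction(dev, obs)

  inv <- integer(n); inv[ord] <- seq_len(n)
  new_classification(data$id, "grs_rank",
                     as.numeric(r)[inv], p[inv], NA_real_, lab[inv],
                     list(alpha = alpha, n_reps = n_reps))
}

#' Classifier: IQR fences within score centiles (GRS-centile method)
#'
#' A non-parametric rule: individuals are binned into `n_bins` score-quantile
#' bins (centiles by default); within each bin the first and third quartiles
#' of the standardized phenotype define Tukey fences at
#' `Q1 - m*IQR` and `Q3 + m*IQR`, and individuals strictly outside are
#' flagged. Quartiles use linear interpolation (type 7); bins are formed by
#' score rank with ties broken by id order. A zero-IQR bin collapses its
#' fences to `[Q1, Q3]`.
#'
#' @inheritParams mahalanobis_pvalues
#' @param iqr_multiplier Fence multiplier `m` (1.5 or 3 in the published
#'   protocol).
#' @param n_bins Number of score-quantile bins (default 100).
#' @return A `pgs_classification` tibble (`statistic` = distance beyond the
#'   nearer fence, positive when outside; no p-value).
#' @export
classify_grs_centile <- function(data, iqr_multiplier = 1.5, n_bins = 100) {
  check_scored(data)
  if (iqr_multiplier <= 0) abort("`iqr_multiplier` must be positive.")
  n <- nrow(data)
  if (n < n_bins) {
    warn(sprintf("Fewer individuals (%d) than bins (%d); bins will be sparse.",
                 n, n_bins))
  }
  ord <- order(data$ps_std, data$id)
  bin <- integer(n)
  bin[ord] <- dplyr::ntile(seq_len(n), n_bins)

  df <- tibble::tibble(id = data$id, pheno = data$pheno_std, bin = bin)
  fences <- df |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      q1 = quantile(.data$pheno, 0.25, type = 7),
      q3 = quantile(.data$pheno, 0.75, type = 7),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      lo = .data$q1 - iqr_multiplier * (.data$q3 - .data$q1),
      hi = .data$q3 + iqr_multiplier * (.data$q3 - .data$q1)
    )
  df <- dplyr::left_join(df, fences, by = "bin")
  stat <- pmax(df$lo - df$pheno, df$pheno - df$hi)
  dev <- stat > 0
  lab <- assign_direction(dev, data$pheno_std)
  new_classification(data$id, "grs_centile", stat, NA_real_, NA_real_, lab,
                     list(iqr_multiplier = iqr_multiplier, n_bins = n_bins))
}

#' Run all four deviator classifiers
#'
#' Convenience wrapper running the Mahalanobis, regression-residual,
#' GRS-rank and GRS-centile classifiers on one scored cohort and binding the
#' results (one row per individual per method).
#'
#' @inheritParams classify_mahalanobis
#' @inheritParams classify_regression_residual
#' @inheritParams classify_grs_rank
#' @inheritParams classify_grs_centile
#' @param methods Subset of methods to run.
#' @return A `pgs_classification` tibble.
#' @export
classify_all <- function(data, covariance = NULL, reference = NULL,
                         methods = c("mahalanobis", "regression_residual",
                                     "grs_rank", "grs_centile"),
                         p_threshold = 0.001, z_retain = 2, z_concordant = 1,
                         bonferroni = FALSE, k = 2, alpha = 0.001,
                         iqr_multiplier = 1.5, n_bins = 100) {
  methods <- match.arg(methods, several.ok = TRUE)
  parts <- list()
  if ("mahalanobis" %in% methods) {
    if (is.null(covariance)) abort("`covariance` is required for the mahalanobis method.")
    parts <- c(parts, list(classify_mahalanobis(
      data, covariance, p_threshold = p_threshold, z_retain = z_retain,
      z_concordant = z_concordant, bonferroni = bonferroni)))
  }
  if ("regression_residual" %in% methods) {
    parts <- c(parts, list(classify_regression_residual(data, k = k)))
  }
  if ("grs_rank" %in% methods) {
    if (is.null(reference)) abort("`reference` is required for the grs_rank method.")
    parts <- c(parts, list(classify_grs_rank(data, reference, alpha = alpha)))
  }
  if ("grs_centile" %in% methods) {
    parts <- c(parts, list(classify_grs_centile(
      data, iqr_multiplier = iqr_multiplier, n_bins = n_bins)))
  }
  specs <- purrr::map(parts, attr, "threshold_spec")
  names(specs) <- purrr::map_chr(parts, ~ .x$method[1])
  out <- dplyr::bind_rows(parts)
  attr(out, "threshold_spec") <- specs
  class(out) <- c("pgs_classification", class(out))
  out
}

#' Overlap of flagged individuals across methods
#'
#' Counts, for every pair of classification sets, how many flagged
#' (lower/higher) individuals are shared; diagonal rows give each method's
#' total.
#'
#' @param classifications A `pgs_classification` tibble covering one or more
#'   methods (e.g. from [classify_all()]), or a list of them.
#' @return Tibble with `method_a`, `method_b`, `n_a`, `n_b`, `n_shared`.
#' @export
compare_methods <- function(classifications) {
  if (is.list(classifications) && !is.data.frame(classifications)) {
    classifications <- dplyr::bind_rows(classifications)
  }
  flagged <- dplyr::filter(classifications,
                           .data$label %in% c("lower", "higher"))
  sets <- split(flagged$id, flagged$method, drop = FALSE)
  meths <- unique(classifications$method)
  sets <- lapply(setNames(meths, meths), function(m) sets[[m]] %||% character())
  grid <- tidyr::expand_grid(method_a = meths, method_b = meths)
  dplyr::mutate(
    grid,
    n_a = purrr::map_int(.data$method_a, ~ length(sets[[.x]])),
    n_b = purrr::map_int(.data$method_b, ~ length(sets[[.x]])),
    n_shared = purrr::map2_int(.data$method_a, .data$method_b,
                               ~ length(intersect(sets[[.x]], sets[[.y]])))
  )
}

#' @exportS3Method base::print
print.pgs_classification <- function(x, ...) {
  tab <- table(x$method, x$label)
  cat("# Deviator classification —", nrow(tab), "method(s)\n")
  print(tab)
  invisible(x)
}

#' Summarise a classification
#'
#' One row per method with flagged/concordant counts — the shape of the
#' published per-method deviator tallies.
#'
#' @param object A `pgs_classification` tibble.
#' @param ... Unused.
#' @return A tibble with per-method counts.
#' @export
summary.pgs_classification <- function(object, ...) {
  object |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_lower = sum(.data$label == "lower"),
      n_higher = sum(.data$label == "higher"),
      n_deviators = .data$n_lower + .data$n_higher,
      n_concordant = sum(.data$label == "concordant"),
      n_indeterminate = sum(.data$label == "indeterminate"),
      .groups = "drop"
    )
}
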