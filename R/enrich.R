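#' Flag extreme values of a quantitative trait
#'
#' Standardizes a vector and flags values beyond `sd_threshold` SDs — used to
#' binarize follow-up traits (e.g. extreme sitting-to-standing height ratio
#' beyond 1 SD) before odds-ratio testing.
#'
#' @param values Numeric vector (`NA` propagates to `NA` flags).
#' @param sd_threshold Threshold in SD units (> strictly).
#' @param side `"both"` (default), `"lower"`, or `"upper"`.
#' @return Logical vector.
#' @export
binarize_extreme <- function(values, sd_threshold = 1,
                             side = c("both", "lower", "upper")) {
  side <- match.arg(side)
  ok <- !is.na(values)
  out <- rep(NA, length(values))
  x <- values[ok]
  if (sd(x) == 0) {
    out[ok] <- FALSE
    return(out)
  }
  z <- (x - mean(x)) / sd(x)
  out[ok] <- switch(side,
    both = abs(z) > sd_threshold,
    lower = z < -sd_threshold,
    upper = z > sd_threshold
  )
  out
}

#' Exact odds-ratio enrichment of a binary trait in a deviator group
#'
#' Builds the 2x2 table (deviator vs concordant) x (trait present vs absent)
#' and applies Fisher's exact test: conditional maximum-likelihood odds
#' ratio, exact confidence interval, exact p-value. The sample cross-product
#' odds ratio is reported alongside. An empty table margin leaves the
#' estimate undefined (`NA`) with the counts intact.
#'
#' @param group_flags Logical: `TRUE` = deviator, `FALSE` = concordant.
#'   Individuals not in either group must be excluded beforehand.
#' @param trait_flags Logical trait indicator over the same individuals; `NA`
#'   pairs are dropped.
#' @param group,trait Labels recorded in the result.
#' @param conf_level Confidence level for the exact CI.
#' @return One-row tibble: `group`, `trait`, `model`, `estimate` (conditional
#'   MLE OR), `sample_or`, `ci_low`, `ci_high`, `p_value`, and the four cell
#'   counts `n_dev_trait`, `n_dev_no`, `n_ref_trait`, `n_ref_no`.
#' @examples
#' fisher_enrichment(rep(c(TRUE, FALSE), c(100, 900)),
#'                   c(rep(TRUE, 10), rep(FALSE, 90),
#'                     rep(TRUE, 10), rep(FALSE, 890)))
#' @export
fisher_enrichment <- function(group_flags, trait_flags, group = "deviator",
                              trait = "trait", conf_level = 0.95) {
  if (length(group_flags) != length(trait_flags)) {
    abort("`group_flags` and `trait_flags` must have the same length.")
  }
  keep <- !is.na(group_flags) & !is.na(trait_flags)
  g <- group_flags[keep]; t <- trait_flags[keep]
  counts <- c(n_dev_trait = sum(g & t), n_dev_no = sum(g & !t),
              n_ref_trait = sum(!g & t), n_ref_no = sum(!g & !t))
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    est <- ci <- c(NA_real_, NA_real_); p <- NA_real_; or_s <- NA_real_
    res <- tibble::tibble(group = group, trait = trait, model = "fisher",
                          estimate = NA_real_, sample_or = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          p_value = NA_real_)
  } else {
    ft <- fisher.test(tab, conf.level = conf_level)
    or_s <- (counts[1] * counts[4]) / (counts[2] * counts[3])
    res <- tibble::tibble(group = group, trait = trait, model = "fisher",
                          estimate = unname(ft$estimate),
                          sample_or = unname(or_s),
                          ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
                          p_value = ft$p.value)
  }
  dplyr::bind_cols(res, tibble::as_tibble(as.list(counts)))
}

#' Covariate-adjusted enrichment regression
#'
#' Effect of deviator-group membership on an outcome, adjusting for
#' covariates: linear regression for quantitative outcomes (which should be
#' rank-inverse-normalized upstream so effects are in SD units), logistic
#' regression for binary outcomes (estimate reported on the odds-ratio
#' scale). Wald confidence interval and p-value.
#'
#' @param data Data frame holding the outcome, the group indicator and the
#'   covariates; rows restricted to deviators and their concordant reference
#'   group.
#' @param outcome Name of the outcome column (numeric, or logical/0-1 for
#'   logistic).
#' @param group Name of the logical group-indicator column (`TRUE` =
#'   deviator).
#' @param covariates Character vector of covariate column names.
#' @param family `"linear"` or `"logistic"`.
#' @param conf_level Confidence level.
#' @return One-row tibble matching [fisher_enrichment()]'s core columns, with
#'   `n_dev`/`n_ref` group sizes.
#' @export
regression_enrichment <- function(data, outcome, group, covariates = character(),
                                  family = c("linear", "logistic"),
                                  conf_level = 0.95) {
  family <- match.arg(family)
  for (col in c(outcome, group, covariates)) {
    if (!col %in% names(data)) abort(paste0("Column `", col, "` not found."))
  }
  d <- data[c(outcome, group, covariates)]
  d <- d[complete.cases(d), , drop = FALSE]
  names(d)[1:2] <- c(".outcome", ".group")
  d$.group <- as.logical(d$.group)
  rhs <- paste(c(".group", covariates), collapse = " + ")
  fml <- stats::as.formula(paste(".outcome ~", rhs))

  fit <- if (family == "linear") {
    lm(fml, data = d)
  } else {
    glm(fml, data = d, family = binomial())
  }
  co <- coef(fit)[".groupTRUE"]
  se <- sqrt(vcov(fit)[".groupTRUE", ".groupTRUE"])
  zq <- qnorm(1 - (1 - conf_level) / 2)
  p <- 2 * pnorm(-abs(co / se))
  est <- c(co - zq * se, co, co + zq * se)
  if (family == "logistic") est <- exp(est)
  tibble::tibble(
    group = group, trait = outcome,
    model = if (family == "linear") "linear" else "logistic",
    estimate = unname(est[2]), ci_low = unname(est[1]),
    ci_high = unname(est[3]), p_value = unname(p),
    n_dev = sum(d$.group), n_ref = sum(!d$.group)
  )
}

#' Define rare-variant carriers from genotypes and annotations
#'
#' Flags individuals carrying at least one allele (dosage >= 1 after
#' rounding) of any variant that lies in a gene of interest, has the required
#' consequence class (default high-confidence loss-of-function), and is rare
#' (minor allele frequency strictly below `maf_max`, 0.001 in the published
#' protocol). MAF is taken from the annotation table, not recomputed from the
#' cohort.
#'
#' @param genotypes A `genotype_matrix` (see [compute_polygenic_score()] for
#'   the accepted shape).
#' @param annotations Tibble with `variant_id`, `gene`, `consequence`, `maf`.
#' @param gene_set Character vector of gene symbols.
#' @param maf_max Strict upper bound on MAF (default 0.001).
#' @param consequence_class Required consequence value (default
#'   `"LoF-HC"`).
#' @return Tibble with `id`, `carrier` (logical), and attribute
#'   `qualifying_variants`.
#' @export
define_carriers <- function(genotypes, annotations, gene_set,
                            maf_max = 0.001, consequence_class = "LoF-HC") {
  need <- c("variant_id", "gene", "consequence", "maf")
  miss <- setdiff(need, names(annotations))
  if (length(miss) > 0) {
    abort(paste0("`annotations` missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(annotations$maf < 0 | annotations$maf > 0.5, na.rm = TRUE)) {
    abort("`maf` must lie in [0, 0.5].")
  }
  dos <- genotypes$dosages
  qual <- annotations |>
    dplyr::filter(.data$gene %in% gene_set,
                  .data$consequence == consequence_class,
                  .data$maf < maf_max,
                  .data$variant_id %in% colnames(dos))
  carrier <- if (nrow(qual) == 0) {
    rep(FALSE, nrow(dos))
  } else {
    sub <- round(dos[, qual$variant_id, drop = FALSE])
    rowSums(sub >= 1, na.rm = TRUE) > 0
  }
  out <- tibble::tibble(id = rownames(dos), carrier = unname(carrier))
  attr(out, "qualifying_variants") <- qual$variant_id
  out
}

#' Run a panel of enrichment tests over deviator groups
#'
#' For one classification (one method), compares each deviator direction
#' (`lower`, `higher`) against the concordant reference group for every
#' supplied trait: exact odds ratios for binary traits, covariate-adjusted
#' linear regression for quantitative ones (rank-inverse-normalized first by
#' default). Traits with no non-missing values are skipped with a warning
#' row.
#'
#' @param classification A `pgs_classification` tibble for a single method.
#' @param traits Data frame with `id` plus one column per trait.
#' @param binary_traits,quantitative_traits Character vectors naming the
#'   trait columns; guessed from column type when `NULL` (logical/0-1 ->
#'   binary).
#' @param covariates Optional data frame with `id` plus covariate columns,
#'   used by the regression models.
#' @param covariate_cols Character vector of covariate names to adjust for.
#' @param rint_outcomes Rank-inverse-normalize quantitative outcomes before
#'   regression (default `TRUE`).
#' @return An `enrichment_panel` tibble: one row per group x trait.
#' @export
run_enrichment_panel <- function(classification, traits,
                                 binary_traits = NULL,
                                 quantitative_traits = NULL,
                                 covariates = NULL,
                                 covariate_cols = character(),
                                 rint_outcomes = TRUE) {
  if (length(unique(classification$method)) != 1) {
    abort("`classification` must cover a single method; filter first.")
  }
  if (!"id" %in% names(traits)) abort("`traits` must contain an `id` column.")
  trait_cols <- setdiff(names(traits), "id")
  if (is.null(binary_traits) && is.null(quantitative_traits)) {
    is_bin <- purrr::map_lgl(trait_cols, function(cn) {
      v <- traits[[cn]]
      is.logical(v) || all(v %in% c(0, 1, NA))
    })
    binary_traits <- trait_cols[is_bin]
    quantitative_traits <- trait_cols[!is_bin]
  } else {
    binary_traits <- binary_traits %||% character()
    quantitative_traits <- quantitative_traits %||% character()
  }

  base <- dplyr::left_join(
    dplyr::select(classification, "id", "label"), traits, by = "id")
  if (!is.null(covariates)) {
    base <- dplyr::left_join(base, covariates, by = "id")
  }

  all_traits <- c(binary_traits, quantitative_traits)
  empty_traits <- all_traits[purrr::map_lgl(all_traits,
                                            ~ all(is.na(base[[.x]])))]
  for (tr in empty_traits) {
    warn(paste0("Trait `", tr, "` has no non-missing values; skipped."))
  }

  rows <- list()
  for (grp in c("lower", "higher")) {
    sub <- dplyr::filter(base, .data$label %in% c(grp, "concordant"))
    sub$.is_dev <- sub$label == grp
    for (tr in all_traits) {
      if (tr %in% empty_traits) {
        rows <- c(rows, list(tibble::tibble(
          group = grp, trait = tr, model = "skipped", estimate = NA_real_,
          ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_)))
        next
      }
      if (tr %in% binary_traits) {
        if (length(covariate_cols) > 0) {
          row <- regression_enrichment(sub, tr, ".is_dev",
                                       covariates = covariate_cols,
                                       family = "logistic")
          row$group <- grp
        } else {
          row <- fisher_enrichment(sub$.is_dev, as.logical(sub[[tr]]),
                                   group = grp, trait = tr)
        }
      } else {
        sub2 <- sub
        if (rint_outcomes) sub2[[tr]] <- rank_inverse_normal(sub2[[tr]])
        row <- regression_enrichment(sub2, tr, ".is_dev",
                                     covariates = covariate_cols,
                                     family = "linear")
        row$group <- grp
      }
      rows <- c(rows, list(row))
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, p_bonferroni = pmin(1, .data$p_value * sum(!is.na(.data$p_value))))
  class(out) <- c("enrichment_panel", class(out))
  out
}
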