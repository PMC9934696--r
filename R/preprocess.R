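#' Residualize a phenotype on covariates and standardize
#'
#' Fits an ordinary least-squares regression of the raw phenotype on the given
#' covariate columns (plus an intercept) and returns the residuals divided by
#' their sample SD (n-1 denominator). This is the standard preparation of a
#' quantitative trait — e.g. height adjusted for age, sex and assessment
#' centre — before comparing it with a polygenic score.
#'
#' Rows with a missing phenotype or any missing covariate are dropped (and
#' counted in the `n_dropped` attribute). Constant covariate columns are
#' dropped; a rank-deficient design after that is an error naming the
#' collinear columns.
#'
#' @param data Data frame with an `id` column, the phenotype column, and the
#'   covariate columns.
#' @param phenotype Name of the phenotype column (string).
#' @param covariates Character vector of covariate column names (may be
#'   empty: reduces to a plain z-score).
#' @param rint Apply the rank-based inverse-normal transform to the residuals
#'   instead of plain scaling? (Used for skewed traits such as LDL-C.)
#' @return Tibble with columns `id`, `pheno_std`; attributes `transform`
#'   (`"standardized-residual"` or `"rint-residual"`) and `n_dropped`.
#' @examples
#' d <- tibble::tibble(id = letters[1:6], y = c(1, 3, 2, 5, 4, 6),
#'                     age = c(20, 30, 25, 50, 40, 60))
#' residualize_standardize(d, "y", "age")
#' @export
residualize_standardize <- function(data, phenotype, covariates = character(),
                                    rint = FALSE) {
  if (!"id" %in% names(data)) abort("`data` must contain an `id` column.")
  if (!phenotype %in% names(data)) {
    abort(paste0("Phenotype column `", phenotype, "` not found."))
  }
  miss <- setdiff(covariates, names(data))
  if (length(miss) > 0) {
    abort(paste0("Covariate column(s) not found: ", paste(miss, collapse = ", ")))
  }
  y <- data[[phenotype]]
  if (any(is.infinite(y))) abort("Phenotype contains infinite values.")

  X <- data[covariates]
  keep <- is.finite(y) & (if (length(covariates)) complete.cases(X) else TRUE)
  n_dropped <- sum(!keep)
  y <- y[keep]
  ids <- data$id[keep]

  if (length(y) < length(covariates) + 2) {
    abort("Need at least 2 more observations than covariate columns.")
  }

  if (length(covariates) == 0) {
    res <- y - mean(y)
  } else {
    Xk <- X[keep, , drop = FALSE]
    # factors/characters expand to indicator columns; constants dropped
    mm <- model.matrix(~ ., data = Xk)
    const <- apply(mm[, -1, drop = FALSE], 2, function(col) var(col) == 0)
    mm <- cbind(mm[, 1, drop = FALSE], mm[, -1, drop = FALSE][, !const, drop = FALSE])
    qr_mm <- qr(mm)
    if (qr_mm$rank < ncol(mm)) {
      bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
      abort(paste0("Covariate design is rank deficient; collinear column(s): ",
                   paste(bad, collapse = ", ")))
    }
    res <- qr.resid(qr_mm, y)
  }

  if (!is.finite(sd(res)) || sd(res) <= 1e-10 * max(sd(y), 1e-300)) {
    abort("Residuals have zero variance; phenotype is an exact linear function of the covariates.")
  }
  value <- if (rint) {
    # re-scale so the stratum satisfies mean 0 / SD 1 exactly (the raw
    # Blom quantiles have SD slightly below 1 at finite n)
    std1(rank_inverse_normal(res))
  } else {
    res / sd(res)
  }

  out <- tibble::tibble(id = ids, pheno_std = value)
  attr(out, "transform") <- if (rint) "rint-residual" else "standardized-residual"
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Rank-based inverse-normal transform
#'
#' Maps values to the standard-normal quantiles of their Blom rank fractions
#' `(rank - 3/8) / (n + 1/4)`, forcing marginal normality while preserving the
#' ordering. Ties receive the average rank and hence identical outputs.
#'
#' @param values Numeric vector; `NA`s are propagated.
#' @return Numeric vector of the same length.
#' @examples
#' rank_inverse_normal(c(10, 2, 5))
#' @export
rank_inverse_normal <- function(values) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(x) < 2) abort("Need at least 2 non-missing values.")
  if (length(unique(x)) == 1) {
    abort("All values are identical; no rank information to transform.")
  }
  r <- rank(x, ties.method = "average")
  out <- values
  out[ok] <- qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  out
}

#' Split a cohort by sex
#'
#' Partitions a cohort into male and female strata for sex-stratified
#' analysis (each stratum is subsequently transformed and classified
#' independently). Individuals with unknown sex are excluded from both strata
#' and reported via a warning and the `n_unknown` attribute.
#'
#' @param data Data frame with an `id` column and a sex column.
#' @param sex_col Name of the sex column; values are matched case-insensitively
#'   to male/female (also accepts M/F, 1/2 coding where 1 = male).
#' @return Named list of tibbles `male` and `female`, with attribute
#'   `n_unknown`.
#' @export
stratify_by_sex <- function(data, sex_col = "sex") {
  if (!sex_col %in% names(data)) {
    abort(paste0("Sex column `", sex_col, "` not found."))
  }
  sx <- tolower(as.character(data[[sex_col]]))
  sx[sx %in% c("m", "male", "1")] <- "male"
  sx[sx %in% c("f", "female", "2")] <- "female"
  sx[!sx %in% c("male", "female")] <- "unknown"
  n_unknown <- sum(sx == "unknown")
  if (n_unknown > 0) {
    warn(sprintf("%d individual(s) with unknown sex excluded from both strata.",
                 n_unknown))
  }
  for (lev in c("male", "female")) {
    if (!any(sx == lev)) {
      warn(paste0("Stratum `", lev, "` is empty."))
    }
  }
  out <- list(
    male = tibble::as_tibble(data[sx == "male", , drop = FALSE]),
    female = tibble::as_tibble(data[sx == "female", , drop = FALSE])
  )
  attr(out, "n_unknown") <- n_unknown
  out
}
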