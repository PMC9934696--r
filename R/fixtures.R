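#' Generate a fully specified test cohort with planted deviators
#'
#' Builds a synthetic data set exercising the whole pipeline without any
#' external data: a base cohort simulated under the additive polygenic model,
#' a planted subset of deviators whose standardized phenotype is displaced
#' `displacement_sd` SDs from its conditional expectation given the score
#' (sign = planted direction), rare loss-of-function carrier variants in
#' designated genes for the `rare_variant`-mechanism deviators (with zero
#' weight in the score, mirroring variation the common-variant predictor
#' misses), and binary traits with elevated prevalence among planted
#' individuals.
#'
#' Displacement is applied after standardization and the phenotype is *not*
#' re-standardized, so planted effects stay in interpretable SD units. Note
#' that once the phenotype is re-standardized downstream (as any pipeline
#' will), planting a fraction `q` at `d` SD inflates the scale by
#' `sqrt(1 + q d^2)` (about 7.7% at the defaults), which shrinks the
#' effective displacement accordingly. The raw cohort
#' phenotype is reconstructed as a linear function of age, sex and centre plus
#' `resid_sd` times the standardized phenotype, so the preprocessing step has
#' real work to do.
#'
#' @param n Individuals.
#' @param n_variants Common variants in the score.
#' @param target_r2 Variance explained by the score (0.316 height-like,
#'   0.167 LDL-like).
#' @param planted_fraction Fraction of individuals planted as deviators (in
#'   `[0, 0.1]`).
#' @param displacement_sd Absolute phenotype displacement in SD units.
#' @param carrier_genes Gene symbols hosting the planted rare LoF variants
#'   (one variant per gene).
#' @param trait_enrichment Named list of binary trait specs, each
#'   `list(base_prev = ..., or = ...)`: prevalence among non-planted
#'   individuals, and the planted odds ratio.
#' @param background_carrier_rate Carrier probability among non-planted
#'   individuals (keeps enrichment odds ratios finite).
#' @param resid_sd,intercept Raw-phenotype scale: residual SD in measurement
#'   units and intercept (defaults emulate height in cm).
#' @param seed Integer seed; the whole fixture is reproducible.
#' @return A list of class `pgs_fixture`: `cohort` (raw phenotype +
#'   covariates), `genotypes` (`genotype_matrix` incl. rare variants),
#'   `weights`, `annotations`, `traits`, `truth` (per-individual planted
#'   status, direction, mechanism, carrier and trait flags), and `params`.
#' @examples
#' fx <- make_fixture(n = 500, n_variants = 50, planted_fraction = 0.02,
#'                    seed = 1)
#' table(fx$truth$is_planted_deviator)
#' @export
make_fixture <- function(n = 20000, n_variants = 200, target_r2 = 0.316,
                         planted_fraction = 0.01, displacement_sd = 4,
                         carrier_genes = c("GENEA", "GENEB"),
                         trait_enrichment = list(
                           short_at_10 = list(base_prev = 0.03, or = 10)),
                         background_carrier_rate = 0.002,
                         resid_sd = 6.5, intercept = 168, seed = NULL) {
  if (planted_fraction < 0 || planted_fraction > 0.1) {
    abort("`planted_fraction` must be in [0, 0.1].")
  }
  if (displacement_sd < 0) abort("`displacement_sd` must be >= 0.")

  sim <- simulate_cohort(n, n_variants = n_variants, target_r2 = target_r2,
                         seed = child_seed(seed, 1), keep_genotypes = TRUE)
  dos <- attr(sim, "dosages")
  betas <- attr(sim, "betas")
  freqs <- attr(sim, "freqs")

  with_seed_if(child_seed(seed, 2), {
    n_planted <- floor(planted_fraction * n)
    if (planted_fraction > 0 && n_planted < 1) {
      warn("`planted_fraction * n` < 1; no individuals planted.")
    }
    planted_idx <- sort(sample.int(n, n_planted))
    direction <- sample(c("lower", "higher"), n_planted, replace = TRUE)
    mechanism <- sample(c("rare_variant", "environment"), n_planted,
                        replace = TRUE)

    pheno <- sim$pheno_std
    shift <- ifelse(direction == "lower", -displacement_sd, displacement_sd)
    pheno[planted_idx] <- pheno[planted_idx] + shift

    # one rare LoF variant per carrier gene; planted rare_variant deviators
    # carry one allele in a gene matched to their direction
    rare_ids <- paste0("rare_", seq_along(carrier_genes))
    rare <- matrix(0L, n, length(carrier_genes),
                   dimnames = list(sim$id, rare_ids))
    bg <- matrix(rbinom(n * length(carrier_genes), 1L,
                        background_carrier_rate), n)
    rare[bg == 1L] <- 1L
    gene_for <- function(dir) {
      if (length(carrier_genes) == 1) 1L
      else ifelse(dir == "lower", 1L, 2L)
    }
    rv <- planted_idx[mechanism == "rare_variant"]
    rv_gene <- gene_for(direction[mechanism == "rare_variant"])
    rare[cbind(rv, rv_gene)] <- 1L

    traits <- tibble::tibble(id = sim$id)
    truth_traits <- list()
    for (tr in names(trait_enrichment)) {
      spec <- trait_enrichment[[tr]]
      odds0 <- spec$base_prev / (1 - spec$base_prev)
      p1 <- spec$or * odds0 / (1 + spec$or * odds0)
      p <- rep(spec$base_prev, n)
      p[planted_idx] <- p1
      traits[[tr]] <- rbinom(n, 1L, p) == 1L
      truth_traits[[tr]] <- traits[[tr]]
    }

    # raw phenotype = covariate signal + resid_sd * standardized residual
    age <- round(runif(n, 40, 70))
    sex <- sample(c("male", "female"), n, replace = TRUE)
    centre <- sample(paste0("centre_", 1:3), n, replace = TRUE)
    sex_eff <- ifelse(sex == "male", 13, 0)
    centre_eff <- unname(c(centre_1 = 0, centre_2 = 0.8,
                           centre_3 = -0.5)[centre])
    raw_pheno <- intercept - 0.05 * (age - 55) + sex_eff + centre_eff +
      resid_sd * pheno

    cohort <- tibble::tibble(id = sim$id, phenotype = raw_pheno, sex = sex,
                             age = age, centre = centre)

    all_dos <- cbind(dos, rare)
    genotypes <- structure(
      list(dosages = all_dos,
           effect_allele = setNames(rep("A", ncol(all_dos)),
                                    colnames(all_dos))),
      class = "genotype_matrix")

    weights <- tibble::tibble(
      variant_id = colnames(all_dos),
      effect_allele = "A", other_allele = "G",
      beta = c(betas, rep(0, length(carrier_genes)))
    )
    annotations <- tibble::tibble(
      variant_id = colnames(all_dos),
      gene = c(paste0("LOCUS_", seq_len(ncol(dos))), carrier_genes),
      consequence = c(rep("other", ncol(dos)),
                      rep("LoF-HC", length(carrier_genes))),
      maf = c(freqs, rep(1e-4, length(carrier_genes)))
    )

    truth <- tibble::tibble(
      id = sim$id,
      ps_std = sim$ps_std,
      pheno_std_true = pheno,
      is_planted_deviator = seq_len(n) %in% planted_idx,
      planted_direction = NA_character_,
      planted_mechanism = NA_character_,
      displacement_sd = 0
    )
    truth$planted_direction[planted_idx] <- direction
    truth$planted_mechanism[planted_idx] <- mechanism
    truth$displacement_sd[planted_idx] <- displacement_sd
    for (j in seq_along(carrier_genes)) {
      truth[[paste0("carrier_", carrier_genes[j])]] <- rare[, j] == 1L
    }
    for (tr in names(truth_traits)) truth[[tr]] <- truth_traits[[tr]]

    structure(
      list(cohort = cohort, genotypes = genotypes, weights = weights,
           annotations = annotations, traits = traits, truth = truth,
           params = list(n = n, n_variants = n_variants,
                         target_r2 = target_r2,
                         planted_fraction = planted_fraction,
                         displacement_sd = displacement_sd,
                         carrier_genes = carrier_genes,
                         background_carrier_rate = background_carrier_rate,
                         seed = seed)),
      class = "pgs_fixture")
  })
}

#' Score a classifier against a fixture's planted truth
#'
#' Runs the full pipeline — polygenic scoring from the fixture's genotypes
#' and weights, phenotype residualization on age/sex/centre, score
#' standardization, classification by the chosen method — and scores the
#' calls against the planted truth: sensitivity (planted deviators
#' recovered), specificity, and the false-discovery proportion of the flagged
#' set. When `carrier_gene` is given, a carrier-enrichment odds ratio of the
#' recovered `lower` group against the concordant group is appended.
#'
#' @param fixture A [make_fixture()] result.
#' @param method One of the four classifier names.
#' @param covariance,reference Passed to the classifier when required; built
#'   automatically from fresh simulations (seeded from the fixture seed) when
#'   `NULL`.
#' @param n_reps Replicates for an auto-built rank reference.
#' @param carrier_gene Optional gene symbol for the follow-up carrier
#'   enrichment.
#' @param ... Threshold arguments forwarded to the classifier.
#' @return A one-row tibble: method, counts, `sensitivity`, `specificity`,
#'   `fdr`, and (if requested) `carrier_or`, `carrier_p`; attribute
#'   `classification` holds the per-individual calls.
#' @export
end_to_end_check <- function(fixture, method = c("mahalanobis",
                                                 "regression_residual",
                                                 "grs_rank", "grs_centile"),
                             covariance = NULL, reference = NULL,
                             n_reps = 2000, carrier_gene = NULL, ...) {
  method <- match.arg(method)
  p <- fixture$params

  scores <- compute_polygenic_score(fixture$genotypes, fixture$weights)
  scores <- pc_adjust_and_standardize(scores)
  pheno <- residualize_standardize(fixture$cohort, "phenotype",
                                   c("age", "sex", "centre"))
  scored <- dplyr::inner_join(dplyr::select(scores, "id", "ps_std"),
                              pheno, by = "id")

  if (method == "mahalanobis" && is.null(covariance)) {
    covariance <- estimate_null_covariance(simulate_cohort(
      max(p$n, 50000), n_variants = 200, target_r2 = p$target_r2,
      seed = child_seed(p$seed, 11), keep_genotypes = FALSE))
  }
  if (method == "grs_rank" && is.null(reference)) {
    reference <- simulate_rank_reference(p$n, n_reps = n_reps,
                                         target_r2 = p$target_r2,
                                         seed = child_seed(p$seed, 12))
  }
  cls <- switch(method,
    mahalanobis = classify_mahalanobis(scored, covariance, ...),
    regression_residual = classify_regression_residual(scored, ...),
    grs_rank = classify_grs_rank(scored, reference, ...),
    grs_centile = classify_grs_centile(scored, ...)
  )

  joined <- dplyr::inner_join(cls, fixture$truth, by = "id")
  called <- joined$label %in% c("lower", "higher")
  planted <- joined$is_planted_deviator
  tp <- sum(called & planted); fp <- sum(called & !planted)
  fn <- sum(!called & planted); tn <- sum(!called & !planted)
  out <- tibble::tibble(
    method = method, n = nrow(joined), n_planted = sum(planted),
    n_called = tp + fp, tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = if (sum(planted) > 0) tp / (tp + fn) else NA_real_,
    specificity = tn / (tn + fp),
    fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_
  )

  if (!is.null(carrier_gene)) {
    carriers <- define_carriers(fixture$genotypes, fixture$annotations,
                                carrier_gene)
    sub <- dplyr::inner_join(
      dplyr::filter(cls, .data$label %in% c("lower", "concordant")),
      carriers, by = "id")
    enr <- fisher_enrichment(sub$label == "lower", sub$carrier,
                             group = "lower",
                             trait = paste0("carrier_", carrier_gene))
    out$carrier_or <- enr$estimate
    out$carrier_p <- enr$p_value
  }
  attr(out, "classification") <- cls
  out
}

#' @exportS3Method base::print
print.pgs_fixture <- function(x, ...) {
  cat(sprintf(
    "# Synthetic deviator fixture: n = %d, %d score variants + %d rare LoF, R^2 = %.3f, %d planted\n",
    x$params$n, x$params$n_variants, length(x$params$carrier_genes),
    x$params$target_r2, sum(x$truth$is_planted_deviator)))
  invisible(x)
}
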