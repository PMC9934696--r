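identity_cov <- diag(2)

test_that("Mahalanobis p-values match the chi-squared(2) closed form", {
  d <- tibble::tibble(id = c("centre", "off"),
                      ps_std = c(0, 2), pheno_std = c(0, 0))
  # keep means at the first point by adding mirrored mass
  d <- tibble::tibble(id = paste0("i", 1:4),
                      ps_std = c(2, -2, 0, 0), pheno_std = c(0, 0, 1, -1))
  out <- mahalanobis_pvalues(d, identity_cov)
  expect_equal(out$d2, c(4, 4, 1, 1))
  # chi-squared with 2 df: survival(x) = exp(-x/2)
  expect_equal(out$p_value, exp(-out$d2 / 2), tolerance = 1e-12)
  expect_equal(out$p_value[3], exp(-0.5), tolerance = 1e-12)
})

test_that("a point at the mean has zero distance and p = 1", {
  d <- tibble::tibble(id = c("a", "b", "c"),
                      ps_std = c(0, 1, -1), pheno_std = c(0, 1, -1))
  out <- mahalanobis_pvalues(d, matrix(c(1, 0.5, 0.5, 1), 2))
  expect_equal(out$d2[1], 0)
  expect_equal(out$p_value[1], 1)
})

test_that("correlated-covariance distances agree with the explicit 2x2 inverse", {
  withr::with_seed(17, {
    for (rho in c(-0.6, 0, 0.3, 0.9)) {
      d <- make_scored(200, max(rho, 0), seed = 100 + round(10 * rho))
      sigma <- matrix(c(1, rho, rho, 1), 2)
      out <- mahalanobis_pvalues(d, sigma)
      x <- cbind(d$ps_std, d$pheno_std)
      expect_equal(out$d2, mahal_oracle(x, colMeans(x), sigma),
                   tolerance = 1e-10)
    }
  })
  expect_error(mahalanobis_pvalues(make_scored(10, 0.5),
                                   matrix(c(1, 1, 1, 1), 2)),
               "positive definite")
})

test_that("residual z has mean 0, SD 1, and errors when degenerate", {
  d <- make_scored(1000, 0.56, seed = 22)
  z <- residual_z(d)$residual_z
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  perfect <- tibble::tibble(id = as.character(1:5),
                            ps_std = std <- scale(1:5)[, 1],
                            pheno_std = std)
  expect_error(residual_z(perfect), "undefined")
})

test_that("null fraction with |z| beyond 2 or 3 matches the normal tails", {
  sim <- simulate_cohort(1e5, 100, 0.316, seed = 23, keep_genotypes = FALSE)
  z <- residual_z(sim)$residual_z
  expect_lt(abs(mean(abs(z) > 2) - 0.0455), 0.004)
  k3 <- classify_regression_residual(sim, k = 3)
  frac3 <- mean(k3$label %in% c("lower", "higher"))
  se3 <- sqrt(0.0027 * (1 - 0.0027) / 1e5)
  expect_lt(frac3, 0.0027 + 3 * se3)
  expect_gt(frac3, 0.0027 - 3 * se3)
  # k = 2 flags a superset of k = 3 flags
  k2 <- classify_regression_residual(sim, k = 2)
  f2 <- k2$id[k2$label != "concordant"]
  f3 <- k3$id[k3$label != "concordant"]
  expect_true(all(f3 %in% f2))
})

test_that("mahalanobis classifier applies the p, |z| retention and concordance rules", {
  withr::with_seed(30, {
    rho <- 0.562
    n <- 5000
    ps <- rnorm(n)
    ph <- rho * ps + sqrt(1 - rho^2) * rnorm(n)
    # plant one individual far below its conditional expectation rho*ps
    ps[1] <- 0.5; ph[1] <- rho * 0.5 - 6
    # and one exactly on the regression line at a moderate score
    ps[2] <- 0.8; ph[2] <- rho * 0.8
    d <- tibble::tibble(id = sprintf("i%04d", 1:n), ps_std = ps,
                        pheno_std = ph)
    sigma <- matrix(c(1, rho, rho, 1), 2)
    cls <- classify_mahalanobis(d, sigma)
    expect_equal(as.character(cls$label[1]), "lower")
    expect_equal(as.character(cls$label[2]), "concordant")
    spec <- attr(cls, "threshold_spec")
    expect_equal(spec$p_threshold, 0.001)
    # bonferroni override
    clsb <- classify_mahalanobis(d, sigma, bonferroni = TRUE)
    expect_equal(attr(clsb, "threshold_spec")$p_threshold, 0.05 / n)
  })
})

test_that("deviator labels require both the p and the z condition", {
  d <- make_scored(4000, 0.56, seed = 31)
  sigma <- matrix(c(1, 0.56, 0.56, 1), 2)
  cls <- classify_mahalanobis(d, sigma, p_threshold = 0.05, z_retain = 2)
  z <- residual_z(d)$residual_z
  p <- mahalanobis_pvalues(d, sigma)$p_value
  dev <- cls$label %in% c("lower", "higher")
  expect_true(all(p[dev] < 0.05))
  expect_true(all(abs(z[dev]) > 2))
  conc <- cls$label == "concordant"
  expect_true(all(p[conc] > 0.05 & abs(z[conc]) < 1))
})

test_that("null calibration: mahalanobis flags strictly fewer than alpha", {
  sim <- simulate_cohort(1e5, 100, 0.316, seed = 32, keep_genotypes = FALSE)
  sigma <- estimate_null_covariance(
    simulate_cohort(2e5, 100, 0.316, seed = 33, keep_genotypes = FALSE))
  cls <- classify_mahalanobis(sim, sigma, p_threshold = 0.001)
  frac <- mean(cls$label %in% c("lower", "higher"))
  expect_lt(frac, 0.001)
  # p-values are uniform under the null
  p <- mahalanobis_pvalues(sim, sigma)$p_value
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("empirical rank p-values equal direct counting on a toy reference", {
  withr::with_seed(40, {
    d <- make_scored(20, 0.5, seed = 41)
    ref <- simulate_rank_reference(20, n_reps = 50, target_r2 = 0.25,
                                   seed = 42)
    cls <- classify_grs_rank(d, ref, alpha = 0.05)
    expect_equal(cls$p_value, grs_rank_oracle(d, ref, 0.05),
                 tolerance = 1e-12)
    # formula bounds: p in [1/(reps+1), 1]
    expect_true(all(cls$p_value >= 1 / 51 & cls$p_value <= 1))
  })
})

test_that("an observation beyond every reference value gets the minimum p", {
  ref <- simulate_rank_reference(5, n_reps = 100, target_r2 = 0, seed = 43)
  d <- tibble::tibble(id = paste0("i", 1:5),
                      ps_std = std1_ <- scale(1:5)[, 1],
                      pheno_std = c(0, 0, 0, 0, 50))
  cls <- classify_grs_rank(d, ref, alpha = 0.05)
  # individual 5 has the top score rank and an impossibly extreme phenotype
  expect_equal(cls$p_value[5], 1 / 101)  # r = 0 -> (0+1)/(100+1)
  expect_equal(as.character(cls$label[5]), "higher")
  # a value at the per-rank median is maximally unexceptional
  med <- median(ref[, 1])
  d2 <- dplyr::mutate(d, pheno_std = c(med, 0, 0, 0, 0))
  expect_gte(classify_grs_rank(d2, ref, alpha = 0.05)$p_value[1], 0.5)
})

test_that("rank classifier rejects a size-mismatched reference", {
  ref <- simulate_rank_reference(10, n_reps = 20, target_r2 = 0.3, seed = 44)
  expect_error(classify_grs_rank(make_scored(12, 0.5), ref, 0.05),
               "n = 10")
})

test_that("centile fences flag the expected normal tail fraction", {
  sim <- simulate_cohort(1e5, 60, 0.316, seed = 50, keep_genotypes = FALSE)
  cls <- classify_grs_centile(sim, iqr_multiplier = 1.5)
  frac <- mean(cls$label %in% c("lower", "higher"))
  # fences at +/- 2.698 sigma within each score bin: 2*Phi(-2.698) = 0.00698,
  # mildly inflated by quartile estimation noise at 1000 per bin
  expect_gt(frac, 0.0045)
  expect_lt(frac, 0.0105)
  # stricter fences flag a subset
  cls3 <- classify_grs_centile(sim, iqr_multiplier = 3)
  f15 <- cls$id[cls$label != "concordant"]
  f3 <- cls3$id[cls3$label != "concordant"]
  expect_true(all(f3 %in% f15))
  expect_lt(length(f3), length(f15))
})

test_that("zero-IQR bins flag nothing", {
  d <- tibble::tibble(id = paste0("i", 1:300),
                      ps_std = rnorm(300), pheno_std = rep(5, 300))
  cls <- classify_grs_centile(d, n_bins = 3)
  expect_true(all(cls$label == "concordant"))
})

test_that("negating both axes preserves p-values and swaps direction labels", {
  d <- make_scored(3000, 0.5, seed = 60)
  neg <- dplyr::mutate(d, ps_std = -ps_std, pheno_std = -pheno_std)
  sigma <- matrix(c(1, 0.5, 0.5, 1), 2)
  swap <- function(lab) {
    out <- as.character(lab)
    out[lab == "lower"] <- "higher"
    out[lab == "higher"] <- "lower"
    out
  }
  a <- classify_mahalanobis(d, sigma, p_threshold = 0.05)
  b <- classify_mahalanobis(neg, sigma, p_threshold = 0.05)
  expect_equal(b$p_value, a$p_value, tolerance = 1e-10)
  expect_equal(as.character(b$label), swap(a$label))

  a2 <- classify_regression_residual(d, k = 2)
  b2 <- classify_regression_residual(neg, k = 2)
  expect_equal(abs(b2$statistic), abs(a2$statistic), tolerance = 1e-10)
  expect_equal(as.character(b2$label), swap(a2$label))

  a3 <- classify_grs_centile(d)
  b3 <- classify_grs_centile(neg)
  expect_equal(sum(b3$label == "lower"), sum(a3$label == "higher"))
})

test_that("direction assignment is the sign of the standardized phenotype", {
  expect_equal(assign_direction(c(TRUE, TRUE, FALSE), c(-3, 3, -5)),
               c("lower", "higher", "concordant"))
  expect_warning(lab <- assign_direction(TRUE, 0), "indeterminate")
  expect_equal(lab, "indeterminate")
})

test_that("method overlap counts match hand enumeration on a small fixture", {
  lab <- function(ids, flagged, method) {
    tibble::tibble(id = ids, method = method, statistic = 0,
                   p_value = NA_real_, residual_z = NA_real_,
                   label = factor(ifelse(ids %in% flagged, "lower",
                                         "concordant"),
                                  levels = levels(factor(c("lower",
                                                           "concordant")))))
  }
  ids <- sprintf("i%02d", 1:20)
  m1 <- lab(ids, c("i01", "i02", "i03"), "m1")
  m2 <- lab(ids, c("i02", "i03", "i04", "i05"), "m2")
  m3 <- lab(ids, character(), "m3")
  cmp <- compare_methods(dplyr::bind_rows(m1, m2, m3))
  get <- function(a, b) cmp$n_shared[cmp$method_a == a & cmp$method_b == b]
  expect_equal(get("m1", "m1"), 3L)
  expect_equal(get("m2", "m2"), 4L)
  expect_equal(get("m1", "m2"), 2L)
  expect_equal(get("m1", "m3"), 0L)
  expect_equal(cmp$n_a[cmp$method_a == "m3"][1], 0L)
  # identical flag sets -> overlap equals the total
  cmp2 <- compare_methods(dplyr::bind_rows(m1, dplyr::mutate(m1, method = "m1b")))
  expect_equal(cmp2$n_shared[cmp2$method_a == "m1" & cmp2$method_b == "m1b"], 3L)
})

test_that("classify_all stacks one row per individual per method", {
  d <- make_scored(300, 0.5, seed = 70)
  sigma <- matrix(c(1, 0.5, 0.5, 1), 2)
  ref <- simulate_rank_reference(300, n_reps = 100, target_r2 = 0.25,
                                 seed = 71)
  cls <- classify_all(d, covariance = sigma, reference = ref)
  expect_equal(nrow(cls), 4 * 300)
  expect_setequal(unique(cls$method),
                  c("mahalanobis", "regression_residual", "grs_rank",
                    "grs_centile"))
  expect_named(attr(cls, "threshold_spec"),
               c("mahalanobis", "regression_residual", "grs_rank",
                 "grs_centile"))
  expect_error(classify_all(d, covariance = NULL, methods = "mahalanobis"),
               "covariance")
})
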