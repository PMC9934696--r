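test_that("extreme-value binarization matches the normal tail", {
  withr::with_seed(80, x <- rnorm(2e4))
  expect_lt(abs(mean(binarize_extreme(x, 1)) - 0.317), 0.015)
  expect_true(all(binarize_extreme(x, 0) | x == mean(x)))
  expect_false(any(binarize_extreme(rep(2.5, 50), 1)))
  one_sided <- binarize_extreme(x, 1, side = "upper")
  expect_lt(abs(mean(one_sided) - 0.159), 0.012)
  expect_true(is.na(binarize_extreme(c(x[1:10], NA), 1)[11]))
})

test_that("fisher enrichment reports the exact OR, CI and counts", {
  g <- rep(c(TRUE, FALSE), c(100, 900))
  t <- c(rep(TRUE, 10), rep(FALSE, 90), rep(TRUE, 10), rep(FALSE, 890))
  res <- fisher_enrichment(g, t)
  expect_equal(res$sample_or, (10 * 890) / (90 * 10), tolerance = 1e-12)
  expect_gt(res$estimate, 8); expect_lt(res$estimate, 12)
  expect_true(res$ci_low <= res$estimate & res$estimate <= res$ci_high)
  expect_equal(res$n_dev_trait + res$n_dev_no + res$n_ref_trait +
                 res$n_ref_no, 1000)
})

test_that("fisher enrichment agrees with hypergeometric enumeration on small tables", {
  # exhaustive over modest cells plus random tables with margins up to 30
  cells <- expand.grid(a = 0:4, b = 1:4, c = 1:4, d = 1:4)
  withr::with_seed(81, {
    extra <- data.frame(a = sample(0:15, 60, TRUE), b = sample(1:15, 60, TRUE),
                        c = sample(1:15, 60, TRUE), d = sample(1:15, 60, TRUE))
  })
  tabs <- rbind(cells[sample(nrow(cells), 120), ], extra)
  for (i in seq_len(nrow(tabs))) {
    a <- tabs$a[i]; b <- tabs$b[i]; c <- tabs$c[i]; d <- tabs$d[i]
    res <- fisher_enrichment(rep(c(TRUE, FALSE), c(a + b, c + d)),
                             c(rep(c(TRUE, FALSE), c(a, b)),
                               rep(c(TRUE, FALSE), c(c, d))))
    oracle <- fisher_oracle(a, b, c, d)
    expect_equal(res$p_value, oracle$p, tolerance = 1e-9)
    if (is.finite(oracle$or) && oracle$or > 0) {
      expect_equal(res$estimate, oracle$or, tolerance = 1e-3)
    }
  }
})

test_that("degenerate tables keep counts but not estimates", {
  res <- fisher_enrichment(c(TRUE, TRUE, FALSE, FALSE),
                           c(FALSE, FALSE, FALSE, FALSE))
  expect_true(is.na(res$estimate) && is.na(res$p_value))
  expect_equal(res$n_ref_no, 2)
  # zero deviator-with-trait cell: CI lower bound 0, finite upper bound
  res0 <- fisher_enrichment(rep(c(TRUE, FALSE), c(50, 420)),
                            c(rep(FALSE, 50), rep(c(TRUE, FALSE), c(20, 400))))
  expect_equal(res0$ci_low, 0)
  expect_true(is.finite(res0$ci_high))
})

test_that("equal prevalence gives OR near 1 and p near 1", {
  res <- fisher_enrichment(rep(c(TRUE, FALSE), c(500, 500)),
                           rep(c(TRUE, FALSE, TRUE, FALSE),
                               c(50, 450, 50, 450)))
  expect_lt(abs(log(res$estimate)), 0.1)
  expect_gt(res$p_value, 0.8)
})

test_that("linear enrichment recovers a planted group effect", {
  withr::with_seed(82, {
    n <- 5000
    grp <- rep(c(TRUE, FALSE), c(500, 4500))
    d <- tibble::tibble(
      id = as.character(1:n), grp = grp, age = rnorm(n, 55, 8),
      out = grp * 1 + rnorm(n) + 0.02 * (rnorm(n, 55, 8) - 55)
    )
    res <- regression_enrichment(d, "out", "grp", "age", family = "linear")
    se <- (res$ci_high - res$ci_low) / (2 * qnorm(0.975))
    expect_lt(abs(res$estimate - 1), 3 * se)
    # null outcome shows no effect
    d$null_out <- rnorm(n)
    res0 <- regression_enrichment(d, "null_out", "grp", "age")
    se0 <- (res0$ci_high - res0$ci_low) / (2 * qnorm(0.975))
    expect_lt(abs(res0$estimate), 3 * se0)
  })
})

test_that("logistic enrichment recovers a planted odds ratio of 5", {
  withr::with_seed(83, {
    n <- 1e4
    grp <- runif(n) < 0.05
    base_p <- 0.05
    p <- plogis(qlogis(base_p) + log(5) * grp)
    d <- tibble::tibble(id = as.character(1:n), grp = grp,
                        y = runif(n) < p, bmi = rnorm(n, 27, 4))
    res <- regression_enrichment(d, "y", "grp", "bmi", family = "logistic")
    expect_gt(res$estimate, 3.5)
    expect_lt(res$estimate, 7)
    expect_lt(res$p_value, 0.001)
  })
})

test_that("enrichment models are invariant to affine covariate recoding", {
  withr::with_seed(84, {
    n <- 2000
    d <- tibble::tibble(id = as.character(1:n),
                        grp = runif(n) < 0.1,
                        age = rnorm(n, 55, 8))
    d$y <- 0.5 * d$grp + 0.03 * d$age + rnorm(n)
    d$yb <- runif(n) < plogis(-2 + d$grp + 0.01 * d$age)
    a <- regression_enrichment(d, "y", "grp", "age", family = "linear")
    d2 <- dplyr::mutate(d, age = (age - 55) / 8)
    b <- regression_enrichment(d2, "y", "grp", "age", family = "linear")
    expect_equal(b$estimate, a$estimate, tolerance = 1e-8)
    al <- regression_enrichment(d, "yb", "grp", "age", family = "logistic")
    bl <- regression_enrichment(d2, "yb", "grp", "age", family = "logistic")
    expect_equal(bl$estimate, al$estimate, tolerance = 1e-6)
  })
})

test_that("carrier definition filters on gene, consequence and MAF", {
  dos <- matrix(c(0, 1, 0,
                  0, 0, 2,
                  1, 0, 0), nrow = 3, byrow = TRUE,
                dimnames = list(c("p1", "p2", "p3"), c("v1", "v2", "v3")))
  gt <- structure(list(dosages = dos,
                       effect_allele = c(v1 = "A", v2 = "A", v3 = "A")),
                  class = "genotype_matrix")
  ann <- tibble::tibble(
    variant_id = c("v1", "v2", "v3"),
    gene = c("ACAN", "ACAN", "SHOX"),
    consequence = c("LoF-HC", "LoF-HC", "other"),
    maf = c(0.005, 0.0004, 0.0001)
  )
  # v1 fails the MAF filter, v3 the consequence filter; only v2 qualifies
  out <- define_carriers(gt, ann, c("ACAN", "SHOX"), maf_max = 0.001)
  expect_equal(out$carrier, c(TRUE, FALSE, FALSE))
  expect_equal(attr(out, "qualifying_variants"), "v2")
  # no qualifying variants at all
  none <- define_carriers(gt, ann, "FGFR3")
  expect_false(any(none$carrier))
})

test_that("enrichment panel emits one row per group x trait and skips empty traits", {
  withr::with_seed(85, {
    n <- 3000
    lab <- sample(c("lower", "higher", "concordant"), n, TRUE,
                  prob = c(0.05, 0.05, 0.9))
    cls <- tibble::tibble(id = as.character(1:n), method = "mahalanobis",
                          statistic = 0, p_value = NA_real_,
                          residual_z = NA_real_, label = factor(lab))
    traits <- tibble::tibble(
      id = as.character(1:n),
      t_binary = runif(n) < ifelse(lab == "lower", 0.30, 0.03),
      t_quant = rnorm(n) + (lab == "higher") * 0.8,
      t_empty = NA_real_
    )
    expect_warning(panel <- run_enrichment_panel(cls, traits),
                   "t_empty")
    expect_equal(nrow(panel), 6)
    expect_setequal(unique(panel$group), c("lower", "higher"))
    planted <- dplyr::filter(panel, group == "lower", trait == "t_binary")
    expect_gt(planted$estimate, 5)
    expect_lt(planted$p_value, 0.001)
    qrow <- dplyr::filter(panel, group == "higher", trait == "t_quant")
    expect_equal(qrow$model, "linear")
    expect_gt(qrow$estimate, 0.3)
  })
})

test_that("permuting group labels destroys enrichment", {
  withr::with_seed(86, {
    n <- 800
    grp <- rep(c(TRUE, FALSE), c(80, 720))
    trait <- runif(n) < ifelse(grp, 0.4, 0.05)
    observed <- fisher_enrichment(grp, trait)$p_value
    expect_lt(observed, 1e-6)
    perm_p <- replicate(200, fisher_enrichment(sample(grp), trait)$p_value)
    # permuted p-values behave like a null sample: no excess of small values
    expect_lt(abs(mean(perm_p < 0.25) - 0.25), 0.12)
    expect_gt(mean(perm_p), 0.35)
  })
})
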