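# shared helpers: tiny in-code fixtures and independent oracles

std1 <- function(x) (x - mean(x)) / sd(x)

# a minimal scored cohort built directly from a bivariate normal
make_scored <- function(n, rho, seed = 1) {
  withr::with_seed(seed, {
    ps <- rnorm(n)
    ph <- rho * ps + sqrt(1 - rho^2) * rnorm(n)
    tibble::tibble(id = sprintf("i%05d", seq_len(n)),
                   ps_std = (ps - mean(ps)) / sd(ps),
                   pheno_std = (ph - mean(ph)) / sd(ph))
  })
}

# brute-force 2x2 Mahalanobis oracle: explicit inverse of [[a,b],[b,d]]
mahal_oracle <- function(x, mu, sigma) {
  a <- sigma[1, 1]; b <- sigma[1, 2]; d <- sigma[2, 2]
  det <- a * d - b * b
  dx <- x[, 1] - mu[1]; dy <- x[, 2] - mu[2]
  (d * dx^2 - 2 * b * dx * dy + a * dy^2) / det
}

# independent conditional-MLE odds ratio + exact two-sided p for a 2x2 table,
# by direct noncentral-hypergeometric enumeration
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; cs <- a + c
  klo <- max(0, cs - m2); khi <- min(cs, m1)
  ks <- klo:khi
  logw <- lchoose(m1, ks) + lchoose(m2, cs - ks)
  # two-sided p at the null (psi = 1): sum of point probs <= observed
  pr <- exp(logw - max(logw)); pr <- pr / sum(pr)
  p <- sum(pr[pr <= pr[ks == a] * (1 + 1e-7)])
  # conditional MLE: solve E_psi[K] = a
  if (a == klo) {
    or <- 0
  } else if (a == khi) {
    or <- Inf
  } else {
    f <- function(logpsi) {
      w <- logw + ks * logpsi
      w <- exp(w - max(w)); w <- w / sum(w)
      sum(ks * w) - a
    }
    or <- exp(stats::uniroot(f, c(-50, 50), tol = 1e-12)$root)
  }
  list(or = or, p = p)
}

# direct-counting oracle for the rank-matched empirical p-value
grs_rank_oracle <- function(data, reference, alpha) {
  ord <- order(data$ps_std, data$id)
  n_reps <- nrow(reference)
  p <- numeric(nrow(data))
  for (k in seq_len(nrow(data))) {
    col <- reference[, k]
    med <- stats::median(col)
    r <- sum(abs(col - med) >= abs(data$pheno_std[ord][k] - med))
    p[ord[k]] <- (r + 1) / (n_reps + 1)
  }
  p
}
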