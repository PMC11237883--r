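test_that("modified Pearson implements the pooled-mean formula verbatim", {
  set.seed(1)
  for (k in 1:5) {
    x1 <- rnorm(10); x2 <- rnorm(10)
    n <- 10
    cc <- sum(x1 + x2) / (2 * n)
    S2 <- (sum((x1 - cc)^2) + sum((x2 - cc)^2)) / (2 * n)
    direct <- sum((x1 - cc) * (x2 - cc)) / (n * S2)
    expect_equal(modified_pearson(x1, x2), direct, tolerance = 1e-12)
    # symmetry and shift invariance
    expect_equal(modified_pearson(x1, x2), modified_pearson(x2, x1))
    expect_equal(modified_pearson(x1 + 3, x2 + 3),
                 modified_pearson(x1, x2), tolerance = 1e-10)
  }
  x <- rnorm(8)
  expect_equal(modified_pearson(x, x), 1)
  cc <- mean(x)
  expect_equal(modified_pearson(x, 2 * cc - x), -1, tolerance = 1e-12)
  expect_error(modified_pearson(rep(1, 5), rep(1, 5)), "variance")
})

test_that("ANOVA ICC matches a sums-of-squares oracle and edge cases", {
  y <- matrix(c(1.0, 1.2, 0.9, 1.1,
                5.0, 5.3, 4.8, 5.1,
                9.2, 9.0, 9.1, 9.3), 3, 4, byrow = TRUE)
  k <- 4; n <- 3
  gm <- rowMeans(y)
  msb <- k * sum((gm - mean(y))^2) / (n - 1)
  msw <- sum((y - gm)^2) / (n * (k - 1))
  icc_direct <- max((msb - msw) / k, 0) / (max((msb - msw) / k, 0) + msw)
  expect_equal(icc_anova(y), icc_direct, tolerance = 1e-10)
  # zero within-group variance, distinct means -> 1
  y1 <- matrix(rep(c(1, 5, 9), each = 4), 3, 4, byrow = TRUE)
  expect_equal(icc_anova(y1), 1)
  # common distribution -> near 0 with many replicates
  set.seed(2)
  y0 <- matrix(rnorm(5 * 200), 5, 200)
  expect_lt(icc_anova(y0), 0.05)
  expect_error(icc_anova(matrix(1, 1, 4)), "groups")
})

test_that("compound symmetry covariance structure and eigenvalues", {
  S <- compound_symmetry_covariance(1, 0.5, 2)
  expect_equal(S, matrix(c(1, 0.5, 0.5, 1), 2))
  expect_equal(compound_symmetry_covariance(2, 0, 4), diag(2, 4))
  n <- 5; s2 <- 1.5; rho <- 0.4
  ev <- sort(eigen(compound_symmetry_covariance(s2, rho, n),
                   symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(ev, sort(c(s2 * (1 + (n - 1) * rho),
                          rep(s2 * (1 - rho), n - 1))), tolerance = 1e-10)
  expect_error(compound_symmetry_covariance(1, 1.1, 3), "range")
  expect_error(compound_symmetry_covariance(1, -0.6, 3), "range")
  # boundary of positive definiteness
  expect_silent(compound_symmetry_covariance(1, -0.49, 3))
})

test_that("covariance components recover the interclass correlation", {
  ok_high <- 0L
  ok_null <- 0L
  for (s in 1:20) {
    ph <- generate_evidence_pairs(14, 0.9, sigma2 = 4, seed = s)
    fh <- fit_covariance_components(ph)
    ok_high <- ok_high + (fh$rho >= 0.7 && fh$rho < 1)
    pn <- generate_evidence_pairs(14, 0, sigma2 = 4, seed = 500 + s)
    fn <- fit_covariance_components(pn)
    ok_null <- ok_null + (abs(fn$rho) < 0.3)
  }
  expect_gte(ok_high, 16L) # >= 80%
  expect_gte(ok_null, 16L)
})

test_that("a noiseless linear relation is recovered at GLS precision", {
  set.seed(9)
  k2 <- rnorm(12, 5, 2)
  beta <- 1.7
  k1 <- beta * k2
  pair <- evidence_pair(k1, k2)
  n <- 12
  X <- cbind(slope = c(k2, rep(0, n)), mean2 = rep(c(0, 1), c(n, n)))
  fit <- fit_covariance_components(pair, include_cs = FALSE, design = X)
  expect_equal(unname(fit$beta["slope"]), beta, tolerance = 1e-6)
})

test_that("identical vectors cap the hyperparameters rather than fail", {
  x <- rnorm(10, 100, 5)
  fit <- fit_covariance_components(evidence_pair(x, x))
  expect_true(is.finite(fit$free_energy))
  expect_gt(fit$rho, 0.99)
})

test_that("evidence comparison separates correlated and independent pairs", {
  hits <- 0L; nulls <- 0L
  for (s in 1:15) {
    ch <- compare_evidence_reliability(
      generate_evidence_pairs(14, 0.9, sigma2 = 4, seed = 100 + s))
    hits <- hits + ch$favours_cs
    cn <- compare_evidence_reliability(
      generate_evidence_pairs(14, 0, sigma2 = 4, seed = 200 + s))
    nulls <- nulls + cn$favours_cs
  }
  expect_gte(hits, 14L)
  expect_lte(nulls, 1L)
})

test_that("model selection consistency improves with n", {
  rate <- function(n) {
    mean(vapply(1:12, function(s)
      compare_evidence_reliability(
        generate_evidence_pairs(n, 0.7, sigma2 = 2,
                                seed = 300 + s))$favours_cs, TRUE))
  }
  r8 <- rate(8); r64 <- rate(64)
  expect_gte(r64, r8)
  expect_gte(r64, 0.9)
})

test_that("evidence pairs round-trip through CSV", {
  p <- generate_evidence_pairs(6, 0.5, seed = 1)
  f <- tempfile(fileext = ".csv")
  write_evidence_csv(p, f)
  q <- read_evidence_csv(f)
  expect_equal(q$k1, p$k1)
  expect_equal(q$k2, p$k2)
  unlink(f)
})
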