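test_that("free energy equals the analytic log evidence at the exact posterior", {
  for (seed in c(1, 2, 3)) {
    pr <- linear_problem(seed)
    gls <- linear_gls(pr)
    q <- param_density(stats::setNames(gls$mean, names(pr$prior$mean)),
                       gls$cov)
    Fq <- free_energy(pr$y, q, pr$prior, pr$model,
                      lambda = log(pr$tau), config = pr$config)
    expect_equal(Fq, linear_log_evidence(pr), tolerance = 1e-6)
    # at q = prior the KL term vanishes: F is pure (expected) accuracy
    Fp <- free_energy(pr$y, pr$prior, pr$prior, pr$model,
                      lambda = log(pr$tau), config = pr$config)
    e <- pr$y - drop(pr$A %*% pr$prior$mean)
    acc <- -0.5 * pr$tau * sum(e^2) +
      0.5 * length(e) * log(pr$tau) -
      0.5 * length(e) * log(2 * pi) -
      0.5 * pr$tau * sum(diag(pr$A %*% pr$prior$cov %*% t(pr$A)))
    expect_equal(Fp, acc, tolerance = 1e-8)
  }
})

test_that("noise-variance changes move F by the Gaussian normalisation", {
  pr <- linear_problem(4)
  q <- do.call(function(mean, cov) param_density(
    stats::setNames(mean, names(pr$prior$mean)), cov), linear_gls(pr))
  F1 <- free_energy(pr$y, q, pr$prior, pr$model, lambda = log(pr$tau),
                    config = pr$config)
  # inflating the noise variance (lambda -> lambda - ln 2) changes the
  # Gaussian terms by a closed-form amount at fixed q
  F2 <- free_energy(pr$y, q, pr$prior, pr$model,
                    lambda = log(pr$tau) - log(2), config = pr$config)
  e <- pr$y - drop(pr$A %*% q$mean)
  tr_term <- sum(diag(pr$A %*% q$cov %*% t(pr$A)))
  delta <- -0.5 * (pr$tau / 2 - pr$tau) * (sum(e^2) + tr_term) -
    0.5 * length(e) * log(2)
  expect_equal(F2 - F1, delta, tolerance = 1e-8)
})

test_that("inversion solves the linear-Gaussian problem to GLS precision", {
  for (seed in c(11, 12)) {
    pr <- linear_problem(seed)
    res <- invert(pr$y, pr$prior, pr$model, pr$config)
    gls <- linear_gls(pr)
    expect_lt(max(abs(res$posterior$mean - gls$mean)), 1e-6)
    expect_lt(max(abs(res$posterior$cov - gls$cov)), 1e-6)
    expect_equal(res$free_energy, linear_log_evidence(pr),
                 tolerance = 1e-6)
    expect_true(all(diff(res$trajectory) > -1e-9))
    # posterior variances never exceed the prior in the fully-informed case
    expect_true(all(diag(res$posterior$cov) <=
                      diag(pr$prior$cov) + 1e-10))
  }
})

test_that("a parameter without data influence keeps its prior", {
  set.seed(5)
  A <- cbind(matrix(rnorm(20 * 3), 20, 3), 0) # 4th column ablated
  y <- drop(A %*% c(1, -1, 0.5, 0)) + rnorm(20, 0, 0.3)
  prior <- param_density(stats::setNames(rep(0, 4), paste0("b", 1:4)),
                         diag(0.6, 4))
  res <- invert(y, prior, linear_model_context(A),
                inversion_config(estimate_noise = FALSE,
                                 hyper_mean = log(1 / 0.09)))
  expect_lt(abs(res$posterior$mean["b4"]), 0.05 * sqrt(0.6))
  expect_equal(res$posterior$cov["b4", "b4"], 0.6, tolerance = 1e-6)
})

test_that("noiseless single-region spectra are recovered", {
  set.seed(3)
  pt <- prior_table(net1())
  th_true <- draw_theta(pt, 0.5)
  g <- predict_csd(th_true, pt)
  res <- invert_csd(g, pt, config = inversion_config(max_iterations = 64))
  expect_true(all(diff(res$trajectory) > -1e-9))
  # correlation over identifiable coordinates (posterior clearly updated)
  shrink <- diag(res$posterior$cov) / pt$index$variance
  idf <- shrink < 0.5
  expect_gt(sum(idf), 4)
  expect_gt(stats::cor(th_true[idf], res$posterior$mean[idf]), 0.9)
  # near-perfect fit of the data features
  expect_lt(stats::sd(res$data_features - res$predicted), 1e-3)
})

test_that("inversion is deterministic and serialises", {
  set.seed(9)
  pt <- prior_table(net1())
  g <- predict_csd(draw_theta(pt, 0.3), pt)
  cfg <- inversion_config(max_iterations = 8)
  r1 <- invert_csd(g, pt, config = cfg)
  r2 <- invert_csd(g, pt, config = cfg)
  expect_identical(r1$free_energy, r2$free_energy)
  expect_identical(r1$posterior$mean, r2$posterior$mean)
  f <- tempfile(fileext = ".json")
  write_inversion_json(r1, f)
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(obj$free_energy, r1$free_energy)
  unlink(f)
})
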