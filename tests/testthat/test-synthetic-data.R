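test_that("cohort sampling is seeded, stable and honours the spec", {
  spec <- cohort_spec(n_subjects = 4, n_regions = 1, seed = 11)
  c1 <- sample_cohort(spec)
  c2 <- sample_cohort(spec)
  expect_identical(c1$theta, c2$theta)
  # zero spread and zero session effect: all subjects/sessions identical
  spec0 <- cohort_spec(n_subjects = 3, n_regions = 1,
                       between_subject_sd = 0, seed = 12)
  c0 <- sample_cohort(spec0)
  expect_equal(max(abs(c0$theta)), 0)
  expect_error(cohort_spec(n_subjects = 2, n_regions = 1), "seed")
  expect_error(cohort_spec(n_subjects = 2, n_regions = 1,
                           session_effect = 1, seed = 1), "named")
})

test_that("between-subject spread matches the specification", {
  spec <- cohort_spec(n_subjects = 200, n_regions = 1,
                      between_subject_sd = c(L = 1 / 16), seed = 13)
  coh <- sample_cohort(spec)
  pt <- coh$priors
  # empirical sd of the T family across subjects within 10% of the prior sd
  jT <- which(pt$index$family == "T")
  emp <- apply(coh$theta[, 1, jT], 2, stats::sd)
  expect_true(all(abs(emp / sqrt(1 / 16) - 1) < 0.15))
  # gain family uses the damped spread
  jL <- which(pt$index$family == "L")
  expect_lt(stats::sd(coh$theta[, 1, jL]), 1)
})

test_that("session effects shift only the requested coordinate in session 2", {
  spec <- cohort_spec(n_subjects = 3, n_regions = 1,
                      session_effect = c("T(R1,AMPA)" = 4), seed = 14)
  coh <- sample_cohort(spec)
  d <- coh$theta[, 2, ] - coh$theta[, 1, ]
  j <- which(coh$priors$index$name == "T(R1,AMPA)")
  expect_equal(unname(d[, j]), rep(4 * sqrt(1 / 16), 3))
  expect_equal(max(abs(d[, -j])), 0)
})

test_that("zero observation noise reproduces the prediction exactly", {
  spec <- cohort_spec(n_subjects = 1, n_regions = 1, n_epochs = 3,
                      observation_noise_sd = 0, seed = 15)
  pt <- prior_table(network_spec("R1"))
  th <- zero_theta(pt)
  eps <- simulate_observed_csd(th, spec, pt)
  g0 <- predict_csd(th, pt, freqs = spec$freqs)
  for (e in eps) expect_equal(e$values, g0$values, tolerance = 1e-12)
})

test_that("epoch averages converge to the prediction at the MC rate", {
  pt <- prior_table(network_spec("R1"))
  th <- zero_theta(pt)
  g0 <- predict_csd(th, pt)
  dev <- function(n_ep, seed) {
    spec <- cohort_spec(n_subjects = 1, n_regions = 1, n_epochs = n_ep,
                        observation_noise_sd = 0.05, seed = seed)
    set.seed(seed)
    eps <- simulate_observed_csd(th, spec, pt)
    avg <- average_csd(eps)
    sqrt(mean(abs(avg$values - g0$values)^2))
  }
  d4 <- mean(vapply(1:4, function(s) dev(4, s), 1))
  d64 <- mean(vapply(1:4, function(s) dev(64, 100 + s), 1))
  expect_lt(d64, d4 / 2.2) # ~ sqrt(16) = 4 expected; allow slack
  # every emitted slice Hermitian PSD
  spec <- cohort_spec(n_subjects = 1, n_regions = 1, n_epochs = 2,
                      observation_noise_sd = 0.5, seed = 16)
  set.seed(16)
  eps <- simulate_observed_csd(th, spec, pt)
  for (e in eps) for (k in c(1, 30)) {
    s <- e$values[k, , , drop = FALSE][1, , ]
    ev <- Re(eigen(matrix(s, 1), only.values = TRUE)$values)
    expect_gte(min(ev), -1e-10)
  }
})

test_that("odd/even split partitions the epochs", {
  pt <- prior_table(network_spec("R1"))
  spec <- cohort_spec(n_subjects = 1, n_regions = 1, n_epochs = 10,
                      observation_noise_sd = 0.1, seed = 17)
  set.seed(17)
  eps <- simulate_observed_csd(zero_theta(pt), spec, pt)
  sp <- split_epoch_features(eps)
  manual_odd <- average_csd(eps[seq(1, 9, 2)])
  expect_equal(sp$odd$values, manual_odd$values, tolerance = 1e-12)
  expect_equal(sp$odd$label$split, "odd")
  expect_error(split_epoch_features(eps[1]), "2 epochs")
  # identical epochs give identical split averages
  sp0 <- split_epoch_features(rep(eps[1], 4))
  expect_equal(sp0$odd$values, sp0$even$values)
})

test_that("evidence-pair generator matches its covariance specification", {
  p9 <- generate_evidence_pairs(2000, 0.9, seed = 1)
  expect_lt(abs(stats::cor(p9$k1, p9$k2) - 0.9), 0.05)
  p0 <- generate_evidence_pairs(2000, 0, seed = 2)
  expect_lt(abs(stats::cor(p0$k1, p0$k2)), 0.05)
  expect_identical(generate_evidence_pairs(10, 0.5, seed = 3),
                   generate_evidence_pairs(10, 0.5, seed = 3))
  expect_error(generate_evidence_pairs(10, 1.2, seed = 1), "range")
})
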