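test_that("build_design prepends a ones column and checks rank", {
  X <- build_design(3)
  expect_equal(dim(X), c(3L, 1L))
  expect_true(all(X[, 1] == 1))
  X2 <- build_design(4, covariates = list(group = c(0, 0, 1, 1)))
  expect_equal(colnames(X2), c("mean", "group"))
  expect_equal(X2[, "group"], c(0, 0, 1, 1))
  expect_error(build_design(4, covariates = list(g = c(1, 1, 1, 1))),
               "rank deficient")
  expect_error(build_design(4, covariates = list(g = c(1, 2))), "length")
})

test_that("second-level precision has the stated Kronecker structure", {
  cfg <- peb_config(Q0 = 1e-6, Q1_scale = 16)
  p <- 3; n <- 4
  for (gamma in c(-1, 0, 2)) {
    P <- second_level_precision(gamma, cfg, p, n)
    blk <- diag(1e-6, p) + exp(-gamma) * diag(16, p)
    brute <- matrix(0, n * p, n * p)
    for (i in seq_len(n))
      brute[(i - 1) * p + 1:p, (i - 1) * p + 1:p] <- blk
    expect_equal(P, brute, tolerance = 1e-12)
    expect_true(all(eigen(P, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  }
  # gamma -> +Inf leaves only the floor
  expect_equal(second_level_precision(60, cfg, 2, 2),
               diag(1e-6, 4), tolerance = 1e-9)
  expect_error(second_level_precision(0, cfg, 2, 2,
                                      Q1 = matrix(c(1, 2, 2, 1), 2)),
               "PSD")
})

# dense linear-Gaussian oracle for the PEB hierarchy at fixed gamma:
# theta2 ~ N(m2, S2); theta1_i | theta2 ~ N((x_i' (x) I) theta2, Sb);
# evidence about theta1_i carried by precision Pi and shift r_i.
peb_oracle <- function(qs, prior, X, gamma, Q0 = 1e-6, Q1_scale = 16) {
  p <- prior$n
  n <- length(qs)
  r <- ncol(X)
  P0 <- solve(prior$cov)
  Pb <- diag(Q0, p) + exp(-gamma) * Q1_scale * P0
  Sb <- solve(Pb)
  m2 <- c(prior$mean, rep(0, (r - 1) * p))
  S2 <- diag(r) %x% prior$cov
  W <- X %x% diag(p) # np x rp
  # marginal over theta1: theta1 ~ N(W theta2, I (x) Sb)
  prec_data <- matrix(0, n * p, n * p)
  shift <- numeric(n * p)
  for (i in seq_len(n)) {
    Pq <- solve(qs[[i]]$cov)
    Pi <- Pq - P0
    idx <- (i - 1) * p + 1:p
    prec_data[idx, idx] <- Pi
    shift[idx] <- drop(Pq %*% qs[[i]]$mean - P0 %*% prior$mean)
  }
  # p(theta2 | data) with theta1 marginalised:
  # cov of implied observation about W theta2 is Sb + pinv(Pi); work in the
  # joint over theta1 instead to avoid inverting Pi
  Sb_full <- diag(n) %x% Sb
  # posterior over theta1 given theta2: combine prec_data with Pb
  # evidence for theta2: N-form marginalisation
  A <- solve(prec_data + solve(Sb_full))
  G <- t(W) %*% (solve(Sb_full) -
                   solve(Sb_full) %*% A %*% solve(Sb_full)) %*% W
  g <- t(W) %*% solve(Sb_full) %*% A %*% shift
  Ppost <- solve(S2) + G
  Spost <- solve(Ppost)
  mpost <- drop(Spost %*% (g + solve(S2) %*% m2))
  list(mean = mpost, cov = Spost)
}

test_that("fit_peb matches the dense Gaussian oracle at pinned gamma", {
  set.seed(2)
  p <- 3
  nm <- paste0("b", 1:p)
  prior <- param_density(stats::setNames(rep(0, p), nm), diag(0.8, p))
  qs <- lapply(1:5, function(i) {
    S <- crossprod(matrix(rnorm(p * p, 0, 0.2), p)) + diag(0.1, p)
    S <- S * 0.4
    param_density(stats::setNames(rnorm(p, 0, 0.4), nm), S)
  })
  X <- build_design(5, covariates = list(g = c(0, 0, 0, 1, 1)))
  cfg <- peb_config(gamma_mean = 0, gamma_var = 1e-10) # pin gamma at 0
  fit <- fit_peb(qs, X, prior, config = cfg)
  orc <- peb_oracle(qs, prior, X, gamma = 0)
  # note: oracle orders theta2 subject-major via X %x% I; fit uses the
  # same column-block convention
  expect_lt(max(abs(unname(fit$second_level_posterior$mean) - orc$mean)),
            1e-4)
  expect_lt(max(abs(unname(fit$second_level_posterior$cov) - orc$cov)),
            1e-4)
})

test_that("degenerate single-subject PEB tracks the first-level posterior", {
  p <- 3
  nm <- paste0("b", 1:p)
  prior <- param_density(stats::setNames(rep(0, p), nm), diag(1, p))
  q <- param_density(stats::setNames(c(0.5, -0.2, 0.1), nm), diag(0.2, p))
  fit <- fit_peb(list(q), build_design(1), prior)
  expect_lt(max(abs(fit$second_level_posterior$mean[1:p] - q$mean)), 0.05)
})

test_that("subject permutation leaves the PEB posterior unchanged", {
  set.seed(3)
  p <- 2
  nm <- paste0("b", 1:p)
  prior <- param_density(stats::setNames(rep(0, p), nm), diag(1, p))
  qs <- lapply(1:6, function(i)
    param_density(stats::setNames(rnorm(p, 0, 0.4), nm), diag(0.3, p)))
  f1 <- fit_peb(qs, build_design(6), prior)
  f2 <- fit_peb(qs[c(4, 2, 6, 1, 3, 5)], build_design(6), prior)
  expect_equal(f1$second_level_posterior$mean,
               f2$second_level_posterior$mean, tolerance = 1e-8)
  expect_equal(f1$free_energy, f2$free_energy, tolerance = 1e-6)
})

test_that("PEB pooling beats no pooling for cohorts sharing a mean", {
  set.seed(4)
  p <- 3
  nm <- paste0("b", 1:p)
  prior <- param_density(stats::setNames(rep(0, p), nm), diag(1, p))
  wins <- 0L
  for (rep in 1:8) {
    mu_g <- rnorm(p, 0, 0.6)
    qs <- lapply(1:8, function(i)
      param_density(stats::setNames(mu_g + rnorm(p, 0, 0.25), nm),
                    diag(0.2, p)))
    fit <- fit_peb(qs, build_design(8), prior)
    # "no pooling": between-subject covariance pinned at the full prior,
    # i.e. exp(-gamma) * 16 P0 + Q0 = P0  =>  gamma = log(16)
    cfg_np <- peb_config(gamma_mean = log(16), gamma_var = 1e-10)
    fit_np <- fit_peb(qs, build_design(8), prior, config = cfg_np)
    wins <- wins + (fit$free_energy > fit_np$free_energy)
  }
  expect_gte(wins, 6L)
})

test_that("covariate effects are recovered by the second level", {
  set.seed(6)
  p <- 2
  nm <- paste0("b", 1:p)
  prior <- param_density(stats::setNames(rep(0, p), nm), diag(1, p))
  covered <- 0L
  for (rep in 1:20) {
    beta <- 0.8 # true effect of the covariate on b1
    xg <- rep(c(0, 1), each = 5)
    qs <- lapply(1:10, function(i)
      param_density(stats::setNames(c(0.2 + beta * xg[i], -0.1) +
                                      rnorm(p, 0, 0.15), nm),
                    diag(0.1, p)))
    fit <- fit_peb(qs, build_design(10, covariates = list(g = xg)), prior)
    q2 <- fit$second_level_posterior
    j <- which(q2$index$name == "g:b1")
    lo <- q2$mean[j] - 1.645 * sqrt(q2$cov[j, j])
    hi <- q2$mean[j] + 1.645 * sqrt(q2$cov[j, j])
    covered <- covered + (beta >= lo && beta <= hi)
  }
  expect_gte(covered, 16L) # 90% CI coverage in >= 80% of replicates
})

test_that("null PEB-of-PEBs rarely flags and injected effects are found", {
  set.seed(8)
  p <- 4
  nm <- paste0("b", 1:p)
  prior <- param_density(stats::setNames(rep(0, p), nm), diag(0.5, p))
  n_flag_null <- 0L
  n_total <- 0L
  found <- 0L
  for (s in 1:10) {
    make_group <- function(shift = 0) {
      mu <- rnorm(p, 0, 0.3)
      lapply(1:6, function(i) {
        m <- mu + rnorm(p, 0, 0.2)
        m[2] <- m[2] + shift
        param_density(stats::setNames(m, nm), diag(0.15, p))
      })
    }
    g1 <- fit_peb(make_group(), build_design(6), prior)
    g2 <- fit_peb(make_group(), build_design(6), prior)
    p3 <- peb_of_pebs(list(g1, g2), prior)
    fl <- flag_differences(p3)
    n_flag_null <- n_flag_null + nrow(fl)
    n_total <- n_total + p
    # now inject 4 prior sd on b2 in the second group
    g2b <- fit_peb(make_group(shift = 4 * sqrt(0.5)), build_design(6),
                   prior)
    p3b <- peb_of_pebs(list(g1, g2b), prior)
    flb <- flag_differences(p3b)
    found <- found + ("group:b2" %in% flb$parameter)
  }
  expect_lte(n_flag_null / n_total, 0.05 + 0.08) # null rate + MC slack
  expect_gte(found, 9L)
})

test_that("flag_differences reports intervals and respects its contract", {
  p <- 3
  nm <- paste0("b", 1:p)
  prior <- param_density(stats::setNames(rep(0, p), nm), diag(1, p))
  qs1 <- lapply(1:4, function(i)
    param_density(stats::setNames(rep(0, p), nm), diag(0.2, p)))
  f1 <- fit_peb(qs1, build_design(4), prior)
  f2 <- fit_peb(qs1, build_design(4), prior)
  p3 <- peb_of_pebs(list(f1, f2), prior)
  fl <- flag_differences(p3)
  expect_equal(nrow(fl), 0L) # identical groups: nothing flagged
  all_tab <- attr(fl, "all")
  expect_equal(nrow(all_tab), p)
  expect_true(all(all_tab$lower <= all_tab$upper))
  expect_error(flag_differences(f1), "no effect column")
})
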