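# shared fixtures: everything is generated in code, no data files

net1 <- function() network_spec("R1")
net2 <- function() network_spec(c("R1", "R2"))
net4 <- function() network_spec(c("LAG", "RAG", "MPFC", "PCC"))

zero_theta <- function(pt) stats::setNames(rep(0, pt$n), pt$index$name)

# random log-scale deviations at a fraction of the prior sd
draw_theta <- function(pt, frac = 0.5) {
  stats::setNames(stats::rnorm(pt$n, 0, frac * sqrt(pt$index$variance)),
                  pt$index$name)
}

# small conjugate linear-Gaussian problem with known noise precision
linear_problem <- function(seed, p = 4, nobs = 12, tau = 4,
                           prior_var = 0.5) {
  set.seed(seed)
  A <- matrix(stats::rnorm(nobs * p), nobs, p)
  theta <- stats::rnorm(p)
  y <- drop(A %*% theta) + stats::rnorm(nobs, 0, 1 / sqrt(tau))
  nm <- paste0("b", seq_len(p))
  list(A = A, y = y, theta = theta, tau = tau,
       prior = param_density(stats::setNames(rep(0, p), nm),
                             diag(prior_var, p)),
       model = linear_model_context(A),
       config = inversion_config(estimate_noise = FALSE,
                                 hyper_mean = log(tau)))
}

# analytic log evidence of the linear problem: y ~ N(0, A S0 A' + I/tau)
linear_log_evidence <- function(pr) {
  C <- pr$A %*% pr$prior$cov %*% t(pr$A) + diag(1 / pr$tau, length(pr$y))
  -0.5 * length(pr$y) * log(2 * pi) -
    0.5 * as.numeric(determinant(C)$modulus) -
    0.5 * drop(pr$y %*% solve(C, pr$y))
}

# exact GLS posterior of the linear problem
linear_gls <- function(pr) {
  P <- pr$tau * crossprod(pr$A) + solve(pr$prior$cov)
  m <- solve(P, pr$tau * crossprod(pr$A, pr$y))
  list(mean = drop(m), cov = solve(P))
}

# finite-difference jacobian of the flow (independent oracle)
fd_flow_jacobian <- function(x0, params, net, constants, h = 1e-6) {
  n <- length(x0)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    xp <- x0; xp[j] <- xp[j] + h
    xm <- x0; xm[j] <- xm[j] - h
    J[, j] <- (state_derivatives(xp, 0, params, net, constants) -
                 state_derivatives(xm, 0, params, net, constants)) / (2 * h)
  }
  J
}
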