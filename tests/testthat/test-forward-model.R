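test_that("scale_parameters reproduces the scaling constants at theta = 0", {
  pt <- prior_table(net2())
  p <- scale_parameters(zero_theta(pt), pt)
  expect_equal(unname(p$T[["R1"]]), c(4, 16, 100))
  expect_equal(unname(p$C[["R1"]]), c(128, 128, 256, 32) / 1000)
  expect_equal(unname(p$D), c(2, 16))
  expect_equal(unname(p$L), c(1, 1))
  # extrinsic scale 1/8 per edge
  expect_true(all(abs(unlist(p$A) - 1 / 8) < 1e-12))
  expect_equal(unname(p$H[["R2"]]), unname(default_H_template()))
})

test_that("scale_parameters applies exp scaling coordinate-wise", {
  pt <- prior_table(net1())
  th <- zero_theta(pt)
  th["T(R1,AMPA)"] <- log(2)
  p <- scale_parameters(th, pt)
  expect_equal(unname(p$T[["R1"]]), c(8, 16, 100))
  expect_error(scale_parameters(c(bogus = 1), pt), "not indexed")
})

test_that("magnesium switch has the stated value, limits and monotonicity", {
  cs <- model_constants()
  expect_equal(magnesium_switch(0, cs), 1 / 1.2, tolerance = 1e-12)
  expect_lt(magnesium_switch(-1e4, cs), 1e-10)
  expect_gt(magnesium_switch(1e4, cs), 1 - 1e-10)
  v <- seq(-100, 100, by = 0.5)
  expect_true(all(diff(magnesium_switch(v, cs)) > 0))
})

test_that("firing sigmoid is half at threshold with maximal slope there", {
  cs <- model_constants()
  expect_equal(firing_rate(cs$sigmoid_threshold, cs), 0.5)
  expect_lt(firing_rate(-1e4, cs), 1e-10)
  v <- seq(cs$sigmoid_threshold - 20, cs$sigmoid_threshold + 20, by = 0.1)
  s <- firing_rate(v, cs)
  d <- diff(s) / 0.1
  expect_equal(v[which.max(d)], cs$sigmoid_threshold - 0.05,
               tolerance = 0.2)
  expect_true(all(s >= 0 & s <= 1))
})

test_that("reversal-potential ordering is enforced", {
  expect_error(model_constants(VGABA = -60), "VGABA < VL")
  expect_error(model_constants(alpha_nmda = -1), "alpha_nmda")
})

test_that("leak-only flow reduces to gL(VL - V)/C and scales with 1/C", {
  pt <- prior_table(net1(), H_template = matrix(0, 4, 4))
  cs <- model_constants()
  p <- scale_parameters(zero_theta(pt), pt)
  net <- net1()
  x <- numeric(16)
  x[seq(1, 16, 4)] <- -50 # depolarised, zero conductances
  dx <- state_derivatives(x, 0, p, net, cs)
  iV <- seq(1, 16, 4)
  expect_equal(dx[iV], cs$gL * (cs$VL - (-50)) / unname(p$C[["R1"]]),
               tolerance = 1e-12)
  th2 <- zero_theta(pt)
  th2[grep("^C", names(th2))] <- log(2)
  p2 <- scale_parameters(th2, pt)
  dx2 <- state_derivatives(x, 0, p2, net, cs)
  expect_equal(dx2[iV], dx[iV] / 2, tolerance = 1e-12)
})

test_that("fixed point satisfies the flow and is deterministic", {
  pt <- prior_table(net2())
  p <- scale_parameters(zero_theta(pt), pt)
  cs <- model_constants()
  x0 <- find_fixed_point(p, net2(), cs)
  expect_lt(max(abs(state_derivatives(x0, 0, p, net2(), cs))), 1e-6)
  expect_identical(x0, find_fixed_point(p, net2(), cs))
  # isolated leak-only population settles at VL
  pt0 <- prior_table(net1(), H_template = matrix(0, 4, 4))
  p0 <- scale_parameters(zero_theta(pt0), pt0)
  x00 <- find_fixed_point(p0, net1(), cs)
  expect_equal(x00[seq(1, 16, 4)], rep(cs$VL, 4), tolerance = 1e-6)
})

test_that("prior-mean models are stable for 1, 2 and 4 regions", {
  cs <- model_constants()
  for (net in list(net1(), net2(), net4())) {
    pt <- prior_table(net)
    p <- scale_parameters(zero_theta(pt), pt)
    x0 <- find_fixed_point(p, net, cs)
    J <- system_jacobian(p, net, x0, cs)
    expect_lt(max(Re(eigen(J, only.values = TRUE)$values)), 0)
  }
})

test_that("analytic Jacobian matches finite differences over random draws", {
  cs <- model_constants()
  net <- net2()
  pt <- prior_table(net)
  set.seed(101)
  checked <- 0L
  excluded <- 0L
  for (k in 1:100) {
    th <- draw_theta(pt, 2)   # within +-2 prior sd on average
    p <- scale_parameters(th, pt)
    x0 <- tryCatch(find_fixed_point(p, net, cs), error = function(e) NULL)
    if (is.null(x0)) { excluded <- excluded + 1L; next }
    Ja <- dcmrel:::raw_jacobian(x0, p, net, cs)
    if (max(Re(eigen(dcmrel:::raw_jacobian(x0, p, net, cs),
                     only.values = TRUE)$values)) >= 0) {
      excluded <- excluded + 1L
      next
    }
    Jf <- fd_flow_jacobian(x0, p, net, cs)
    rel <- max(abs(Ja - Jf)) / max(abs(Ja))
    expect_lt(rel, 1e-5)
    checked <- checked + 1L
  }
  expect_gt(checked, 50) # the stable majority is actually checked
})

test_that("delay correction is neutral at zero delays and reported singular", {
  net <- net2()
  pt <- prior_table(net)
  cs <- model_constants()
  p <- scale_parameters(zero_theta(pt), pt)
  x0 <- find_fixed_point(p, net, cs)
  p0 <- p
  p0$D[] <- 0
  J_raw <- dcmrel:::raw_jacobian(x0, p0, net, cs)
  expect_equal(system_jacobian(p0, net, x0, cs), J_raw, tolerance = 1e-12)
  # without extrinsic connections the Jacobian is block diagonal
  thA <- zero_theta(pt)
  pA <- scale_parameters(thA, pt)
  pA$A[] <- 0
  pA$AN[] <- 0
  xA <- find_fixed_point(pA, net, cs)
  JA <- dcmrel:::raw_jacobian(xA, pA, net, cs)
  expect_equal(max(abs(JA[1:16, 17:32])), 0)
  expect_equal(max(abs(JA[17:32, 1:16])), 0)
})

test_that("transfer function matches the one-state Lorentzian oracle", {
  # all intrinsic connections removed: the spiny-stellate depolarisation is
  # a single leaky state driven by u, so K = L*Jss / (i w + gL/C)
  pt <- prior_table(net1(), H_template = matrix(0, 4, 4))
  cs <- model_constants()
  p <- scale_parameters(zero_theta(pt), pt)
  freqs <- c(1, 5, 10, 40)
  tf <- transfer_function(p, net1(), freqs, cs)
  lam <- cs$gL / p$C[["R1"]][["ss"]]
  gain <- p$L[["R1"]] * p$J[["R1"]][["ss"]]
  om <- 2 * pi * freqs / 1000
  expect_equal(abs(tf$K[, 1, 1])^2, gain^2 / (lam^2 + om^2),
               tolerance = 1e-8)
  # DC limit: K(0) = -W J^-1 B; here 1/lam scaled by the gain
  x0 <- find_fixed_point(p, net1(), cs)
  J <- system_jacobian(p, net1(), x0, cs)
  tf0 <- dcmrel:::transfer_from_jacobian(J, p, net1(), 1e-9)
  expect_equal(Re(tf0[1, 1, 1]), gain / lam, tolerance = 1e-6)
  # conjugate symmetry
  tfm <- dcmrel:::transfer_from_jacobian(J, p, net1(), c(-10, 10))
  expect_equal(tfm[1, 1, 1], Conj(tfm[2, 1, 1]), tolerance = 1e-12)
})

test_that("input spectrum follows the power-law x cosine form", {
  freqs <- seq(1, 64)
  g0 <- input_spectrum(c(0, 0), rep(0, 4), freqs)
  expect_equal(g0, 1 / freqs)
  g2 <- input_spectrum(c(log(2), 0), rep(0, 4), freqs)
  expect_equal(g2, 2 * g0)
  expect_error(input_spectrum(c(0, 0), rep(0, 4), c(-1, 2)), "positive")
  set.seed(7)
  for (k in 1:50) {
    a <- rnorm(2, 0, 3 / sqrt(128))
    d <- rnorm(4, 0, 3 / sqrt(128))
    expect_true(all(input_spectrum(a, d, freqs) > 0))
  }
})

test_that("noise spectrum is Hermitian PSD with common + specific structure", {
  freqs <- seq(1, 32)
  go <- noise_spectrum(c(0, 0), c(log(0.5), 0), c(0, 0), freqs, 3)
  for (k in c(1, 16, 32)) {
    s <- go[k, , ]
    expect_equal(s, Conj(t(s)))
    expect_gte(min(eigen(s, symmetric = TRUE, only.values = TRUE)$values),
               -1e-12)
    expect_equal(s[1, 2], s[1, 3]) # common term identical across pairs
  }
  go2 <- noise_spectrum(c(log(2), 0), c(log(0.5), 0), c(0, 0), freqs, 3)
  expect_equal(go2[, 1, 2], 2 * go[, 1, 2]) # amplitude + ln 2 doubles common
  set.seed(8)
  for (k in 1:20) {
    b <- rnorm(2, 0, 3 / sqrt(128)); cc <- rnorm(2, 0, 3 / sqrt(128))
    g <- noise_spectrum(b, cc, c(0, 0), c(2, 13), 4)
    ev <- eigen(g[1, , ], symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-12)
  }
})

test_that("predicted CSD slices are Hermitian PSD and engines agree", {
  pt <- prior_table(net2())
  set.seed(33)
  th <- draw_theta(pt, 0.3)
  g_cpp <- predict_csd(th, pt, engine = "cpp")
  g_r <- predict_csd(th, pt, engine = "R")
  expect_equal(g_cpp$values, g_r$values, tolerance = 1e-10)
  for (k in seq_along(g_cpp$frequencies)) {
    s <- g_cpp$values[k, , ]
    expect_lt(max(abs(s - Conj(t(s)))), 1e-10 * max(abs(s)))
    ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(Re(ev)), -1e-10)
    expect_true(all(Re(diag(s)) >= 0))
  }
})

test_that("removing extrinsic connections factorises the predicted CSD", {
  pt <- prior_table(net2())
  cs <- model_constants()
  th <- zero_theta(pt)
  # switch extrinsic connections off on the natural scale
  p <- scale_parameters(th, pt)
  p$A[] <- 0
  p$AN[] <- 0
  freqs <- default_freqs()
  tf <- transfer_function(p, net2(), freqs, cs)
  gu <- input_spectrum(p$a, p$d, freqs)
  go <- noise_spectrum(p$b, p$c, p$f, freqs, 2)
  # cross-region transfer is zero, so cross terms reduce to common noise
  expect_lt(max(abs(tf$K[, 1, 2])), 1e-12)
  expect_lt(max(abs(tf$K[, 2, 1])), 1e-12)
})

test_that("sensor gain scales the neuronal contribution quadratically", {
  pt <- prior_table(net1())
  th <- zero_theta(pt)
  g1 <- predict_csd(th, pt)
  th2 <- th; th2["L(R1,gain)"] <- log(3)
  g2 <- predict_csd(th2, pt)
  pz <- scale_parameters(th, pt)
  go <- noise_spectrum(pz$b, pz$c, pz$f, g1$frequencies, 1)
  neuro1 <- Re(g1$values[, 1, 1]) - go[, 1, 1]
  neuro2 <- Re(g2$values[, 1, 1]) - go[, 1, 1]
  expect_equal(neuro2, 9 * neuro1, tolerance = 1e-8)
})

test_that("zero input spectrum leaves exactly the observation noise", {
  pt <- prior_table(net1())
  cs <- model_constants()
  th <- zero_theta(pt)
  p <- scale_parameters(th, pt)
  freqs <- default_freqs()
  go <- noise_spectrum(p$b, p$c, p$f, freqs, 1)
  # emulate gu -> 0 via a vanishing input amplitude
  th0 <- th; th0["a(1)"] <- -60
  g <- predict_csd(th0, pt)
  expect_equal(Re(g$values[, 1, 1]), Re(go[, 1, 1]), tolerance = 1e-8)
})

test_that("csd container validates Hermitian structure and serialises", {
  vals <- array(complex(real = 1), c(2, 2, 2))
  vals[1, 1, 2] <- 1 + 1i
  vals[1, 2, 1] <- 1 - 1i
  x <- csd(c(10, 20), vals, regions = c("A", "B"),
           label = list(subject = 1))
  expect_s3_class(x, "csd")
  bad <- vals
  bad[1, 1, 2] <- 5 + 2i
  expect_error(csd(c(10, 20), bad), "Hermitian")
  f <- tempfile(fileext = ".json")
  write_csd_json(x, f)
  y <- read_csd_json(f)
  expect_equal(y$values, x$values)
  expect_equal(y$frequencies, x$frequencies)
  unlink(f)
})
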