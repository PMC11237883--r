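# --- assembly of natural-scale coupling structure -------------------------

# Population-level firing->conductance weight matrices (global population
# index, region-major) for the three channel types, together with per-state
# constants. Intrinsic excitatory sources (ss, sp, dp) drive AMPA (plus a
# fixed fraction of NMDA); the inhibitory pool drives GABA. Extrinsic
# forward connections (sp -> ss,dp) and backward connections
# (dp -> sp, 2*inh) carry separate AMPA (A) and NMDA (AN) strengths.
assemble_weights <- function(params, net, constants) {
  R <- net$n_regions
  np <- R * N_POP
  WA <- matrix(0, np, np); WG <- matrix(0, np, np); WN <- matrix(0, np, np)
  pop <- function(r, p) (r - 1L) * N_POP + match(p, POPULATIONS)
  rho <- constants$nmda_intrinsic_ratio
  for (r in seq_len(R)) {
    H <- params$H[[r]]
    for (i in seq_len(N_POP)) for (j in seq_len(N_POP)) {
      if (H[i, j] == 0) next
      if (POPULATIONS[j] == "inh") {
        WG[pop(r, POPULATIONS[i]), pop(r, POPULATIONS[j])] <- H[i, j]
      } else {
        WA[pop(r, POPULATIONS[i]), pop(r, POPULATIONS[j])] <- H[i, j]
        WN[pop(r, POPULATIONS[i]), pop(r, POPULATIONS[j])] <-
          rho * H[i, j]
      }
    }
  }
  masks <- extrinsic_masks()
  for (type in c("forward", "backward")) {
    ed <- net[[type]]
    msk <- masks[[type]]
    for (k in seq_len(nrow(ed))) {
      lab <- paste0(type, ":", ed[k, 1], "->", ed[k, 2])
      rf <- region_id(net, ed[k, 1]); rt <- region_id(net, ed[k, 2])
      src <- pop(rf, msk$source)
      for (p in POPULATIONS) {
        w <- msk$targets[[p]]
        if (w == 0) next
        WA[pop(rt, p), src] <- WA[pop(rt, p), src] + w * params$A[[lab]] * 8
        WN[pop(rt, p), src] <- WN[pop(rt, p), src] + w * params$AN[[lab]] * 8
      }
    }
  }
  # per-population constants (region-major ordering)
  Cvec <- unlist(lapply(params$C, unname), use.names = FALSE)
  tau <- do.call(rbind, lapply(params$T, function(x)
    matrix(rep(unname(x), each = N_POP), N_POP, 3)))
  list(WA = WA, WG = WG, WN = WN, Cvec = Cvec,
       tauA = tau[, 1], tauG = tau[, 2], tauN = tau[, 3])
}

# note: extrinsic natural strengths params$A are already mask * exp(theta)/8
# per target; assemble_weights multiplies the laminar mask weights by the
# per-edge scalar (exp(theta)/8), hence the "* 8" cancels the scale baked
# into params$A and re-applies the per-target mask weight / 8.

# --- dynamics -------------------------------------------------------------

#' Flow of the conductance-based microcircuit
#'
#' Time derivatives of the neuronal states. Each population carries four
#' states: depolarisation `V` and conductances `gAMPA`, `gGABA`, `gNMDA`.
#' Depolarisation follows the Morris-Lecar-type current balance
#' `dV/dt = (1/C) [ gL (VL - V) + gAMPA (VAMPA - V) + gGABA (VGABA - V)
#' + gNMDA m(V) (VNMDA - V) ] (+ u)`, with the endogenous input `u` injected
#' into the spiny-stellate depolarisation; conductances relax towards the
#' connectivity-weighted afferent firing with channel time constants,
#' `dg/dt = (S sigma(V) - g) / tau`.
#'
#' @param x State vector (region-major, population-minor, states
#'   `V,gAMPA,gGABA,gNMDA`), length `16 * n_regions`.
#' @param u Per-region endogenous input (mV/ms), scalar or length
#'   `n_regions`.
#' @param params Natural-scale parameter set from [scale_parameters()].
#' @param net A [network_spec()].
#' @param constants A [model_constants()].
#' @return Vector of time derivatives, same layout as `x` (units per ms).
#' @export
state_derivatives <- function(x, u, params, net, constants = model_constants()) {
  nx <- n_states(net)
  if (length(x) != nx) stop("state vector has length ", length(x),
                            ", expected ", nx)
  if (!all(is.finite(x))) stop("non-finite state vector")
  u <- rep_len(u, net$n_regions)
  w <- assemble_weights(params, net, constants)
  np <- net$n_regions * N_POP
  iV <- seq(1, nx, by = STATES_PER_POP)
  V <- x[iV]; gA <- x[iV + 1]; gG <- x[iV + 2]; gN <- x[iV + 3]
  sig <- firing_rate(V, constants)
  m <- magnesium_switch(V, constants)
  dV <- (constants$gL * (constants$VL - V) + gA * (constants$VAMPA - V) +
           gG * (constants$VGABA - V) + gN * m * (constants$VNMDA - V)) /
    w$Cvec
  # endogenous input enters spiny-stellate depolarisation
  ss_pop <- (seq_len(net$n_regions) - 1L) * N_POP + 1L
  dV[ss_pop] <- dV[ss_pop] + u
  dgA <- (drop(w$WA %*% sig) - gA) / w$tauA
  dgG <- (drop(w$WG %*% sig) - gG) / w$tauG
  dgN <- (drop(w$WN %*% sig) - gN) / w$tauN
  dx <- numeric(nx)
  dx[iV] <- dV; dx[iV + 1] <- dgA; dx[iV + 2] <- dgG; dx[iV + 3] <- dgN
  dx
}

# analytic Jacobian of state_derivatives (no delay correction)
raw_jacobian <- function(x, params, net, constants) {
  nx <- n_states(net)
  w <- assemble_weights(params, net, constants)
  iV <- seq(1, nx, by = STATES_PER_POP)
  V <- x[iV]; gA <- x[iV + 1]; gG <- x[iV + 2]; gN <- x[iV + 3]
  m <- magnesium_switch(V, constants)
  mg <- magnesium_switch_grad(V, constants)
  sg <- firing_rate_grad(V, constants)
  J <- matrix(0, nx, nx)
  np <- length(V)
  for (p in seq_len(np)) {
    a <- iV[p]
    J[a, a] <- (-constants$gL - gA[p] - gG[p] +
                  gN[p] * (mg[p] * (constants$VNMDA - V[p]) - m[p])) / w$Cvec[p]
    J[a, a + 1] <- (constants$VAMPA - V[p]) / w$Cvec[p]
    J[a, a + 2] <- (constants$VGABA - V[p]) / w$Cvec[p]
    J[a, a + 3] <- m[p] * (constants$VNMDA - V[p]) / w$Cvec[p]
    for (q in seq_len(np)) {
      b <- iV[q]
      if (w$WA[p, q] != 0) J[a + 1, b] <- w$WA[p, q] * sg[q] / w$tauA[p]
      if (w$WG[p, q] != 0) J[a + 2, b] <- w$WG[p, q] * sg[q] / w$tauG[p]
      if (w$WN[p, q] != 0) J[a + 3, b] <- w$WN[p, q] * sg[q] / w$tauN[p]
    }
    J[a + 1, a + 1] <- -1 / w$tauA[p]
    J[a + 2, a + 2] <- -1 / w$tauG[p]
    J[a + 3, a + 3] <- -1 / w$tauN[p]
  }
  J
}

# state-level conduction-delay matrix (ms): intrinsic delay between distinct
# populations of one region, extrinsic delay between regions, zero within a
# population.
delay_matrix <- function(params, net) {
  nx <- n_states(net)
  pop_of <- rep(seq_len(net$n_regions * N_POP), each = STATES_PER_POP)
  reg_of <- rep(seq_len(net$n_regions), each = N_POP * STATES_PER_POP)
  D <- matrix(params$D[["extrinsic"]], nx, nx)
  same_region <- outer(reg_of, reg_of, "==")
  D[same_region] <- params$D[["intrinsic"]]
  same_pop <- outer(pop_of, pop_of, "==")
  D[same_pop] <- 0
  D
}

#' Fixed point of the neuronal model
#'
#' Deterministic search for the equilibrium of the flow (`u = 0`): a damped
#' Newton iteration, falling back to semi-implicit (Rosenbrock-Euler)
#' integration of the stiff flow followed by a Newton polish.
#'
#' @inheritParams state_derivatives
#' @param tol Residual tolerance on the infinity norm of the flow.
#' @param x_init Optional initial state (defaults to `V = VL`, zero
#'   conductances).
#' @return The equilibrium state vector.
#' @export
find_fixed_point <- function(params, net, constants = model_constants(),
                             tol = 1e-8, x_init = NULL) {
  nx <- n_states(net)
  x <- x_init
  if (is.null(x)) {
    x <- numeric(nx)
    x[seq(1, nx, by = STATES_PER_POP)] <- constants$VL
  }
  newton <- function(x, iter) {
    for (k in seq_len(iter)) {
      f <- state_derivatives(x, 0, params, net, constants)
      f0 <- max(abs(f))
      if (f0 < tol) return(list(x = x, ok = TRUE))
      J <- raw_jacobian(x, params, net, constants)
      step <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(step)) return(list(x = x, ok = FALSE))
      lam <- 1
      repeat {
        xn <- x + lam * step
        fn <- tryCatch(max(abs(state_derivatives(xn, 0, params, net, constants))),
                       error = function(e) Inf)
        if ((is.finite(fn) && fn < f0) || lam < 1e-4) break
        lam <- lam / 2
      }
      if (!is.finite(fn) || fn >= f0) return(list(x = x, ok = FALSE))
      x <- xn
    }
    f <- state_derivatives(x, 0, params, net, constants)
    list(x = x, ok = max(abs(f)) < tol)
  }
  res <- newton(x, 64L)
  if (!res$ok) {
    # semi-implicit integration towards the equilibrium, then polish
    x <- res$x
    dt <- 1
    for (k in seq_len(2000L)) {
      f <- state_derivatives(x, 0, params, net, constants)
      if (!all(is.finite(f)))
        stop("fixed-point integration diverged (non-finite flow)")
      if (max(abs(f)) < 1e-4) break
      J <- raw_jacobian(x, params, net, constants)
      step <- tryCatch(solve(diag(nx) / dt - J, f), error = function(e) NULL)
      if (is.null(step)) stop("fixed-point integration: singular step")
      xn <- x + step
      if (!all(is.finite(xn))) {
        dt <- dt / 2
        if (dt < 1e-4) stop("fixed-point integration diverged")
        next
      }
      x <- xn
    }
    res <- newton(x, 64L)
    if (!res$ok) {
      f <- state_derivatives(res$x, 0, params, net, constants)
      stop(sprintf("fixed-point search did not converge (residual %.3e)",
                   max(abs(f))))
    }
  }
  res$x
}

#' System Jacobian with first-order delay correction
#'
#' Analytic Jacobian of the flow at a fixed point, corrected for conduction
#' delays by the first-order operator `J_eff = (I + J o D)^-1 J`, where `o`
#' is the element-wise product with the delay matrix (intrinsic delays
#' between populations of a region, extrinsic delays between regions). The
#' correction follows from a first-order Taylor expansion of delayed
#' arguments, `x'(t) = J x(t - D) ~ J x(t) - (J o D) x'(t)`.
#'
#' @inheritParams state_derivatives
#' @param x0 Fixed-point state vector.
#' @return The delay-corrected Jacobian matrix.
#' @export
system_jacobian <- function(params, net, x0, constants = model_constants()) {
  J <- raw_jacobian(x0, params, net, constants)
  D <- delay_matrix(params, net)
  M <- diag(nrow(J)) + J * D
  rc <- rcond(M)
  if (!is.finite(rc) || rc < 1e-12)
    stop(sprintf("delay correction operator is ill-conditioned (rcond %.2e)", rc))
  solve(M, J)
}

# --- spectra --------------------------------------------------------------

#' Endogenous fluctuation input spectrum
#'
#' Power-law spectrum of the structured ("pink") endogenous input with a
#' cosine-basis modulation: `gu(f) = exp(a1) * f^(-exp(a2)) *
#' max(1 + sum_i d_i cos(i pi nu(f)), 1e-8)`, with `nu` the frequency
#' rescaled to \[0, 1\] over the analysis band.
#'
#' @param a Length-2 log-scale amplitude/exponent parameters.
#' @param d Length-4 cosine coefficients.
#' @param freqs Frequencies (Hz), strictly positive.
#' @param band Band edges used to rescale frequency; defaults to
#'   `range(freqs)`.
#' @return Positive input power at each frequency.
#' @export
input_spectrum <- function(a, d, freqs, band = range(freqs)) {
  if (any(freqs <= 0)) stop("frequencies must be positive")
  stopifnot(length(a) == 2, length(d) == 4)
  nu <- (freqs - band[1]) / max(band[2] - band[1], .Machine$double.eps)
  mod <- 1 + cos(pi * nu) * d[1] + cos(2 * pi * nu) * d[2] +
    cos(3 * pi * nu) * d[3] + cos(4 * pi * nu) * d[4]
  exp(a[1]) * freqs^(-exp(a[2])) * pmax(mod, 1e-8)
}

#' Smooth frequency-scaling of the pass band
#'
#' Multiplicative taper modelling the effect of data filtration: two smooth
#' Gaussian bumps pinned to the lower and upper band edges whose log-weights
#' are the two `f` parameters. Neutral (identically 1) at `f = 0`.
#'
#' @param f Length-2 log-scale edge weights.
#' @inheritParams input_spectrum
#' @return Positive scaling at each frequency.
#' @export
filter_scaling <- function(f, freqs, band = range(freqs)) {
  stopifnot(length(f) == 2)
  nu <- (freqs - band[1]) / max(band[2] - band[1], .Machine$double.eps)
  exp(f[1] * exp(-(nu / 0.2)^2) + f[2] * exp(-((1 - nu) / 0.2)^2))
}

#' Observation-noise cross-spectrum
#'
#' Sum of a common (rank-one, identical across source pairs) and a
#' source-specific (diagonal) power-law noise term, scaled by the smooth
#' filter taper: `go(f) = taper(f) * [ exp(b1) f^(-exp(b2)) * 11' +
#' exp(c1) f^(-exp(c2)) * I ]`. Every slice is Hermitian positive
#' semi-definite by construction.
#'
#' @param b,c Length-2 log-scale (amplitude, exponent) parameters of the
#'   common and specific noise.
#' @param f Length-2 filter-scaling parameters (see [filter_scaling()]).
#' @param n_sources Number of sources.
#' @inheritParams input_spectrum
#' @return Array `n_freq x n_sources x n_sources`.
#' @export
noise_spectrum <- function(b, c, f, freqs, n_sources, band = range(freqs)) {
  if (any(freqs <= 0)) stop("frequencies must be positive")
  stopifnot(length(b) == 2, length(c) == 2)
  common <- exp(b[1]) * freqs^(-exp(b[2]))
  specific <- exp(c[1]) * freqs^(-exp(c[2]))
  taper <- filter_scaling(f, freqs, band)
  nf <- length(freqs)
  out <- array(0, c(nf, n_sources, n_sources))
  ones <- matrix(1, n_sources, n_sources)
  for (k in seq_len(nf))
    out[k, , ] <- taper[k] * (common[k] * ones +
                                diag(specific[k], n_sources))
  out
}

#' Frequency transfer function of the linearised network
#'
#' `K(w) = W (i w I - J)^-1 B`, where `J` is the delay-corrected Jacobian at
#' the fixed point, `B` injects the endogenous input of each region into its
#' spiny-stellate depolarisation, and `W` reads out the `J`-weighted
#' population depolarisations scaled by the sensor gain `L`. Angular
#' frequency is `2 pi f / 1000` (rad/ms) for `f` in Hz.
#'
#' @inheritParams state_derivatives
#' @param freqs Frequencies in Hz.
#' @return Object of class `"transfer_function"`: list with `frequencies`
#'   and complex array `K` of dimension `n_freq x n_sources x n_regions`.
#' @export
transfer_function <- function(params, net, freqs,
                              constants = model_constants()) {
  x0 <- find_fixed_point(params, net, constants)
  J <- system_jacobian(params, net, x0, constants)
  ev <- eigen(J, only.values = TRUE)$values
  if (max(Re(ev)) >= 0)
    stop(sprintf("unstable Jacobian: max real eigenvalue part %.3e",
                 max(Re(ev))))
  K <- transfer_from_jacobian(J, params, net, freqs)
  structure(list(frequencies = freqs, K = K), class = "transfer_function")
}

# K(w) given a (delay-corrected) Jacobian
transfer_from_jacobian <- function(J, params, net, freqs) {
  nx <- nrow(J)
  R <- net$n_regions
  B <- matrix(0, nx, R)
  W <- matrix(0, R, nx)
  for (r in seq_len(R)) {
    B[state_index(net, r, "ss", "V"), r] <- 1
    for (p in seq_len(N_POP)) {
      wgt <- params$J[[r]][p]
      if (wgt != 0)
        W[r, state_index(net, r, p, "V")] <- params$L[[r]] * wgt
    }
  }
  nf <- length(freqs)
  K <- array(complex(real = 0), c(nf, R, R))
  for (k in seq_len(nf)) {
    om <- 2 * pi * freqs[k] / 1000 # rad/ms
    K[k, , ] <- W %*% solve(diag(complex(real = 0, imaginary = om), nx) - J, B)
  }
  K
}

# --- cross-spectrum container --------------------------------------------

#' Cross-spectral density container
#'
#' @param frequencies Frequencies in Hz.
#' @param values Complex array `n_freq x n_sources x n_sources`; every
#'   frequency slice must be Hermitian with a real non-negative diagonal.
#' @param regions Optional region names.
#' @param label Optional identifier list (subject, session, split).
#' @return An object of class `"csd"`.
#' @export
csd <- function(frequencies, values, regions = NULL, label = list()) {
  stopifnot(length(dim(values)) == 3,
            dim(values)[1] == length(frequencies),
            dim(values)[2] == dim(values)[3])
  for (k in seq_len(dim(values)[1])) {
    s <- values[k, , ]
    if (max(abs(s - Conj(t(s)))) > 1e-6 * max(1, max(abs(s))))
      stop("CSD slice ", k, " is not Hermitian")
  }
  structure(list(frequencies = frequencies, values = values,
                 regions = regions, label = label,
                 n_sources = dim(values)[2]),
            class = "csd")
}

#' @export
print.csd <- function(x, ...) {
  cat("Cross-spectral density:", length(x$frequencies), "frequencies x",
      x$n_sources, "sources\n")
  invisible(x)
}

# project each slice onto the Hermitian PSD cone
psd_project <- function(values, floor = 0) {
  for (k in seq_len(dim(values)[1])) {
    s <- (values[k, , ] + Conj(t(values[k, , ]))) / 2
    eh <- eigen(s, symmetric = TRUE)
    lam <- pmax(Re(eh$values), floor)
    values[k, , ] <- eh$vectors %*% diag(lam, length(lam)) %*% Conj(t(eh$vectors))
  }
  values
}

#' Predicted cross-spectral density of the model
#'
#' The spectral response of the linearised neuronal model plus observation
#' noise: `gx(w) = taper(w) K(w) gu(w) K(w)* + go(w)`, clipped to the
#' Hermitian PSD cone (eigenvalue floor 0; inputs below `-1e-10` never
#' arise by construction).
#'
#' @param theta_hat Named log-scale parameter deviations (or a
#'   [param_density()]).
#' @param priors A [prior_table()].
#' @param net A [network_spec()] (defaults to the network the priors were
#'   built for).
#' @param constants A [model_constants()].
#' @param freqs Frequencies (Hz); default 1-64 Hz in 1 Hz steps.
#' @param engine `"cpp"` (fast compiled path, the default) or `"R"`
#'   (reference implementation); both give the same result to numerical
#'   precision.
#' @param x_init Optional warm-start state for the fixed-point search
#'   (compiled path only); the converged fixed point is attached to the
#'   result as attribute `"x0"`.
#' @return A [csd()] with the subject-less label `list()`.
#' @export
predict_csd <- function(theta_hat, priors, net = priors$net,
                        constants = model_constants(),
                        freqs = default_freqs(), engine = c("cpp", "R"),
                        x_init = NULL) {
  engine <- match.arg(engine)
  if (inherits(theta_hat, "param_density")) theta_hat <- theta_hat$mean
  params <- scale_parameters(theta_hat, priors)
  x0 <- NULL
  if (engine == "cpp") {
    res <- predict_csd_cpp_driver(params, net, constants, freqs, x_init)
    values <- res$values
    x0 <- res$x0
  } else {
    tf <- transfer_function(params, net, freqs, constants)
    gu <- input_spectrum(params$a, params$d, freqs)
    taper <- filter_scaling(params$f, freqs)
    go <- noise_spectrum(params$b, params$c, params$f, freqs,
                         net$n_regions)
    R <- net$n_regions
    values <- array(complex(real = 0), c(length(freqs), R, R))
    for (k in seq_along(freqs)) {
      K <- matrix(tf$K[k, , ], R, R)
      values[k, , ] <- taper[k] * gu[k] * (K %*% Conj(t(K))) + go[k, , ]
    }
  }
  values <- psd_project(values)
  out <- csd(freqs, values, regions = net$region_names)
  attr(out, "x0") <- x0
  out
}

#' Default analysis frequency grid (1-64 Hz, 1 Hz steps)
#' @export
default_freqs <- function() seq(1, 64, by = 1)

# compiled fast path: assemble the natural-scale structure in R and delegate
# fixed point / Jacobian / resolvent to cpp_forward_csd
predict_csd_cpp_driver <- function(params, net, constants, freqs,
                                   x_init = NULL) {
  w <- assemble_weights(params, net, constants)
  nx <- n_states(net)
  R <- net$n_regions
  B <- matrix(0, nx, R)
  W <- matrix(0, R, nx)
  for (r in seq_len(R)) {
    B[state_index(net, r, "ss", "V"), r] <- 1
    for (p in seq_len(N_POP)) {
      wgt <- params$J[[r]][p]
      if (wgt != 0) W[r, state_index(net, r, p, "V")] <- params$L[[r]] * wgt
    }
  }
  gu <- input_spectrum(params$a, params$d, freqs)
  taper <- filter_scaling(params$f, freqs)
  go <- noise_spectrum(params$b, params$c, params$f, freqs, R)
  go_cube <- array(complex(real = 0), c(R, R, length(freqs)))
  for (k in seq_along(freqs)) go_cube[, , k] <- go[k, , ]
  if (is.null(x_init)) {
    x_init <- numeric(nx)
    x_init[seq(1, nx, by = STATES_PER_POP)] <- constants$VL
  }
  cvec <- c(VL = constants$VL, VAMPA = constants$VAMPA,
            VGABA = constants$VGABA, VNMDA = constants$VNMDA,
            alpha_nmda = constants$alpha_nmda,
            sigmoid_threshold = constants$sigmoid_threshold,
            sigmoid_slope = constants$sigmoid_slope, gL = constants$gL)
  res <- cpp_forward_csd(w$WA, w$WG, w$WN, w$Cvec, w$tauA, w$tauG, w$tauN,
                         cvec, delay_matrix(params, net), B, W, freqs,
                         gu, taper, go_cube, x_init, 1e-8)
  if (!isTRUE(res$ok)) {
    reason <- res$reason
    if (identical(reason, "unstable"))
      stop(sprintf("unstable Jacobian: max real eigenvalue part %.3e",
                   res$max_re))
    if (identical(reason, "fixed_point"))
      stop(sprintf("fixed-point search did not converge (residual %.3e)",
                   res$residual))
    stop("forward model failure: ", reason)
  }
  values <- array(complex(real = 0), c(length(freqs), R, R))
  for (k in seq_along(freqs)) values[k, , ] <- res$values[, , k]
  list(values = values, x0 = drop(res$x0))
}
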