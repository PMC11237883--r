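# Precomputed evaluation context for the spectral forward model.
#
# The variational inversion evaluates the forward model thousands of times
# (numerical derivatives w.r.t. every parameter); this context front-loads
# all structure resolution (coordinate lookup, connection scatter indices,
# spectral bases) so a single evaluation is a handful of vectorised
# operations plus one call into the compiled core. Results agree with
# predict_csd() to numerical precision (asserted in the test suite).

make_forward_context <- function(priors, net = priors$net,
                                 constants = model_constants(),
                                 freqs = default_freqs()) {
  idx <- priors$index
  coord <- function(fam, region = NA, element = NA) {
    keep <- idx$family == fam
    if (!is.na(region)) keep <- keep & idx$region == region
    if (!is.na(element)) keep <- keep & idx$element == element
    out <- which(keep)
    if (!length(out)) stop("no coordinate for ", fam, "/", region, "/", element)
    out
  }
  R <- net$n_regions
  np <- R * N_POP
  nx <- np * STATES_PER_POP
  pop <- function(r, p) (r - 1L) * N_POP + match(p, POPULATIONS)

  # conductance scatter: linear indices into np x np matrices, base scale,
  # and the driving coordinate
  wa_i <- wg_i <- wn_i <- integer(0)
  wa_b <- wg_b <- wn_b <- numeric(0)
  wa_c <- wg_c <- wn_c <- integer(0)
  lin <- function(i, j) (j - 1L) * np + i
  rho <- constants$nmda_intrinsic_ratio
  for (r in seq_len(R)) {
    rn <- net$region_names[r]
    for (k in seq_len(nrow(priors$free_H))) {
      i <- priors$free_H[k, 1]; j <- priors$free_H[k, 2]
      base <- priors$scaling$H[i, j]
      cc <- coord("H", rn, paste0(POPULATIONS[i], "<-", POPULATIONS[j]))
      li <- lin(pop(r, POPULATIONS[i]), pop(r, POPULATIONS[j]))
      if (POPULATIONS[j] == "inh") {
        wg_i <- c(wg_i, li); wg_b <- c(wg_b, base); wg_c <- c(wg_c, cc)
      } else {
        wa_i <- c(wa_i, li); wa_b <- c(wa_b, base); wa_c <- c(wa_c, cc)
        wn_i <- c(wn_i, li); wn_b <- c(wn_b, rho * base); wn_c <- c(wn_c, cc)
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
        li <- lin(pop(rt, p), src)
        wa_i <- c(wa_i, li); wa_b <- c(wa_b, w)
        wa_c <- c(wa_c, coord("A", element = lab))
        wn_i <- c(wn_i, li); wn_b <- c(wn_b, w)
        wn_c <- c(wn_c, coord("AN", element = lab))
      }
    }
  }

  cT <- unlist(lapply(net$region_names, function(r) coord("T", r)))
  cC <- unlist(lapply(net$region_names, function(r) coord("C", r)))
  T_base <- rep(unname(priors$scaling$T), R) # per region: AMPA, GABA, NMDA
  C_base <- rep(unname(priors$scaling$C), R)

  # observer entries: value = base * exp(th[cL]) * exp(th[cJ] or 0)
  w_row <- w_col <- w_cL <- w_cJ <- integer(0)
  w_base <- numeric(0)
  B <- matrix(0, nx, R)
  for (r in seq_len(R)) {
    rn <- net$region_names[r]
    B[state_index(net, r, "ss", "V"), r] <- 1
    cL <- coord("L", rn)
    for (p in POPULATIONS) {
      base <- switch(p, ss = priors$scaling$J[["ss"]], sp = 1, inh = 0,
                     dp = priors$scaling$J[["dp"]])
      if (base == 0) next
      w_row <- c(w_row, r)
      w_col <- c(w_col, state_index(net, r, p, "V"))
      w_base <- c(w_base, base * priors$scaling$L)
      w_cL <- c(w_cL, cL)
      w_cJ <- c(w_cJ, if (p %in% c("ss", "dp")) coord("J", rn, p) else 0L)
    }
  }

  # delay masks
  pop_of <- rep(seq_len(np), each = STATES_PER_POP)
  reg_of <- rep(seq_len(R), each = N_POP * STATES_PER_POP)
  same_region <- outer(reg_of, reg_of, "==")
  same_pop <- outer(pop_of, pop_of, "==")
  D_int_mask <- same_region & !same_pop
  D_ext_mask <- !same_region
  cD <- coord("D")
  D_base <- unname(priors$scaling$D)

  nf <- length(freqs)
  lf <- log(freqs)
  nu <- (freqs - min(freqs)) / max(max(freqs) - min(freqs),
                                   .Machine$double.eps)
  cosmat <- cbind(cos(pi * nu), cos(2 * pi * nu), cos(3 * pi * nu),
                  cos(4 * pi * nu))
  bump_lo <- exp(-(nu / 0.2)^2)
  bump_hi <- exp(-((1 - nu) / 0.2)^2)
  ca <- coord("a"); cd <- coord("d"); cb <- coord("b")
  cc_ <- coord("c"); cf <- coord("f")
  ones_flat <- as.vector(matrix(1, R, R))
  eye_flat <- as.vector(diag(R))

  cvec <- c(VL = constants$VL, VAMPA = constants$VAMPA,
            VGABA = constants$VGABA, VNMDA = constants$VNMDA,
            alpha_nmda = constants$alpha_nmda,
            sigmoid_threshold = constants$sigmoid_threshold,
            sigmoid_slope = constants$sigmoid_slope, gL = constants$gL)
  x_cold <- numeric(nx)
  x_cold[seq(1, nx, by = STATES_PER_POP)] <- constants$VL

  ctx <- new.env(parent = emptyenv())
  ctx$priors <- priors; ctx$net <- net; ctx$constants <- constants
  ctx$freqs <- freqs; ctx$n <- priors$n
  ctx$x_last <- x_cold

  # residual stacking: per frequency, real upper triangle (incl. diagonal)
  # then imaginary strict upper triangle; frequency-major
  ut <- which(upper.tri(matrix(0, R, R), diag = TRUE), arr.ind = TRUE)
  sut <- which(upper.tri(matrix(0, R, R), diag = FALSE), arr.ind = TRUE)
  re_idx <- im_idx <- integer(0)
  re_src_i <- re_src_j <- im_src_i <- im_src_j <- integer(0)
  for (k in seq_len(nf)) {
    re_idx <- c(re_idx, (k - 1L) * R * R + (ut[, 2] - 1L) * R + ut[, 1])
    im_idx <- c(im_idx, (k - 1L) * R * R + (sut[, 2] - 1L) * R + sut[, 1])
    re_src_i <- c(re_src_i, ut[, 1]); re_src_j <- c(re_src_j, ut[, 2])
    im_src_i <- c(im_src_i, sut[, 1]); im_src_j <- c(im_src_j, sut[, 2])
  }
  ctx$re_idx <- re_idx; ctx$im_idx <- im_idx
  ctx$n_resid <- length(re_idx) + length(im_idx)
  ctx$resid_src_i <- c(re_src_i, im_src_i)
  ctx$resid_src_j <- c(re_src_j, im_src_j)

  ctx$pack <- list(
    R = R, np = np, nx = nx, nf = nf, nth = priors$n,
    wa_i = wa_i, wa_b = wa_b, wa_c = wa_c,
    wg_i = wg_i, wg_b = wg_b, wg_c = wg_c,
    wn_i = wn_i, wn_b = wn_b, wn_c = wn_c,
    cT = cT, cC = cC, T_base = T_base, C_base = C_base,
    w_row = w_row, w_col = w_col, w_cL = w_cL,
    w_cJ = ifelse(w_cJ > 0L, w_cJ, 0L), w_base = w_base,
    D_int = D_int_mask * D_base[1], D_ext = D_ext_mask * D_base[2],
    cD = cD, freqs = freqs, bump_lo = bump_lo, bump_hi = bump_hi,
    cosmat = cosmat, ca = ca, cd = cd, cb = cb, cc = cc_, cf = cf,
    B = B, consts = cvec, re_idx = re_idx, im_idx = im_idx,
    x_cold = x_cold)

  ctx$eval_features <- function(th, warm = TRUE) {
    res <- cpp_eval_features(ctx$pack, th,
                             if (warm) ctx$x_last else x_cold)
    if (isTRUE(res$ok)) ctx$x_last <- drop(res$x0)
    res
  }

  ctx$jacobian <- function(th, fd_step = 1e-4, warm = TRUE) {
    res <- cpp_eval_jacobian(ctx$pack, th, fd_step,
                             if (warm) ctx$x_last else x_cold)
    if (isTRUE(res$ok)) ctx$x_last <- drop(res$x0)
    res
  }

  ctx$eval <- function(th, warm = TRUE) {
    eth <- exp(th)
    WA <- matrix(0, np, np); WG <- matrix(0, np, np); WN <- matrix(0, np, np)
    WA[wa_i] <- wa_b * eth[wa_c]
    WG[wg_i] <- wg_b * eth[wg_c]
    WN[wn_i] <- wn_b * eth[wn_c]
    Cvec <- C_base * eth[cC]
    tauALL <- T_base * eth[cT]
    tau <- matrix(tauALL, nrow = 3) # 3 x R
    tauA <- rep(tau[1, ], each = N_POP)
    tauG <- rep(tau[2, ], each = N_POP)
    tauN <- rep(tau[3, ], each = N_POP)
    W <- matrix(0, R, nx)
    jfac <- ifelse(w_cJ > 0L, eth[pmax(w_cJ, 1L)], 1)
    W[cbind(w_row, w_col)] <- w_base * eth[w_cL] * jfac
    D <- D_int_mask * (D_base[1] * eth[cD[1]]) +
      D_ext_mask * (D_base[2] * eth[cD[2]])
    gu <- exp(th[ca[1]] - eth[ca[2]] * lf) *
      pmax(1 + drop(cosmat %*% th[cd]), 1e-8)
    taper <- exp(th[cf[1]] * bump_lo + th[cf[2]] * bump_hi)
    common <- exp(th[cb[1]] - eth[cb[2]] * lf)
    specific <- exp(th[cc_[1]] - eth[cc_[2]] * lf)
    gom <- outer(ones_flat, taper * common) + outer(eye_flat, taper * specific)
    go <- array(complex(real = gom), c(R, R, nf))
    x0 <- if (warm) ctx$x_last else x_cold
    res <- cpp_forward_csd(WA, WG, WN, Cvec, tauA, tauG, tauN, cvec, D, B,
                           W, freqs, gu, taper, go, x0, 1e-8)
    if (isTRUE(res$ok)) ctx$x_last <- drop(res$x0)
    res
  }

  # residual feature vector (real) from an eval() result
  ctx$features <- function(values) {
    v <- as.vector(values)
    c(Re(v[re_idx]), Im(v[im_idx]))
  }
  ctx
}

# features of an observed csd object under the same stacking convention
csd_features_vector <- function(ctx, g) {
  stopifnot(inherits(g, "csd"))
  if (!isTRUE(all.equal(g$frequencies, ctx$freqs)))
    stop("data frequency grid does not match the model context")
  R <- ctx$net$n_regions
  nf <- length(ctx$freqs)
  cube <- array(complex(real = 0), c(R, R, nf))
  for (k in seq_len(nf)) cube[, , k] <- g$values[k, , ]
  ctx$features(cube)
}
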