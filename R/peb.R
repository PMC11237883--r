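#' Second-level design matrix
#'
#' First column all ones (group mean), optional covariate columns appended.
#'
#' @param n Number of subjects (rows).
#' @param covariates Optional named list / data frame / matrix of covariate
#'   columns of length `n`.
#' @return An object of class `"design_matrix"` (a numeric matrix with a
#'   leading `"mean"` column; must have full column rank).
#' @export
build_design <- function(n, covariates = NULL) {
  stopifnot(n >= 1)
  X <- matrix(1, n, 1, dimnames = list(NULL, "mean"))
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    if (nrow(cv) != n)
      stop("covariate length ", nrow(cv), " does not match n = ", n)
    if (is.null(colnames(cv)))
      colnames(cv) <- paste0("cov", seq_len(ncol(cv)))
    X <- cbind(X, cv)
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  class(X) <- c("design_matrix", class(X))
  X
}

#' PEB configuration
#'
#' @param Q0 Precision floor added to the between-subject precision
#'   (a small positive scalar on the identity).
#' @param Q1_scale The between-subject precision is
#'   `Q0 I + exp(-gamma) * Q1` with `Q1 = Q1_scale` times the prior
#'   precision of the group-mean parameters (default 16).
#' @param gamma_mean,gamma_var Gaussian prior on the log precision-scale
#'   hyperparameter `gamma`.
#' @param max_iterations,tol Newton ascent control for `gamma`.
#' @return An object of class `"peb_config"`.
#' @export
peb_config <- function(Q0 = 1e-6, Q1_scale = 16, gamma_mean = 0,
                       gamma_var = 1, max_iterations = 64, tol = 1e-4) {
  stopifnot(Q0 > 0, Q1_scale > 0, gamma_var > 0)
  structure(list(Q0 = Q0, Q1_scale = Q1_scale, gamma_mean = gamma_mean,
                 gamma_var = gamma_var,
                 max_iterations = as.integer(max_iterations), tol = tol),
            class = "peb_config")
}

#' Kronecker-structured second-level precision
#'
#' `Pi_2 = I_n (x) (Q0 I_p + exp(-gamma) Q1)`: identical
#' positive-definite blocks for every subject.
#'
#' @param gamma Scalar log precision-scale hyperparameter.
#' @param config A [peb_config()].
#' @param p Parameters per subject.
#' @param n Subjects.
#' @param Q1 Optional precision-scale matrix (default `Q1_scale * I_p`,
#'   i.e. unit group-mean prior precision).
#' @return The `n p x n p` precision matrix.
#' @export
second_level_precision <- function(gamma, config = peb_config(), p, n,
                                   Q1 = NULL) {
  stopifnot(p >= 1, n >= 1)
  if (is.null(Q1)) Q1 <- diag(config$Q1_scale, p)
  Q1 <- as.matrix(Q1)
  ev <- eigen((Q1 + t(Q1)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) stop("Q1 must be PSD")
  blk <- diag(config$Q0, p) + exp(-gamma) * Q1
  diag(n) %x% blk
}

# symmetrised inverse via Cholesky
.inv <- function(M) chol2inv(chol((M + t(M)) / 2))
.ldet <- function(M) 2 * sum(log(diag(chol((M + t(M)) / 2))))

# clip a symmetric matrix to the PSD cone (for data-evidence precisions)
.psd_clip <- function(M, floor = 0) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, floor)
  e$vectors %*% (lam * t(e$vectors))
}

# extract a posterior density from mixed input (inversion_result or
# param_density), optionally restricted to a coordinate subset
.as_density <- function(x, subset = NULL) {
  q <- if (inherits(x, "inversion_result")) x$posterior else x
  if (!inherits(q, "param_density"))
    stop("first-level elements must be inversion results or densities")
  if (!is.null(subset)) q <- density_subset(q, subset)
  q
}

#' Parametric empirical Bayes over first-level posteriors
#'
#' Fits the hierarchical model `theta_1 = (X (x) I) theta_2 + eps_2`,
#' `eps_2 ~ N(0, (Q0 I + exp(-gamma) Q1)^-1)` over the first-level Gaussian
#' posteriors, by exact Gaussian marginalisation given `gamma` and a
#' monotone Newton ascent on the second-level free energy over `gamma`.
#' First-level posteriors are re-evaluated under the empirical prior by
#' Bayesian model reduction.
#'
#' @param first_level List of `"inversion_result"` or [param_density()]
#'   posteriors sharing one coordinate index.
#' @param X A [build_design()] matrix with one row per subject.
#' @param prior The shared first-level prior [param_density()].
#' @param config A [peb_config()].
#' @param parameters Optional coordinate names to restrict the hierarchy to
#'   (per-family PEB); defaults to all coordinates.
#' @return An object of class `"peb_result"`: second-level posterior (over
#'   `r * p` group-effect coordinates), `gamma` posterior, free energy
#'   `free_energy`, and `reestimated_first_level` densities.
#' @export
fit_peb <- function(first_level, X, prior, config = peb_config(),
                    parameters = NULL) {
  stopifnot(is.list(first_level), length(first_level) >= 1)
  n <- length(first_level)
  if (!is.matrix(X)) stop("X must be a design matrix")
  if (nrow(X) != n) stop("rows of X (", nrow(X), ") != subjects (", n, ")")
  if (is.null(parameters)) parameters <- prior$index$name
  prior <- density_subset(prior, parameters)
  qs <- lapply(first_level, .as_density, subset = parameters)
  p <- prior$n
  r <- ncol(X)
  for (q in qs)
    if (!identical(q$index$name, prior$index$name))
      stop("first-level posteriors do not share the parameter index")

  P0 <- .inv(prior$cov)
  m0 <- prior$mean
  ld_P0 <- .ldet(P0)

  # first-level data evidence in information form (BMR identity):
  # L_i(theta) propto exp(theta' r_i - 0.5 theta' Pi theta)
  Pi_list <- vector("list", n)
  r_list <- vector("list", n)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    Pq <- .inv(qs[[i]]$cov)
    Pi <- .psd_clip(Pq - P0)
    Pi_list[[i]] <- Pi
    r_list[[i]] <- drop(Pq %*% qs[[i]]$mean - P0 %*% m0)
    Fi <- if (inherits(first_level[[i]], "inversion_result"))
      first_level[[i]]$free_energy else 0
    ci[i] <- Fi - 0.5 * drop(crossprod(qs[[i]]$mean, Pq %*% qs[[i]]$mean)) +
      0.5 * drop(crossprod(m0, P0 %*% m0)) + 0.5 * .ldet(Pq) - 0.5 * ld_P0
  }

  # second-level prior over theta_2 (column blocks): group-mean block uses
  # the first-level prior; covariate blocks are zero-centred with the same
  # covariance
  m2 <- c(m0, rep(0, (r - 1) * p))
  S2 <- diag(r) %x% prior$cov
  P2 <- .inv(S2)
  Q1 <- config$Q1_scale * P0

  evidence <- function(gamma) {
    Pb <- diag(config$Q0, p) + exp(-gamma) * Q1 # between-subject precision
    ld_Pb <- .ldet(Pb)
    G <- matrix(0, r * p, r * p)
    g <- numeric(r * p)
    const <- 0
    for (i in seq_len(n)) {
      A <- Pi_list[[i]] + Pb
      Ainv <- .inv(A)
      const <- const + 0.5 * ld_Pb - 0.5 * .ldet(A) +
        0.5 * drop(crossprod(r_list[[i]], Ainv %*% r_list[[i]]))
      M <- Pb - Pb %*% Ainv %*% Pb        # p x p
      G <- G + (X[i, ] %o% X[i, ]) %x% M
      g <- g + X[i, ] %x% drop(Pb %*% Ainv %*% r_list[[i]])
    }
    Ppost <- P2 + G
    bb <- g + drop(P2 %*% m2)
    ch <- tryCatch(chol((Ppost + t(Ppost)) / 2), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Spost <- chol2inv(ch)
    mpost <- drop(Spost %*% bb)
    FF <- sum(ci) + const -
      0.5 * drop(crossprod(m2, P2 %*% m2)) +
      0.5 * drop(crossprod(bb, Spost %*% bb)) +
      0.5 * .ldet(P2) - sum(log(diag(ch)))
    list(F = FF, mean = mpost, cov = Spost)
  }

  # monotone Newton ascent on F2(gamma) + ln p(gamma)
  obj <- function(gm) {
    ev <- evidence(gm)
    if (is.null(ev)) return(-Inf)
    ev$F - 0.5 * (gm - config$gamma_mean)^2 / config$gamma_var -
      0.5 * log(2 * pi * config$gamma_var)
  }
  gamma <- config$gamma_mean
  curF <- obj(gamma)
  h <- 1e-3
  trajectory <- curF
  for (it in seq_len(config$max_iterations)) {
    f1 <- (obj(gamma + h) - obj(gamma - h)) / (2 * h)
    f2 <- (obj(gamma + h) - 2 * curF + obj(gamma - h)) / h^2
    step <- if (is.finite(f2) && f2 < -1e-10) -f1 / f2 else sign(f1)
    step <- max(min(step, 4), -4)
    accepted <- FALSE
    for (tries in 1:8) {
      cand <- gamma + step
      Fc <- obj(cand)
      if (is.finite(Fc) && Fc > curF) {
        gamma <- cand; curF <- Fc
        trajectory <- c(trajectory, curF)
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted || (length(trajectory) > 1 &&
                      diff(utils::tail(trajectory, 2)) < config$tol)) break
  }
  # Laplace entropy correction for gamma
  f2 <- (obj(gamma + h) - 2 * obj(gamma) + obj(gamma - h)) / h^2
  s_gamma <- if (is.finite(f2) && f2 < 0) -1 / f2 else config$gamma_var
  F2 <- curF + 0.5 * log(2 * pi * s_gamma) + 0.5

  ev <- evidence(gamma)
  idx2 <- do.call(rbind, lapply(colnames(X), function(cn) {
    ix <- prior$index
    ix$name <- paste0(cn, ":", ix$name)
    ix$effect <- cn
    ix
  }))
  q2 <- param_density(ev$mean, ev$cov, idx2)

  # re-estimate first-level posteriors under the empirical prior by BMR
  Pb <- diag(config$Q0, p) + exp(-gamma) * Q1
  Sb <- .inv(Pb)
  reest <- vector("list", n)
  for (i in seq_len(n)) {
    Wi <- t(X[i, ] %x% diag(p)) # p x rp
    vi <- drop(Wi %*% ev$mean)
    Svi <- Sb + Wi %*% ev$cov %*% t(Wi)
    red <- reduce_model(qs[[i]], prior,
                        param_density(vi, (Svi + t(Svi)) / 2, prior$index))
    reest[[i]] <- red$reduced_posterior
  }

  structure(list(second_level_posterior = q2,
                 gamma = gamma, gamma_var = s_gamma,
                 free_energy = F2, trajectory = trajectory,
                 reestimated_first_level = reest,
                 design = X, prior = prior, config = config,
                 parameters = parameters),
            class = "peb_result")
}

#' @export
print.peb_result <- function(x, ...) {
  cat(sprintf("PEB: %d effect(s) x %d parameter(s), F2 = %.2f, gamma = %.2f\n",
              ncol(x$design), x$prior$n, x$free_energy, x$gamma))
  invisible(x)
}

#' Third-level PEB over per-group PEB results
#'
#' Takes the group-mean posteriors of two (or more) second-level PEB
#' analyses (for example one per session or per cohort) and combines them in
#' a third-level PEB whose design is a ones column plus a group indicator
#' (0/1), yielding posteriors over commonalities and differences.
#'
#' @param group_results List of `"peb_result"` objects with matching
#'   parameter sets (or, equivalently, a list of [param_density()] group
#'   posteriors).
#' @param prior Shared first-level prior [param_density()] over the same
#'   parameters.
#' @param config A [peb_config()].
#' @return A `"peb_result"` whose design columns are `mean` and `group`.
#' @export
peb_of_pebs <- function(group_results, prior, config = peb_config()) {
  stopifnot(is.list(group_results), length(group_results) >= 2)
  qg <- lapply(group_results, function(gr) {
    if (inherits(gr, "peb_result")) {
      q2 <- gr$second_level_posterior
      keep <- which(q2$index$effect == "mean")
      q <- param_density(q2$mean[keep], q2$cov[keep, keep, drop = FALSE],
                         within_index(q2$index[keep, , drop = FALSE]))
      q
    } else {
      .as_density(gr)
    }
  })
  ng <- length(qg)
  X3 <- build_design(ng, covariates = list(group = c(0, seq_len(ng - 1))))
  fit_peb(qg, X3, prior, config = config)
}

# strip the "mean:" prefix applied by fit_peb so third-level indices match
# the first-level prior
within_index <- function(ix) {
  ix$name <- sub("^mean:", "", ix$name)
  ix$effect <- NULL
  ix
}

#' Flag parameters with evidence of a group difference
#'
#' For every parameter of the indicated effect column, computes the
#' Bayesian-model-reduction evidence for a non-zero effect (free energy of
#' the model with the effect against the model with the effect switched
#' off) and flags parameters whose posterior probability of a non-zero
#' effect exceeds the criterion. The central 95% interval of each flagged
#' effect is reported; whether the interval excludes zero is included as a
#' secondary criterion.
#'
#' @param peb A `"peb_result"` containing an indicator column.
#' @param effect Name of the difference column (default `"group"`).
#' @param criterion Posterior-probability threshold (default 0.95).
#' @return A data frame (possibly empty): parameter, family, expectation,
#'   2.5% / 97.5% quantiles, posterior probability, interval criterion. The
#'   full per-parameter table is attached as attribute `"all"`.
#' @export
flag_differences <- function(peb, effect = "group", criterion = 0.95) {
  stopifnot(inherits(peb, "peb_result"))
  q2 <- peb$second_level_posterior
  rows <- which(q2$index$effect == effect)
  if (!length(rows))
    stop("PEB result has no effect column named '", effect, "'")
  prior2 <- param_density(
    c(peb$prior$mean, rep(0, (ncol(peb$design) - 1) * peb$prior$n)),
    diag(ncol(peb$design)) %x% peb$prior$cov, q2$index)
  out <- data.frame(parameter = q2$index$name[rows],
                    family = q2$index$family[rows],
                    expectation = unname(q2$mean[rows]),
                    lower = NA_real_, upper = NA_real_,
                    posterior_prob = NA_real_,
                    excludes_zero = NA,
                    stringsAsFactors = FALSE)
  for (k in seq_along(rows)) {
    j <- rows[k]
    sdj <- sqrt(q2$cov[j, j])
    out$lower[k] <- q2$mean[j] - 1.959964 * sdj
    out$upper[k] <- q2$mean[j] + 1.959964 * sdj
    out$excludes_zero[k] <- out$lower[k] > 0 || out$upper[k] < 0
    red <- reduce_model(q2, prior2,
                        switch_off_prior(prior2, q2$index$name[j]))
    dF_with <- -red$delta_F # evidence for the model WITH the effect
    out$posterior_prob[k] <- 1 / (1 + exp(-dF_with))
  }
  flagged <- out[out$posterior_prob > criterion, , drop = FALSE]
  attr(flagged, "all") <- out
  attr(flagged, "criterion") <- criterion
  flagged
}
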