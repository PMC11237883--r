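#' Specification of a synthetic cohort
#'
#' Defines the statistical world the reliability analyses assume: subjects
#' drawn around a group-mean parameter vector, an optional additive session
#' effect (session 2 only), spectral observation noise and an epoch
#' structure. All generators are pure functions of (spec, seed).
#'
#' @param n_subjects Number of subjects.
#' @param n_regions 1, 2 or 4 (region names `R1..R4`).
#' @param between_subject_sd Between-subject spread in units of the prior
#'   standard deviation: a single number, or a named vector per family
#'   (unnamed families default to 1). The default draws every family at one
#'   prior standard deviation except the sensor gain `L`, whose prior
#'   variance (64 on the log scale) expresses inversion vagueness about
#'   units rather than biological spread; subject gains are drawn with a
#'   realistic 0.5 log-unit standard deviation (factor `1/16` of the prior
#'   sd).
#' @param session_effect Named numeric vector of injected session-2 effects,
#'   in prior-sd units, indexed by parameter name (default: none).
#' @param observation_noise_sd Standard deviation of the complex Gaussian
#'   perturbation added to each epoch's cross-spectrum. `NULL` (default)
#'   calibrates it once from the prior-mean model so the alpha-band (8-12
#'   Hz) peak of the diagonal power has a 10:1 signal-to-noise ratio.
#' @param n_epochs Epochs per session.
#' @param n_sessions Sessions per subject.
#' @param freqs Frequency grid (Hz).
#' @param seed Mandatory integer seed.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 8, n_regions = 2,
                        between_subject_sd = c(L = 1 / 16),
                        session_effect = NULL,
                        observation_noise_sd = NULL, n_epochs = 16,
                        n_sessions = 2, freqs = default_freqs(), seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(n_subjects >= 1, n_regions %in% c(1, 2, 4),
            all(between_subject_sd >= 0), n_epochs >= 1, n_sessions >= 1)
  if (!is.null(session_effect) && is.null(names(session_effect)))
    stop("session_effect must be a named vector of parameter coordinates")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_regions = as.integer(n_regions),
                 between_subject_sd = between_subject_sd,
                 session_effect = session_effect,
                 observation_noise_sd = observation_noise_sd,
                 n_epochs = as.integer(n_epochs),
                 n_sessions = as.integer(n_sessions),
                 freqs = freqs, seed = as.integer(seed)),
            class = "cohort_spec")
}

cohort_network <- function(spec) network_spec(paste0("R", seq_len(spec$n_regions)))

# per-coordinate between-subject sd on the log scale (prior sd * factor)
.bs_sd_vector <- function(spec, priors) {
  fam <- priors$index$family
  prior_sd <- sqrt(priors$index$variance)
  fac <- rep(1, priors$n)
  bs <- spec$between_subject_sd
  if (is.null(names(bs))) {
    fac[] <- bs[1]
  } else {
    for (f in names(bs)) fac[fam == f] <- bs[[f]]
  }
  fac * prior_sd
}

.session_effect_vector <- function(spec, priors) {
  out <- setNames(rep(0, priors$n), priors$index$name)
  se <- spec$session_effect
  if (!is.null(se)) {
    bad <- setdiff(names(se), priors$index$name)
    if (length(bad)) stop("unknown session_effect coordinate(s): ",
                          paste(bad, collapse = ", "))
    out[names(se)] <- se * sqrt(priors$index$variance[
      match(names(se), priors$index$name)])
  }
  out
}

#' Sample true subject/session parameters of a cohort
#'
#' `theta(subject, session) = 0 + between-subject draw + session effect
#' (session 2 and later only)`, on the log scale. Subjects whose implied
#' model is unstable (in any session) are redrawn, so every returned
#' parameter vector generates a valid spectrum; redraws are counted and the
#' procedure is reproducible by seed.
#'
#' @param spec A [cohort_spec()].
#' @param priors A [prior_table()] for the spec's network (defaults to the
#'   standard table).
#' @param constants A [model_constants()].
#' @return A list with `theta` (array subjects x sessions x parameters),
#'   `priors`, `net` and the redraw count.
#' @export
sample_cohort <- function(spec, priors = NULL,
                          constants = model_constants()) {
  stopifnot(inherits(spec, "cohort_spec"))
  net <- cohort_network(spec)
  if (is.null(priors)) priors <- prior_table(net)
  set.seed(spec$seed)
  sdv <- .bs_sd_vector(spec, priors)
  sev <- .session_effect_vector(spec, priors)
  ctx <- make_forward_context(priors, net, constants, spec$freqs)
  p <- priors$n
  th <- array(0, c(spec$n_subjects, spec$n_sessions, p),
              dimnames = list(NULL, NULL, priors$index$name))
  redraws <- 0L
  for (i in seq_len(spec$n_subjects)) {
    for (try in seq_len(50L)) {
      base <- rnorm(p) * sdv
      ok <- TRUE
      for (s in seq_len(spec$n_sessions)) {
        v <- base + if (s >= 2) sev else 0
        if (!isTRUE(ctx$eval(v, warm = FALSE)$ok)) { ok <- FALSE; break }
      }
      if (ok) break
      redraws <- redraws + 1L
    }
    if (!ok) stop("could not draw a stable subject after 50 attempts")
    for (s in seq_len(spec$n_sessions))
      th[i, s, ] <- base + if (s >= 2) sev else 0
  }
  list(theta = th, priors = priors, net = net, spec = spec,
       redraws = redraws)
}

# calibrate the epoch-noise sd from the prior-mean model: alpha-band peak
# diagonal power / 10
calibrate_noise_sd <- function(priors, net, constants = model_constants(),
                               freqs = default_freqs()) {
  th <- setNames(rep(0, priors$n), priors$index$name)
  g <- predict_csd(th, priors, net, constants, freqs)
  band <- freqs >= 8 & freqs <= 12
  if (!any(band)) band <- rep(TRUE, length(freqs))
  peak <- max(Re(apply(g$values[band, , , drop = FALSE], 1, function(s)
    max(Re(diag(matrix(s, net$n_regions)))))))
  peak / 10
}

#' Simulate observed (noisy) epoch cross-spectra for one subject/session
#'
#' The noiseless model prediction plus an independent Hermitian complex
#' Gaussian perturbation per epoch, projected back onto the PSD cone, so
#' epoch averages converge to the noiseless prediction at the Monte-Carlo
#' rate.
#'
#' @param theta_hat Named log-scale parameter vector (truth).
#' @param spec A [cohort_spec()] (supplies noise sd, epoch count, grid).
#' @param priors,net,constants Forward-model context.
#' @param label Label list stored on each epoch.
#' @return List of [csd()] objects, one per epoch.
#' @export
simulate_observed_csd <- function(theta_hat, spec, priors,
                                  net = cohort_network(spec),
                                  constants = model_constants(),
                                  label = list()) {
  g0 <- predict_csd(theta_hat, priors, net, constants, spec$freqs)
  sd0 <- spec$observation_noise_sd
  if (is.null(sd0))
    sd0 <- calibrate_noise_sd(priors, net, constants, spec$freqs)
  nf <- length(spec$freqs)
  R <- net$n_regions
  epochs <- vector("list", spec$n_epochs)
  for (ep in seq_len(spec$n_epochs)) {
    vals <- g0$values
    if (sd0 > 0) {
      for (k in seq_len(nf)) {
        Zr <- matrix(rnorm(R * R, sd = sd0 / sqrt(2)), R, R)
        Zi <- matrix(rnorm(R * R, sd = sd0 / sqrt(2)), R, R)
        E <- Zr + 1i * Zi
        vals[k, , ] <- vals[k, , ] + (E + Conj(t(E))) / 2
      }
      vals <- psd_project(vals)
    }
    lab <- label
    lab$epoch <- ep
    epochs[[ep]] <- csd(spec$freqs, vals, regions = net$region_names,
                        label = lab)
  }
  epochs
}

#' Average a list of epoch cross-spectra
#'
#' @param epochs List of [csd()] with a common grid.
#' @param label Label attached to the average.
#' @return A [csd()].
#' @export
average_csd <- function(epochs, label = list()) {
  stopifnot(length(epochs) >= 1)
  vals <- Reduce(`+`, lapply(epochs, function(e) e$values)) / length(epochs)
  csd(epochs[[1]]$frequencies, vals, regions = epochs[[1]]$regions,
      label = label)
}

#' Split epochs into odd/even averages
#'
#' Disjoint partition of the epoch list by parity of the epoch position;
#' returns the two averages, labelled `"odd"` and `"even"`.
#'
#' @param epochs List of at least two [csd()] objects.
#' @return List with elements `odd` and `even`.
#' @export
split_epoch_features <- function(epochs) {
  if (length(epochs) < 2) stop("need at least 2 epochs to split")
  idx <- seq_along(epochs)
  list(odd = average_csd(epochs[idx %% 2 == 1], label = list(split = "odd")),
       even = average_csd(epochs[idx %% 2 == 0], label = list(split = "even")))
}

#' Simulate paired evidence vectors with compound-symmetry structure
#'
#' Each subject's pair `(k1_i, k2_i)` shares a latent component of variance
#' `rho * sigma2` (scaled by `beta` in `k1`), with independent residuals of
#' variance `(1 - rho) * sigma2`, so the pair covariance matches the
#' compound-symmetry structure with interclass correlation `rho`.
#'
#' @param n Number of subjects.
#' @param rho Interclass correlation in `(-1, 1)` (positive-definite range
#'   for pairs).
#' @param sigma2 Total variance per measurement.
#' @param beta Scaling of the shared component in the first measurement.
#' @param seed Integer seed.
#' @param mu Length-2 means of the two measurements.
#' @return An [evidence_pair()].
#' @export
generate_evidence_pairs <- function(n, rho, sigma2 = 1, beta = 1, seed,
                                    mu = c(0, 0)) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (rho <= -1 || rho >= 1) stop("rho outside the valid range (-1, 1)")
  if (rho < 0) stop("negative interclass correlations are not generated")
  set.seed(as.integer(seed))
  s <- rnorm(n, 0, sqrt(rho * sigma2))
  e1 <- rnorm(n, 0, sqrt((1 - rho) * sigma2))
  e2 <- rnorm(n, 0, sqrt((1 - rho) * sigma2))
  evidence_pair(mu[1] + beta * s + e1, mu[2] + s + e2)
}
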