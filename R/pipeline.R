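PEB_FAMILIES <- c("T", "H", "A", "AN", "L", "J", "a", "d")

#' Study configuration for the reliability pipeline
#'
#' @param cohort A [cohort_spec()] describing the synthetic cohort (or
#'   `NULL` when a manifest of observed spectra is supplied).
#' @param manifest Optional nested list of [csd()] objects,
#'   `manifest[[subject]][[condition]]`, replacing simulation.
#' @param analyses Subset of `c("split_sample", "between_session",
#'   "between_subject", "evidence_reliability")`.
#' @param inversion An [inversion_config()].
#' @param peb A [peb_config()].
#' @param families Parameter families analysed by per-family PEB.
#' @param flag_criterion Posterior-probability criterion for difference
#'   flagging.
#' @param constants A [model_constants()].
#' @param out_dir Optional output directory for the JSON report and CSV
#'   tables.
#' @param seed Seed for the full pipeline run.
#' @return An object of class `"study_config"`.
#' @export
study_config <- function(cohort = NULL, manifest = NULL,
                         analyses = c("evidence_reliability",
                                      "between_session"),
                         inversion = inversion_config(),
                         peb = peb_config(),
                         families = PEB_FAMILIES,
                         flag_criterion = 0.95,
                         constants = model_constants(),
                         out_dir = NULL, seed = 1) {
  allowed <- c("split_sample", "between_session", "between_subject",
               "evidence_reliability")
  bad <- setdiff(analyses, allowed)
  if (length(bad)) stop("unknown analyses: ", paste(bad, collapse = ", "))
  if (is.null(cohort) && is.null(manifest))
    stop("either a cohort spec or a manifest is required")
  structure(list(cohort = cohort, manifest = manifest, analyses = analyses,
                 inversion = inversion, peb = peb, families = families,
                 flag_criterion = flag_criterion, constants = constants,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "study_config")
}

#' Welch-style cross-spectral features from source time series
#'
#' Hann-windowed FFT cross-spectra averaged over epochs, sampled at the
#' requested frequency grid (nearest FFT bin). Optionally compresses each
#' slice onto the leading principal components of the frequency-averaged
#' cross-spectrum.
#'
#' @param timeseries A time x sources matrix or a list of such epochs.
#' @param sfreq Sampling rate (Hz).
#' @param freqs Requested frequency grid (Hz); must not exceed Nyquist.
#' @param n_components Optional principal-component count (default: off).
#' @return A [csd()].
#' @export
csd_features <- function(timeseries, sfreq, freqs = default_freqs(),
                         n_components = NULL) {
  if (is.matrix(timeseries)) timeseries <- list(timeseries)
  stopifnot(length(timeseries) >= 1)
  if (max(freqs) > sfreq / 2)
    stop("frequency grid exceeds the Nyquist frequency ", sfreq / 2, " Hz")
  ns <- ncol(timeseries[[1]])
  nt <- nrow(timeseries[[1]])
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nt) / (nt + 1)) # Hann
  fft_freqs <- (seq_len(nt) - 1) * sfreq / nt
  bins <- vapply(freqs, function(f) which.min(abs(fft_freqs - f)), 1L)
  nf <- length(freqs)
  acc <- array(complex(real = 0), c(nf, ns, ns))
  for (ep in timeseries) {
    stopifnot(ncol(ep) == ns, nrow(ep) == nt)
    X <- stats::mvfft(ep * w)
    for (k in seq_len(nf)) {
      xk <- X[bins[k], ]
      acc[k, , ] <- acc[k, , ] + (xk %o% Conj(xk)) /
        (sum(w^2) * sfreq / 2)
    }
  }
  vals <- acc / length(timeseries)
  if (!is.null(n_components) && n_components < ns) {
    avg <- apply(vals, c(2, 3), mean)
    e <- eigen((avg + Conj(t(avg))) / 2, symmetric = TRUE)
    U <- e$vectors[, seq_len(n_components), drop = FALSE]
    P <- U %*% Conj(t(U))
    for (k in seq_len(nf)) vals[k, , ] <- P %*% vals[k, , ] %*% P
  }
  csd(freqs, vals, label = list(estimator = "welch"))
}

# simulate the full cohort data set: per subject x session, the averaged
# epoch spectrum plus (for session 1) the odd/even split averages
simulate_study_data <- function(config) {
  spec <- config$cohort
  coh <- sample_cohort(spec, constants = config$constants)
  priors <- coh$priors
  net <- coh$net
  sd0 <- spec$observation_noise_sd
  if (is.null(sd0))
    sd0 <- calibrate_noise_sd(priors, net, config$constants, spec$freqs)
  spec$observation_noise_sd <- sd0
  data <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    data[[i]] <- vector("list", spec$n_sessions)
    for (s in seq_len(spec$n_sessions)) {
      epochs <- simulate_observed_csd(
        coh$theta[i, s, ], spec, priors, net, config$constants,
        label = list(subject = i, session = s))
      entry <- list(average = average_csd(
        epochs, label = list(subject = i, session = s)))
      if (s == 1 && spec$n_epochs >= 2)
        entry$splits <- split_epoch_features(epochs)
      data[[i]][[s]] <- entry
    }
  }
  list(cohort = coh, data = data, priors = priors, net = net,
       noise_sd = sd0)
}

#' First-level inversions for a study
#'
#' Simulates (or takes) the per-subject spectra and inverts every
#' subject/session (and, for the split-sample analysis, the session-1
#' odd/even splits). Per-item failures are isolated, logged in the result
#' and do not stop the run. Deterministic given the configuration.
#'
#' @param config A [study_config()].
#' @return List with the inversion results (`fits[[subject]][[condition]]`),
#'   the underlying data and model objects, and an error log.
#' @export
run_first_level <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  if (is.null(config$cohort)) stop("manifest-driven runs need a cohort spec or csd manifest; see invert_csd for single fits")
  sim <- simulate_study_data(config)
  priors <- sim$priors
  model <- model_context(priors, sim$net, config$constants,
                         config$cohort$freqs)
  prior <- prior_density(priors)
  errors <- list()
  need_splits <- "split_sample" %in% config$analyses
  fits <- vector("list", length(sim$data))
  for (i in seq_along(sim$data)) {
    fits[[i]] <- list()
    for (s in seq_along(sim$data[[i]])) {
      entry <- sim$data[[i]][[s]]
      key <- paste0("session", s)
      fit <- tryCatch(invert(entry$average, prior, model, config$inversion),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        errors[[paste0("subject", i, ".", key)]] <- conditionMessage(fit)
        fit <- NULL
      }
      fits[[i]][[key]] <- fit
      if (s == 1 && need_splits && !is.null(entry$splits)) {
        for (sp in c("odd", "even")) {
          f2 <- tryCatch(invert(entry$splits[[sp]], prior, model,
                                config$inversion),
                         error = function(e) e)
          if (inherits(f2, "error")) {
            errors[[paste0("subject", i, ".", sp)]] <- conditionMessage(f2)
            f2 <- NULL
          }
          fits[[i]][[sp]] <- f2
        }
      }
    }
  }
  list(fits = fits, sim = sim, priors = priors, net = sim$net,
       prior = prior, model = model, errors = errors, config = config)
}

# family -> coordinate names
family_coordinates <- function(priors, families) {
  out <- lapply(families, function(f) priors$index$name[priors$index$family == f])
  names(out) <- families
  out[vapply(out, length, 1L) > 0]
}

# per-family PEB on each condition set, then third-level contrast and flags
contrast_analysis <- function(set1, set2, priors, prior, config) {
  fams <- family_coordinates(priors, config$families)
  flagged <- list()
  all_rows <- list()
  reest <- list(first = list(), second = list())
  for (fam in names(fams)) {
    coords <- fams[[fam]]
    peb1 <- fit_peb(set1, build_design(length(set1)), prior,
                    config = config$peb, parameters = coords)
    peb2 <- fit_peb(set2, build_design(length(set2)), prior,
                    config = config$peb, parameters = coords)
    peb3 <- peb_of_pebs(list(peb1, peb2), density_subset(prior, coords),
                        config = config$peb)
    fl <- flag_differences(peb3, criterion = config$flag_criterion)
    flagged[[fam]] <- fl
    all_rows[[fam]] <- attr(fl, "all")
    reest$first[[fam]] <- peb1$reestimated_first_level
    reest$second[[fam]] <- peb2$reestimated_first_level
  }
  all_tab <- do.call(rbind, all_rows)
  flag_tab <- do.call(rbind, flagged)
  rownames(all_tab) <- rownames(flag_tab) <- NULL
  n_total <- nrow(all_tab)
  n_flagged <- if (is.null(flag_tab)) 0L else nrow(flag_tab)
  list(flagged = flag_tab, all = all_tab,
       n_parameters = n_total, n_flagged = n_flagged,
       fraction_no_difference = 1 - n_flagged / n_total,
       reestimated = reest)
}

#' Correlation of paired parameter expectations before and after PEB
#'
#' For every parameter, the across-subject Pearson correlation between the
#' paired expectations of the two conditions (splits or sessions), computed
#' from the raw first-level posteriors and again from the PEB re-estimated
#' posteriors; counts per family of parameters with correlation above the
#' threshold. The modified pooled-mean correlation is available via
#' `method = "modified"`.
#'
#' @param first1,first2 Lists of first-level posteriors (paired by
#'   position).
#' @param reest1,reest2 Matching lists of re-estimated posteriors.
#' @param priors The [prior_table()] (for family structure).
#' @param threshold Correlation threshold (default 0.5).
#' @param method `"pearson"` (default) or `"modified"`.
#' @return Data frame: family, parameter count, `before` and `after`
#'   counts of parameters with correlation above the threshold.
#' @export
parameter_correlation_report <- function(first1, first2, reest1, reest2,
                                         priors, threshold = 0.5,
                                         method = c("pearson", "modified")) {
  method <- match.arg(method)
  n <- length(first1)
  if (length(first2) != n || length(reest1) != n || length(reest2) != n)
    stop("inputs must be paired lists of equal length")
  get_means <- function(lst) t(vapply(lst, function(x) .as_density(x)$mean,
                                      numeric(.as_density(lst[[1]])$n)))
  m1 <- get_means(first1); m2 <- get_means(first2)
  r1 <- get_means(reest1); r2 <- get_means(reest2)
  nm <- .as_density(first1[[1]])$index
  corfun <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    if (method == "pearson") stats::cor(a, b) else modified_pearson(a, b)
  }
  cb <- vapply(seq_len(ncol(m1)), function(j) corfun(m1[, j], m2[, j]), 1)
  ca <- vapply(seq_len(ncol(r1)), function(j) corfun(r1[, j], r2[, j]), 1)
  fams <- unique(nm$family)
  out <- do.call(rbind, lapply(fams, function(f) {
    j <- which(nm$family == f)
    data.frame(family = f, n_parameters = length(j),
               before = sum(cb[j] > threshold, na.rm = TRUE),
               after = sum(ca[j] > threshold, na.rm = TRUE))
  }))
  attr(out, "correlations") <- data.frame(parameter = nm$name,
                                          family = nm$family,
                                          before = cb, after = ca)
  out
}

#' Run the full reliability study
#'
#' Orchestrates the requested analyses over a (synthetic) cohort: evidence
#' reliability of paired free energies (compound-symmetry comparison),
#' per-family PEB and third-level PEB-of-PEBs contrasts with difference
#' flagging for split-sample, between-session and between-subject designs,
#' and the before/after-PEB correlation report.
#'
#' @param config A [study_config()].
#' @param first_level Optional precomputed [run_first_level()] output.
#' @return An object of class `"reliability_report"`.
#' @export
run_reliability_study <- function(config, first_level = NULL) {
  stopifnot(inherits(config, "study_config"))
  fl <- if (is.null(first_level)) run_first_level(config) else first_level
  fits <- fl$fits
  report <- list(analyses = list(), errors = fl$errors,
                 seed = config$seed)

  pick <- function(key) lapply(fits, function(x) x[[key]])
  complete <- function(a, b) {
    keep <- !vapply(a, is.null, TRUE) & !vapply(b, is.null, TRUE)
    list(a = a[keep], b = b[keep], n = sum(keep))
  }
  contrasts <- list()
  if ("split_sample" %in% config$analyses)
    contrasts$split_sample <- complete(pick("odd"), pick("even"))
  if ("between_session" %in% config$analyses &&
      config$cohort$n_sessions >= 2)
    contrasts$between_session <- complete(pick("session1"), pick("session2"))
  if ("between_subject" %in% config$analyses) {
    s1 <- pick("session1")
    keep <- !vapply(s1, is.null, TRUE)
    s1 <- s1[keep]
    half <- floor(length(s1) / 2)
    contrasts$between_subject <- list(a = s1[seq_len(half)],
                                      b = s1[half + seq_len(half)],
                                      n = half)
  }

  for (nm in names(contrasts)) {
    ct <- contrasts[[nm]]
    if (ct$n < 2) {
      report$analyses[[nm]] <- list(error = "fewer than 2 complete pairs")
      next
    }
    res <- contrast_analysis(ct$a, ct$b, fl$priors, fl$prior, config)
    if ("evidence_reliability" %in% config$analyses) {
      F1 <- vapply(ct$a, function(x) x$free_energy, 1)
      F2 <- vapply(ct$b, function(x) x$free_energy, 1)
      if (ct$n >= 3)
        res$evidence_reliability <-
          compare_evidence_reliability(evidence_pair(F1, F2))
    }
    # correlation report needs a paired re-estimated set; use the joint
    # family-wise re-estimates (concatenated over families)
    cat1 <- join_family_densities(res$reestimated$first)
    cat2 <- join_family_densities(res$reestimated$second)
    if (ct$n >= 3 && nm != "between_subject") {
      res$correlations <- parameter_correlation_report(
        lapply(ct$a, function(x) density_subset(x$posterior, cat1$coords)),
        lapply(ct$b, function(x) density_subset(x$posterior, cat1$coords)),
        cat1$densities, cat2$densities, fl$priors)
    }
    res$reestimated <- NULL
    report$analyses[[nm]] <- res
  }
  report$noise_sd <- fl$sim$noise_sd
  class(report) <- "reliability_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# concatenate per-family re-estimated densities into one density per subject
join_family_densities <- function(by_family) {
  n <- length(by_family[[1]])
  coords <- unlist(lapply(by_family, function(l) l[[1]]$index$name))
  dens <- lapply(seq_len(n), function(i) {
    means <- unlist(lapply(by_family, function(l) l[[i]]$mean))
    covs <- lapply(by_family, function(l) l[[i]]$cov)
    S <- matrix(0, length(means), length(means))
    off <- 0
    for (cv in covs) {
      d <- nrow(cv)
      S[off + seq_len(d), off + seq_len(d)] <- cv
      off <- off + d
    }
    idx <- do.call(rbind, lapply(by_family, function(l) l[[i]]$index))
    param_density(means, S, idx)
  })
  list(coords = coords, densities = dens)
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("Reliability report (seed", x$seed, ")\n")
  for (nm in names(x$analyses)) {
    a <- x$analyses[[nm]]
    if (!is.null(a$error)) { cat(" ", nm, ": ", a$error, "\n"); next }
    cat(sprintf("  %s: %d/%d parameters flagged (%.1f%% without evidence of difference)\n",
                nm, a$n_flagged, a$n_parameters,
                100 * a$fraction_no_difference))
    if (!is.null(a$evidence_reliability))
      cat(sprintf("    evidence reliability dF = %.2f (rho = %.2f)\n",
                  a$evidence_reliability$delta_F,
                  a$evidence_reliability$rho))
  }
  invisible(x)
}

# write the JSON report and CSV tables
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trimmed <- list(seed = report$seed, noise_sd = report$noise_sd,
                  analyses = lapply(report$analyses, function(a) {
    if (!is.null(a$error)) return(a["error"])
    out <- list(n_parameters = a$n_parameters, n_flagged = a$n_flagged,
                fraction_no_difference = a$fraction_no_difference)
    if (!is.null(a$evidence_reliability)) {
      er <- a$evidence_reliability
      out$evidence_reliability <- list(delta_F = er$delta_F,
                                       rho = er$rho,
                                       favours_cs = er$favours_cs)
    }
    out
  }))
  jsonlite::write_json(trimmed, file.path(out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE)
  for (nm in names(report$analyses)) {
    a <- report$analyses[[nm]]
    if (!is.null(a$flagged) && nrow(a$flagged))
      utils::write.csv(a$flagged,
                       file.path(out_dir, paste0(nm, "_flagged.csv")),
                       row.names = FALSE)
    if (!is.null(a$correlations))
      utils::write.csv(a$correlations,
                       file.path(out_dir, paste0(nm, "_correlations.csv")),
                       row.names = FALSE)
  }
  invisible(out_dir)
}
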