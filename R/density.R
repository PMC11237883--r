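#' Gaussian density over log-scale parameter deviations
#'
#' The package represents priors and posteriors over model parameters as a
#' multivariate Gaussian on the log-scale deviations `theta_hat` (so that the
#' natural-scale parameter is `theta0 * exp(theta_hat)`).
#'
#' @param mean Named numeric vector of log-scale deviations.
#' @param cov Covariance matrix (symmetric positive semi-definite); a single
#'   numeric vector is interpreted as a diagonal.
#' @param index Optional coordinate index (a data frame as built by
#'   [prior_table()]); defaults to a minimal index built from names.
#' @return An object of class `"param_density"`.
#' @export
param_density <- function(mean, cov, index = NULL) {
  mean <- drop(mean)
  p <- length(mean)
  if (is.null(dim(cov))) {
    stopifnot(length(cov) %in% c(1L, p))
    cov <- diag(rep_len(as.numeric(cov), p), p)
  }
  cov <- as.matrix(cov)
  if (!all(dim(cov) == p)) stop("dimension mismatch between mean and cov")
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("covariance must be symmetric")
  cov <- (cov + t(cov)) / 2
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("covariance must be positive semi-definite")
  if (is.null(index)) {
    nm <- names(mean)
    if (is.null(nm)) nm <- paste0("p", seq_len(p))
    index <- data.frame(family = NA_character_, region = NA_character_,
                        element = nm, name = nm, stringsAsFactors = FALSE)
  }
  if (nrow(index) != p) stop("index size must equal mean length")
  names(mean) <- index$name
  dimnames(cov) <- list(index$name, index$name)
  structure(list(mean = mean, cov = cov, index = index, n = p),
            class = "param_density")
}

#' Prior density implied by a prior table
#'
#' Zero mean and diagonal covariance with the per-family prior variances.
#'
#' @param priors A [prior_table()].
#' @return A [param_density()].
#' @export
prior_density <- function(priors) {
  stopifnot(inherits(priors, "prior_table"))
  param_density(stats::setNames(rep(0, priors$n), priors$index$name),
                priors$index$variance, priors$index)
}

#' @export
print.param_density <- function(x, ...) {
  cat("Gaussian parameter density over", x$n, "coordinates\n")
  invisible(x)
}

# subset a density to a set of coordinate names (marginal density)
density_subset <- function(q, names) {
  i <- match(names, q$index$name)
  if (anyNA(i)) stop("unknown coordinate(s): ",
                     paste(names[is.na(i)], collapse = ", "))
  param_density(q$mean[i], q$cov[i, i, drop = FALSE],
                q$index[i, , drop = FALSE])
}

#' Map log-scale deviations to natural-scale model parameters
#'
#' Applies `theta = theta0 * exp(theta_hat)` coordinate-wise and assembles
#' the structured natural-scale parameter set (per-region rate constants,
#' capacitances, intrinsic matrices, per-edge extrinsic strengths, gains,
#' read-out weights and spectral parameters).
#'
#' @param theta_hat Named numeric vector of log-scale deviations (or a
#'   [param_density()] whose mean is used). Every coordinate must be indexed
#'   in `priors`.
#' @param priors A [prior_table()].
#' @return A list with one element per parameter family on the natural scale.
#' @export
scale_parameters <- function(theta_hat, priors) {
  stopifnot(inherits(priors, "prior_table"))
  if (inherits(theta_hat, "param_density")) theta_hat <- theta_hat$mean
  if (is.null(names(theta_hat)))
    stop("theta_hat must be a named vector of indexed coordinates")
  unknown <- setdiff(names(theta_hat), priors$index$name)
  if (length(unknown))
    stop("coordinate(s) not indexed in the prior table: ",
         paste(unknown, collapse = ", "))
  th <- stats::setNames(rep(0, priors$n), priors$index$name)
  th[names(theta_hat)] <- theta_hat
  idx <- priors$index
  net <- priors$net
  sc <- priors$scaling
  get <- function(fam, region = NULL, element = NULL) {
    keep <- idx$family == fam
    if (!is.null(region)) keep <- keep & idx$region %in% region
    if (!is.null(element)) keep <- keep & idx$element %in% element
    stats::setNames(th[idx$name[keep]], idx$element[keep])
  }
  out <- list()
  out$T <- lapply(stats::setNames(net$region_names, net$region_names),
                  function(r) sc$T * exp(get("T", r)))
  out$C <- lapply(stats::setNames(net$region_names, net$region_names),
                  function(r) sc$C * exp(get("C", r)))
  out$H <- lapply(stats::setNames(net$region_names, net$region_names),
                  function(r) {
                    Hm <- sc$H
                    v <- get("H", r)
                    for (k in seq_len(nrow(priors$free_H))) {
                      i <- priors$free_H[k, 1]; j <- priors$free_H[k, 2]
                      lab <- paste0(POPULATIONS[i], "<-", POPULATIONS[j])
                      Hm[i, j] <- Hm[i, j] * exp(v[[lab]])
                    }
                    Hm
                  })
  eA <- get("A"); eAN <- get("AN")
  out$A <- sc$A * exp(eA)
  out$AN <- sc$AN * exp(eAN)
  out$L <- sc$L * exp(get("L"))
  names(out$L) <- net$region_names
  out$J <- lapply(stats::setNames(net$region_names, net$region_names),
                  function(r) {
                    j <- sc$J * exp(get("J", r))
                    c(ss = unname(j["ss"]), sp = 1, inh = 0,
                      dp = unname(j["dp"]))
                  })
  for (fam in c("a", "d", "b", "c", "f"))
    out[[fam]] <- unname(get(fam)) # kept on log scale; spectra exponentiate
  out$D <- sc$D * exp(unname(get("D")))
  names(out$D) <- c("intrinsic", "extrinsic")
  out
}
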