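#' Write a cross-spectral density to JSON
#'
#' Plain-text container mirroring the in-memory layout: frequencies, real
#' and imaginary parts (`n_freq x n_src x n_src`, flattened row-major by
#' frequency), region names and label.
#'
#' @param x A [csd()].
#' @param path Output file path.
#' @export
write_csd_json <- function(x, path) {
  stopifnot(inherits(x, "csd"))
  obj <- list(frequencies = x$frequencies,
              dim = dim(x$values),
              real = as.vector(Re(x$values)),
              imag = as.vector(Im(x$values)),
              regions = x$regions,
              label = x$label)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a cross-spectral density from JSON
#'
#' @param path File written by [write_csd_json()].
#' @return A [csd()].
#' @export
read_csd_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dm <- as.integer(obj$dim)
  vals <- array(complex(real = obj$real, imaginary = obj$imag), dm)
  lab <- as.list(obj$label)
  csd(obj$frequencies, vals, regions = obj$regions, label = lab)
}

#' Write / read paired evidence vectors as CSV
#'
#' Columns: `subject`, `k1`, `k2`.
#'
#' @param pair An [evidence_pair()].
#' @param path CSV file path.
#' @export
write_evidence_csv <- function(pair, path) {
  stopifnot(inherits(pair, "evidence_pair"))
  utils::write.csv(data.frame(subject = seq_len(pair$n), k1 = pair$k1,
                              k2 = pair$k2),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_evidence_csv
#' @export
read_evidence_csv <- function(path) {
  df <- utils::read.csv(path)
  evidence_pair(df$k1, df$k2)
}

#' Serialise an inversion result to JSON
#'
#' Posterior mean and covariance, free energy, noise hyperparameters and
#' the free-energy trajectory, for audit and archiving.
#'
#' @param x An `"inversion_result"`.
#' @param path Output file path.
#' @export
write_inversion_json <- function(x, path) {
  stopifnot(inherits(x, "inversion_result"))
  obj <- list(posterior_mean = as.list(x$posterior$mean),
              posterior_cov = x$posterior$cov,
              free_energy = x$free_energy,
              noise_hyperparameters = x$noise_hyperparameters,
              trajectory = x$trajectory,
              scale = x$scale,
              converged = x$converged)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
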