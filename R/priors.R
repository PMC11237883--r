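# Default intrinsic connection template. Row = target population, column =
# source population, order (ss, sp, inh, dp). Magnitudes follow the
# conductance-based canonical microcircuit convention: a feedforward
# excitatory chain ss -> sp -> dp, excitatory drive onto the inhibitory pool
# from all pyramidal populations, recurrent self-inhibition of the
# inhibitory pool, and GABAergic inhibition of every population. Entries are
# conductance scale factors; the sign (channel routing) is determined by the
# source population, not by the entry.
default_H_template <- function() {
  H <- matrix(0, 4, 4, dimnames = list(POPULATIONS, POPULATIONS))
  H["ss", "inh"] <- 48
  H["sp", "ss"]  <- 80
  H["sp", "inh"] <- 48
  H["inh", "ss"] <- 20
  H["inh", "sp"] <- 40
  H["inh", "inh"] <- 32
  H["inh", "dp"] <- 20
  H["dp", "sp"]  <- 80
  H["dp", "inh"] <- 48
  H
}

# Laminar targets of extrinsic connections (scale 1/8): forward connections
# arise from sp and reach ss and dp; backward connections arise from dp and
# reach sp and (doubly weighted) inh.
extrinsic_masks <- function() {
  fwd <- c(ss = 1, sp = 0, inh = 0, dp = 1) / 8
  bwd <- c(ss = 0, sp = 1, inh = 2, dp = 0) / 8
  list(forward = list(source = "sp", targets = fwd),
       backward = list(source = "dp", targets = bwd))
}

#' Prior table of the conductance-based microcircuit model
#'
#' Builds the table of scaling constants `theta0` and log-scale prior
#' variances for every parameter family of the model: channel rate (time)
#' constants `T`, membrane capacitances `C`, intrinsic connection strengths
#' `H`, extrinsic AMPA (`A`) and NMDA (`AN`) connections, sensor gain `L`,
#' population read-out contributions `J`, endogenous fluctuation spectrum
#' (`a`, `d`), sensor noise spectra (`b`, `c`), filter scaling `f` and
#' conduction delays `D`. A parameter on the natural scale is
#' `theta0 * exp(theta_hat)` with `theta_hat ~ N(0, variance)`.
#'
#' @param net A [network_spec()].
#' @param H_template 4x4 intrinsic connection scale matrix (target x source);
#'   free parameters are attached to its non-zero entries.
#' @param variances Optional named numeric overriding the default per-family
#'   prior variances.
#' @return An object of class `"prior_table"` carrying the scaling constants,
#'   per-family variances and the coordinate index of the parameter vector.
#' @export
prior_table <- function(net, H_template = default_H_template(),
                        variances = NULL) {
  stopifnot(inherits(net, "network_spec"))
  H_template <- as.matrix(H_template)
  stopifnot(identical(dim(H_template), c(4L, 4L)), all(H_template >= 0))
  dimnames(H_template) <- list(POPULATIONS, POPULATIONS)

  var_default <- c(T = 1/16, C = 1/16, H = 1/32, A = 1/8, AN = 1/8,
                   L = 64, J = 1/16, a = 1/128, d = 1/128, b = 1/128,
                   c = 1/128, f = 1/128, D = 1/64)
  if (!is.null(variances)) {
    bad <- setdiff(names(variances), names(var_default))
    if (length(bad)) stop("unknown family in variances: ", paste(bad, collapse = ", "))
    var_default[names(variances)] <- variances
  }
  if (any(var_default <= 0)) stop("prior variances must be positive")

  scaling <- list(
    T = c(AMPA = 4, GABA = 16, NMDA = 100),      # channel time constants, ms
    C = c(ss = 128, sp = 128, inh = 256, dp = 32) / 1000,
    H = H_template,
    A = 1 / 8, AN = 1 / 8,
    L = 1,
    J = c(ss = 0.2, dp = 0.2),                   # sp fixed at 1, inh at 0
    a = c(1, 1), d = c(1, 1, 1, 1), b = c(1, 1), c = c(1, 1), f = c(1, 1),
    D = unname(net$delays_prior)                 # (intrinsic, extrinsic) ms
  )

  # coordinate index of the stacked log-scale parameter vector
  rows <- list()
  add <- function(family, region, element) {
    rows[[length(rows) + 1L]] <<-
      data.frame(family = family, region = region, element = element,
                 stringsAsFactors = FALSE)
  }
  for (r in net$region_names) for (ch in names(scaling$T)) add("T", r, ch)
  for (r in net$region_names) for (p in names(scaling$C)) add("C", r, p)
  free_H <- which(H_template > 0, arr.ind = TRUE)
  for (r in net$region_names)
    for (k in seq_len(nrow(free_H)))
      add("H", r, paste0(POPULATIONS[free_H[k, 1]], "<-",
                         POPULATIONS[free_H[k, 2]]))
  edge_label <- function(e, type) paste0(type, ":", e[1], "->", e[2])
  for (type in c("forward", "backward")) {
    ed <- net[[type]]
    for (k in seq_len(nrow(ed))) add("A", NA, edge_label(ed[k, ], type))
  }
  for (type in c("forward", "backward")) {
    ed <- net[[type]]
    for (k in seq_len(nrow(ed))) add("AN", NA, edge_label(ed[k, ], type))
  }
  for (r in net$region_names) add("L", r, "gain")
  for (r in net$region_names) for (p in names(scaling$J)) add("J", r, p)
  for (k in 1:2) add("a", NA, as.character(k))
  for (k in 1:4) add("d", NA, as.character(k))
  for (k in 1:2) add("b", NA, as.character(k))
  for (k in 1:2) add("c", NA, as.character(k))
  for (k in 1:2) add("f", NA, as.character(k))
  add("D", NA, "intrinsic"); add("D", NA, "extrinsic")

  index <- do.call(rbind, rows)
  index$name <- ifelse(is.na(index$region),
                       paste0(index$family, "(", index$element, ")"),
                       paste0(index$family, "(", index$region, ",",
                              index$element, ")"))
  if (anyDuplicated(index$name)) stop("internal error: duplicate parameter names")
  index$variance <- unname(var_default[index$family])
  rownames(index) <- NULL

  structure(list(net = net, scaling = scaling, variances = var_default,
                 index = index, n = nrow(index), free_H = free_H),
            class = "prior_table")
}

#' @export
print.prior_table <- function(x, ...) {
  cat("Prior table:", x$n, "log-scale parameters over",
      x$net$n_regions, "region(s)\n")
  print(table(x$index$family))
  invisible(x)
}
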