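POPULATIONS <- c("ss", "sp", "inh", "dp")
N_POP <- 4L
STATES_PER_POP <- 4L # V, gAMPA, gGABA, gNMDA

#' Specify a cortical network of conductance-based sources
#'
#' A network is a set of named regions plus directed extrinsic connections.
#' Forward connections originate in the superficial pyramidal population and
#' target spiny stellate and deep pyramidal cells of the distal region;
#' backward connections originate in deep pyramidal cells and target
#' superficial pyramidal and inhibitory populations. Each region contains
#' four populations (spiny stellate `ss`, superficial pyramidal `sp`,
#' inhibitory interneurons `inh`, deep pyramidal `dp`).
#'
#' @param region_names Character vector of region labels (e.g. the default
#'   mode network `c("LAG", "RAG", "MPFC", "PCC")`).
#' @param forward,backward Two-column matrices (or data frames) of directed
#'   edges `(from, to)` given as region names. The default is a fully
#'   connected network: every ordered pair of regions receives both a
#'   forward and a backward connection.
#' @param delays_prior Length-2 numeric: intrinsic (within-region) and
#'   extrinsic (between-region) conduction delays in ms.
#' @return An object of class `"network_spec"`.
#' @examples
#' net <- network_spec(c("LAG", "RAG"))
#' net$forward
#' @export
network_spec <- function(region_names,
                         forward = NULL, backward = NULL,
                         delays_prior = c(intrinsic = 2, extrinsic = 16)) {
  stopifnot(is.character(region_names), length(region_names) >= 1,
            !anyDuplicated(region_names))
  all_pairs <- function() {
    if (length(region_names) < 2) {
      matrix(character(0), 0, 2, dimnames = list(NULL, c("from", "to")))
    } else {
      g <- expand.grid(from = region_names, to = region_names,
                       stringsAsFactors = FALSE)
      as.matrix(g[g$from != g$to, , drop = FALSE])
    }
  }
  as_edges <- function(e) {
    if (is.null(e)) return(all_pairs())
    e <- as.matrix(e)
    if (ncol(e) != 2) stop("edges must have two columns (from, to)")
    colnames(e) <- c("from", "to")
    storage.mode(e) <- "character"
    bad <- setdiff(c(e), region_names)
    if (length(bad))
      stop("edge references undeclared region(s): ", paste(bad, collapse = ", "))
    if (any(e[, 1] == e[, 2])) stop("self-edges are not allowed")
    rownames(e) <- NULL
    e
  }
  structure(list(region_names = region_names,
                 n_regions = length(region_names),
                 n_populations = N_POP,
                 forward = as_edges(forward),
                 backward = as_edges(backward),
                 delays_prior = delays_prior),
            class = "network_spec")
}

n_states <- function(net) net$n_regions * N_POP * STATES_PER_POP

region_id <- function(net, region) {
  i <- match(region, net$region_names)
  if (anyNA(i)) stop("unknown region: ", paste(region[is.na(i)], collapse = ", "))
  i
}

# global index of a state: region-major, population-minor, states (V,gA,gG,gN)
state_index <- function(net, region, population, state) {
  r <- if (is.character(region)) region_id(net, region) else region
  p <- if (is.character(population)) match(population, POPULATIONS) else population
  s <- if (is.character(state)) match(state, c("V", "gAMPA", "gGABA", "gNMDA")) else state
  (r - 1L) * N_POP * STATES_PER_POP + (p - 1L) * STATES_PER_POP + s
}

state_names <- function(net) {
  nm <- character(n_states(net))
  for (r in seq_len(net$n_regions))
    for (p in seq_len(N_POP))
      for (s in seq_len(STATES_PER_POP))
        nm[state_index(net, r, p, s)] <-
          paste(net$region_names[r], POPULATIONS[p],
                c("V", "gAMPA", "gGABA", "gNMDA")[s], sep = ".")
  nm
}
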