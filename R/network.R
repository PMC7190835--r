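#' Build the TES reaction network
#'
#' Assembles the mass-action reaction network shared by the deterministic and
#' stochastic engines. Species order is fixed and documented as
#' `(m, s, c, p)`: free THS mRNA, free tuner sRNA, mRNA-sRNA complex, output
#' protein. The ten reactions are
#'
#' 1.  `0 -> m` at `u_in` (input-promoter transcription)
#' 2.  `0 -> s` at `booster_factor * u_tun` (tuner transcription)
#' 3.  `m + s -> c` at `k_on` (toehold hybridization / branch migration)
#' 4.  `c -> m + s` at `k_off` (dissociation; 0 by default)
#' 5.  `m -> m + p` at `k_leak` (leak translation from the closed switch)
#' 6.  `c -> c + p` at `k_act` (translation from the opened switch)
#' 7.-10. first-order removal of `m, s, c, p` at `delta_x + phi`
#'
#' @param params a [tes_parameters()] object.
#' @return A `reaction_network`: list with `species` (character), `stoichiometry`
#'   (species x reactions integer matrix), and `propensity_spec` (per reaction,
#'   a mass-action constant `rate` and integer reactant `orders` per species).
#' @export
build_tes_network <- function(params) {
  stopifnot(inherits(params, "tes_parameters"))
  validate_tes_parameters(params)
  species <- c("m", "s", "c", "p")
  rxn <- list(
    transcribe_m   = list(rate = params$u_in,                           orders = c(0, 0, 0, 0), change = c(+1, 0, 0, 0)),
    transcribe_s   = list(rate = params$booster_factor * params$u_tun,  orders = c(0, 0, 0, 0), change = c(0, +1, 0, 0)),
    hybridize      = list(rate = params$k_on,                           orders = c(1, 1, 0, 0), change = c(-1, -1, +1, 0)),
    dissociate     = list(rate = params$k_off,                          orders = c(0, 0, 1, 0), change = c(+1, +1, -1, 0)),
    translate_leak = list(rate = params$k_leak,                         orders = c(1, 0, 0, 0), change = c(0, 0, 0, +1)),
    translate_act  = list(rate = params$k_act,                          orders = c(0, 0, 1, 0), change = c(0, 0, 0, +1)),
    decay_m        = list(rate = params$delta_m + params$phi,           orders = c(1, 0, 0, 0), change = c(-1, 0, 0, 0)),
    decay_s        = list(rate = params$delta_s + params$phi,           orders = c(0, 1, 0, 0), change = c(0, -1, 0, 0)),
    decay_c        = list(rate = params$delta_c + params$phi,           orders = c(0, 0, 1, 0), change = c(0, 0, -1, 0)),
    decay_p        = list(rate = params$delta_p + params$phi,           orders = c(0, 0, 0, 1), change = c(0, 0, 0, -1))
  )
  reaction_network(
    species = species,
    stoichiometry = vapply(rxn, function(r) as.integer(r$change), integer(4)),
    rates = vapply(rxn, `[[`, numeric(1), "rate"),
    orders = vapply(rxn, function(r) as.integer(r$orders), integer(4)),
    reaction_names = names(rxn)
  )
}

#' Construct a mass-action reaction network
#'
#' General constructor used by [build_tes_network()] and by the test fixtures
#' (birth-death chains and the like).
#'
#' @param species character vector of species labels.
#' @param stoichiometry integer matrix, species x reactions: net change of each
#'   species per firing.
#' @param rates non-negative mass-action rate constants, one per reaction.
#' @param orders integer matrix, species x reactions: reactant order of each
#'   species in each reaction's propensity.
#' @param reaction_names optional labels.
#' @return A `reaction_network` object.
#' @export
reaction_network <- function(species, stoichiometry, rates, orders,
                             reaction_names = NULL) {
  stoichiometry <- as.matrix(stoichiometry)
  orders <- as.matrix(orders)
  n_sp <- length(species)
  n_rx <- length(rates)
  if (nrow(stoichiometry) != n_sp || ncol(stoichiometry) != n_rx) {
    stop("stoichiometry must be species x reactions (", n_sp, " x ", n_rx, ")")
  }
  if (nrow(orders) != n_sp || ncol(orders) != n_rx) {
    stop("orders must be species x reactions (", n_sp, " x ", n_rx, ")")
  }
  if (any(!is.finite(rates)) || any(rates < 0)) {
    bad <- which(!is.finite(rates) | rates < 0)[1]
    nm <- if (!is.null(reaction_names)) reaction_names[bad] else bad
    stop("mass-action constant for reaction '", nm, "' must be a finite non-negative number")
  }
  if (any(orders < 0)) stop("reactant orders must be non-negative integers")
  rownames(stoichiometry) <- rownames(orders) <- species
  if (!is.null(reaction_names)) {
    colnames(stoichiometry) <- colnames(orders) <- reaction_names
  }
  structure(
    list(species = species,
         stoichiometry = stoichiometry,
         propensity_spec = list(rates = as.numeric(rates),
                                orders = matrix(as.integer(orders), n_sp, n_rx,
                                                dimnames = dimnames(orders)))),
    class = "reaction_network"
  )
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Mass-action reaction network:", length(x$species), "species,",
      ncol(x$stoichiometry), "reactions\n")
  cat("species:", paste(x$species, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate reaction propensities at a state
#'
#' Mass-action propensities: for the stochastic interpretation an order-k
#' reactant contributes the falling factorial `x(x-1)...(x-k+1)`; for the
#' deterministic interpretation it contributes `x^k`. The two coincide for the
#' order-0/1 reactions used by the TES network.
#'
#' @param network a `reaction_network`.
#' @param state numeric vector of copy numbers, in `network$species` order.
#' @param kind `"stochastic"` (falling factorial) or `"deterministic"` (`x^k`).
#' @return numeric vector of per-reaction propensities.
#' @export
propensities <- function(network, state, kind = c("stochastic", "deterministic")) {
  kind <- match.arg(kind)
  stopifnot(inherits(network, "reaction_network"),
            length(state) == length(network$species))
  rates <- network$propensity_spec$rates
  orders <- network$propensity_spec$orders
  a <- rates
  for (j in seq_along(a)) {
    for (i in seq_len(nrow(orders))) {
      k <- orders[i, j]
      if (k == 0L) next
      if (kind == "deterministic") {
        a[j] <- a[j] * state[i]^k
      } else {
        for (q in seq_len(k)) a[j] <- a[j] * (state[i] - q + 1)
      }
    }
  }
  pmax(a, 0)
}

#' Deterministic right-hand side assembled from a network
#'
#' Returns `S %*% a(x)` with deterministic mass-action propensities; this is the
#' ODE system that the dedicated TES right-hand side must reproduce.
#'
#' @inheritParams propensities
#' @return numeric vector `d state / dt`.
#' @export
network_rhs <- function(network, state) {
  as.numeric(network$stoichiometry %*%
               propensities(network, state, kind = "deterministic"))
}

#' Export a reaction network as a tidy data frame
#'
#' One row per (reaction, species) with non-zero stoichiometry or order;
#' suitable for CSV/JSON serialization of the model structure.
#'
#' @param network a `reaction_network`.
#' @return data.frame with columns reaction, rate, species, change, order.
#' @export
network_table <- function(network) {
  S <- network$stoichiometry
  O <- network$propensity_spec$orders
  rates <- network$propensity_spec$rates
  rx <- colnames(S)
  if (is.null(rx)) rx <- paste0("r", seq_len(ncol(S)))
  out <- do.call(rbind, lapply(seq_len(ncol(S)), function(j) {
    keep <- which(S[, j] != 0L | O[, j] != 0L)
    if (!length(keep)) keep <- 1L
    data.frame(reaction = rx[j], rate = rates[j],
               species = network$species[keep],
               change = S[keep, j], order = O[keep, j],
               row.names = NULL)
  }))
  out
}
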