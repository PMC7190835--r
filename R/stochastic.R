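#' Exact stochastic simulation (Gillespie direct method)
#'
#' Simulates a mass-action [reaction_network()] exactly: waiting times are
#' exponential with the total propensity and state changes follow the
#' stoichiometry. States are reported at `n_points + 1` equally spaced times;
#' each reported state is the state holding at that instant.
#'
#' @param network a `reaction_network`.
#' @param initial non-negative integer copy numbers, one per species.
#' @param duration simulated time (min).
#' @param n_points number of reporting intervals.
#' @param seed integer RNG seed; the same seed, network and arguments replay a
#'   bit-identical trajectory.
#' @return A `trajectory`: list with `times`, integer `states`
#'   (time x species), `seed`, `method`, and `absorbed` (`TRUE` when every
#'   propensity hit zero before `duration`).
#' @export
simulate_ssa <- function(network, initial, duration, n_points = 100, seed) {
  check_stoch_args(network, initial, duration, seed)
  res <- ssa_simulate_cpp(network$stoichiometry,
                          network$propensity_spec$rates,
                          network$propensity_spec$orders,
                          as.integer(initial), duration,
                          as.integer(n_points), as.double(seed))
  new_trajectory(res, network, seed, "exact-SSA")
}

#' Approximate stochastic simulation (adaptive tau-leaping)
#'
#' Tau-leaping with Poisson reaction counts per leap. The leap size is chosen
#' by the bounded-relative-propensity-change criterion (`epsilon`, default
#' 0.03) and never exceeds the reporting interval; leaps that would drive a
#' species negative are halved and redrawn, never clipped. Agreement with the
#' exact method is distributional, not path-wise.
#'
#' @inheritParams simulate_ssa
#' @param n_intervals number of reporting intervals (leap ceiling =
#'   `duration / n_intervals`).
#' @param epsilon bound on the expected relative species change per leap.
#' @return A `trajectory` (see [simulate_ssa()]).
#' @export
simulate_tauleap <- function(network, initial, duration = 100,
                             n_intervals = 100, epsilon = 0.03, seed) {
  check_stoch_args(network, initial, duration, seed)
  stopifnot(epsilon > 0)
  res <- tauleap_simulate_cpp(network$stoichiometry,
                              network$propensity_spec$rates,
                              network$propensity_spec$orders,
                              as.integer(initial), duration,
                              as.integer(n_intervals), epsilon,
                              as.double(seed))
  new_trajectory(res, network, seed, "tau-leap")
}

check_stoch_args <- function(network, initial, duration, seed) {
  stopifnot(inherits(network, "reaction_network"))
  if (length(initial) != length(network$species)) {
    stop("initial state must have one entry per species")
  }
  if (any(initial < 0) || any(initial != round(initial))) {
    stop("initial state must be non-negative integers")
  }
  stopifnot(duration > 0, is.numeric(seed), length(seed) == 1L)
  invisible(TRUE)
}

new_trajectory <- function(res, network, seed, method) {
  states <- res$states
  colnames(states) <- network$species
  structure(list(times = as.numeric(res$times), states = states,
                 seed = seed, method = method, absorbed = res$absorbed),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("%s trajectory: %d time points, species %s, seed %s%s\n",
              x$method, length(x$times),
              paste(colnames(x$states), collapse = "/"),
              format(x$seed), if (x$absorbed) " (absorbed)" else ""))
  invisible(x)
}

#' Stochastic ensemble of TES simulations
#'
#' Runs `n` independent stochastic simulations of the TES network, each
#' starting from the deterministic steady state rounded to integer copy
#' numbers (round-half-to-even) and running for `duration` minutes, and
#' collects a per-cell terminal statistic: protein copies or the instantaneous
#' protein production rate `k_leak*m + k_act*c`. Per-run seeds are split from
#' the master seed by a counter-based mixing function (run index into
#' splitmix64), so ensembles are reproducible and order-independent.
#'
#' @param params a [tes_parameters()] object.
#' @param n ensemble size.
#' @param seed master seed.
#' @param statistic `"protein"` or `"production_rate"`.
#' @param duration,n_intervals,epsilon simulation controls (see
#'   [simulate_tauleap()]).
#' @param method `"tauleap"` (default) or `"ssa"` (exact).
#' @return An `ensemble`: list with `n`, `terminal_values`, `condition`
#'   (`u_in`, `u_tun`), `statistic`, `seed`, `method`.
#' @export
run_ensemble <- function(params, n = 4000, seed,
                         statistic = c("protein", "production_rate"),
                         duration = 100, n_intervals = 100, epsilon = 0.03,
                         method = c("tauleap", "ssa")) {
  statistic <- match.arg(statistic)
  method <- match.arg(method)
  stopifnot(inherits(params, "tes_parameters"), n >= 1)
  net <- build_tes_network(params)
  init <- round(c(steady_state(params)$m, steady_state(params)$s,
                  steady_state(params)$c, steady_state(params)$p))
  term <- ensemble_terminal_cpp(net$stoichiometry,
                                net$propensity_spec$rates,
                                net$propensity_spec$orders,
                                as.integer(init), duration,
                                as.integer(n_intervals), epsilon,
                                as.integer(n), as.double(seed), method)
  colnames(term) <- net$species
  vals <- if (statistic == "protein") {
    term[, "p"]
  } else {
    params$k_leak * term[, "m"] + params$k_act * term[, "c"]
  }
  structure(list(n = n, terminal_values = as.numeric(vals),
                 terminal_states = term,
                 condition = c(u_in = params$u_in, u_tun = params$u_tun),
                 statistic = statistic, seed = seed, method = method),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("Stochastic ensemble: n=%d, %s, u_in=%.3g u_tun=%.3g (%s)\n",
              x$n, x$statistic, x$condition["u_in"], x$condition["u_tun"],
              x$method))
  invisible(x)
}

#' Terminal states of a stochastic ensemble over an arbitrary network
#'
#' Lower-level companion to [run_ensemble()]: runs `n` independent simulations
#' of any [reaction_network()] from a fixed integer state and returns the
#' matrix of terminal copy numbers. Per-run seeds are split from the master
#' seed by the same counter-based scheme.
#'
#' @inheritParams simulate_tauleap
#' @param n number of runs.
#' @param method `"tauleap"` or `"ssa"`.
#' @return numeric matrix, `n` x species.
#' @export
ensemble_terminal_states <- function(network, initial, duration = 100,
                                     n_intervals = 100, n, seed,
                                     method = c("tauleap", "ssa"),
                                     epsilon = 0.03) {
  method <- match.arg(method)
  check_stoch_args(network, initial, duration, seed)
  out <- ensemble_terminal_cpp(network$stoichiometry,
                               network$propensity_spec$rates,
                               network$propensity_spec$orders,
                               as.integer(initial), duration,
                               as.integer(n_intervals), epsilon,
                               as.integer(n), as.double(seed), method)
  colnames(out) <- network$species
  out
}

#' Histogram intersection between two ensembles
#'
#' Bins both ensembles' terminal statistics on shared edges and delegates to
#' [intersection_fraction()], the same overlap statistic used for measured
#' fluorescence distributions.
#'
#' @param a,b `ensemble` objects (non-empty).
#' @param n_bins number of shared bins.
#' @return intersection fraction in `[0, 1]`.
#' @export
ensemble_intersection <- function(a, b, n_bins = 256) {
  stopifnot(inherits(a, "ensemble"), inherits(b, "ensemble"),
            a$n >= 1, b$n >= 1)
  pair <- histogram_pair(a$terminal_values, b$terminal_values,
                         n_bins = n_bins, scale = "linear")
  intersection_fraction(pair)
}
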