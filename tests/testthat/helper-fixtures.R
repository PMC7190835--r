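# Shared fixtures: nominal parameter sets, small networks, and independent
# oracles used across the suite.

nominal_params <- function(...) {
  do.call(tes_parameters,
          modifyList(list(u_in = 1.5, u_tun = 38), list(...)))
}

# direct transcription of the four TES ODEs, independent of the package's
# network assembly (the oracle for build_tes_network)
hand_rhs <- function(state, p) {
  m <- state[1]; s <- state[2]; cc <- state[3]; pr <- state[4]
  c(p$u_in - p$k_on * m * s + p$k_off * cc - (p$delta_m + p$phi) * m,
    p$booster_factor * p$u_tun - p$k_on * m * s + p$k_off * cc - (p$delta_s + p$phi) * s,
    p$k_on * m * s - p$k_off * cc - (p$delta_c + p$phi) * cc,
    p$k_leak * m + p$k_act * cc - (p$delta_p + p$phi) * pr)
}

# single-species birth-death network: 0 -> X at lambda, X -> 0 at delta
birth_death_network <- function(lambda, delta) {
  reaction_network(species = "x",
                   stoichiometry = matrix(c(1L, -1L), 1, 2),
                   rates = c(lambda, delta),
                   orders = matrix(c(0L, 1L), 1, 2),
                   reaction_names = c("birth", "death"))
}

# random positive parameter set for property sweeps
random_params <- function() {
  tes_parameters(u_in = runif(1, 0.01, 50),
                 u_tun = runif(1, 0.01, 50),
                 k_on = runif(1, 0.001, 0.5),
                 k_off = runif(1, 0, 0.5),
                 k_leak = runif(1, 0.001, 0.1),
                 k_act = runif(1, 0.2, 5),
                 delta_m = runif(1, 0.05, 0.7),
                 delta_s = runif(1, 0.05, 0.7),
                 delta_c = runif(1, 0.05, 0.7),
                 delta_p = runif(1, 0, 0.05),
                 phi = runif(1, 0.005, 0.05),
                 booster_factor = 1 + runif(1, 0, 4))
}
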