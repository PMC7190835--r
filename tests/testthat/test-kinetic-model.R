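test_that("steady state handles switched-off limits exactly", {
  # input off: no transcript, no protein; sRNA at its own balance
  p <- nominal_params(u_in = 0, booster_factor = 2)
  st <- steady_state(p)
  expect_equal(st$m, 0)
  expect_equal(st$c, 0)
  expect_equal(st$p, 0)
  expect_equal(st$s, 2 * p$u_tun / (p$delta_s + p$phi), tolerance = 1e-10)

  # no sRNA and no leak: bare mRNA, no translation
  q <- nominal_params(u_tun = 0, k_leak = 0)
  st2 <- steady_state(q)
  expect_equal(st2$p, 0)
  expect_equal(st2$m, q$u_in / (q$delta_m + q$phi), tolerance = 1e-10)
  expect_equal(st2$production_rate, 0)
})

test_that("steady state agrees with long-time ODE integration", {
  p <- nominal_params()
  st <- steady_state(p)
  traj <- simulate_ode_timecourse(p, initial = c(0, 0, 0, 0),
                                  duration = 1e4, n_points = 20)
  terminal <- as.numeric(traj[nrow(traj), c("m", "s", "c", "p")])
  expect_equal(terminal, c(st$m, st$s, st$c, st$p), tolerance = 1e-3)
  expect_lt(st$residual, 1e-9)
})

test_that("no-binding limit matches the closed form to 1e-9 relative", {
  set.seed(7)
  for (i in 1:20) {
    p <- random_params()
    p <- update_params(p, k_on = 0)
    st <- steady_state(p)
    closed <- p$k_leak * p$u_in / ((p$delta_m + p$phi) * (p$delta_p + p$phi))
    expect_equal(st$p, closed, tolerance = 1e-9)
  }
})

test_that("binding conserves total transcript pools without degradation", {
  # all delta = phi = 0 and k_off = 0: m + c and s + c grow linearly at the
  # transcription fluxes along the trajectory (phi tiny to satisfy invariants)
  p <- tes_parameters(u_in = 2, u_tun = 3, k_on = 0.05, k_off = 0,
                      k_leak = 0.01, k_act = 1,
                      delta_m = 0, delta_s = 0, delta_c = 0, delta_p = 0,
                      phi = 1e-12, booster_factor = 1)
  tr <- simulate_ode_timecourse(p, c(0, 0, 0, 0), duration = 50, n_points = 50)
  expect_equal(tr$m + tr$c, p$u_in * tr$time, tolerance = 1e-6)
  expect_equal(tr$s + tr$c, p$u_tun * tr$time, tolerance = 1e-6)
})

test_that("ODE time course is anchored at its initial state and at fixed points", {
  p <- nominal_params()
  tr <- simulate_ode_timecourse(p, c(1, 2, 3, 4), duration = 10, n_points = 10)
  expect_equal(as.numeric(tr[1, c("m", "s", "c", "p")]), c(1, 2, 3, 4))

  # zero rates: constant trajectory
  z <- tes_parameters(u_in = 0, u_tun = 0, k_on = 0, k_leak = 0, k_act = 0,
                      delta_m = 0, delta_s = 0, delta_c = 0, delta_p = 0,
                      phi = 1e-12)
  trz <- simulate_ode_timecourse(z, c(5, 6, 7, 8), duration = 100, n_points = 5)
  for (col in c("m", "s", "c", "p")) {
    expect_equal(trz[[col]], rep(trz[[col]][1], 6), tolerance = 1e-8)
  }

  # starting at the steady state stays flat to 0.1%
  st <- steady_state(p)
  trf <- simulate_ode_timecourse(p, st, duration = 500, n_points = 10)
  expect_equal(trf$p / st$p, rep(1, 11), tolerance = 1e-3)
})

test_that("trajectory from zero relaxes to the steady state", {
  p <- nominal_params()
  st <- steady_state(p)
  dur <- 20 / min(p$delta_m + p$phi, p$delta_s + p$phi, p$phi + p$delta_p)
  tr <- simulate_ode_timecourse(p, c(0, 0, 0, 0), duration = dur, n_points = 10)
  expect_equal(as.numeric(tr[11, c("m", "s", "c", "p")]),
               c(st$m, st$s, st$c, st$p), tolerance = 5e-3)
})

test_that("steady-state output is monotone in the expected parameter directions", {
  set.seed(11)
  for (i in 1:25) {
    p <- random_params()
    base <- steady_state(p)$p
    up <- function(...) steady_state(update_params(p, ...))$p
    expect_gte(up(u_in = p$u_in * 1.3) - base, -1e-8)
    expect_gte(up(u_tun = p$u_tun * 1.3) - base, -1e-8)
    expect_gte(up(k_act = p$k_act * 1.3) - base, -1e-8)
    expect_lte(up(delta_m = p$delta_m * 1.3) - base, 1e-8)
    expect_lte(up(delta_p = p$delta_p * 1.3) - base, 1e-8)
    expect_lte(up(delta_s = p$delta_s * 1.3) - base, 1e-8)
  }
})

test_that("response surface equals pointwise steady-state calls and shifts with tuner", {
  p <- nominal_params()
  ig <- c(0.5, 2, 8)
  tg <- c(0.1, 1, 10)
  rs <- response_surface(p, ig, tg)
  for (r in seq_len(nrow(rs))) {
    st <- steady_state(update_params(p, u_in = rs$input_activity[r],
                                     u_tun = rs$tuner_activity[r]))
    expect_equal(rs$output[r], st$p, tolerance = 1e-10)
  }
  # flat zero when tuner off and no leak (tuner_grid = [0], k_leak = 0)
  flat <- response_surface(update_params(p, k_leak = 0), ig, 0)
  expect_equal(flat$output, rep(0, 3))
  expect_error(response_surface(p, c(2, 1), tg), "increasing")
})

test_that("sRNA-limited plateau bounds the output at fixed low tuner", {
  p <- nominal_params(u_tun = 0.5)
  for (u in c(10, 100, 1000)) {
    st <- steady_state(update_params(p, u_in = u))
    bound <- (p$k_act * (st$s + st$c) + p$k_leak * st$m) / (p$delta_p + p$phi)
    expect_lte(st$p, bound * (1 + 1e-9))
  }
  # saturation: doubling a large input barely moves the activated component
  p1 <- steady_state(update_params(p, u_in = 500))
  p2 <- steady_state(update_params(p, u_in = 1000))
  act1 <- p$k_act * p1$c
  act2 <- p$k_act * p2$c
  expect_lt(act2 / act1, 1.05)
})

test_that("THS/tuner ratio behaves under symmetry, excess and sweeps", {
  # symmetric rates: ratio exactly 1
  p <- tes_parameters(u_in = 5, u_tun = 5, delta_m = 0.2, delta_s = 0.2,
                      delta_c = 0.2, booster_factor = 1, k_on = 0.05)
  expect_equal(ths_tuner_ratio(p), 1, tolerance = 1e-9)
  # sRNA in excess
  p2 <- update_params(p, u_tun = 50)
  expect_lt(ths_tuner_ratio(p2), 1)
  # undefined when no sRNA at all
  p3 <- tes_parameters(u_tun = 0, u_in = 1)
  expect_warning(r <- ths_tuner_ratio(p3), "undefined")
  expect_true(is.na(r))
  # strictly increasing in u_in; crossing of 1 matches an integration-based
  # bisection oracle to 1e-6
  base <- tes_parameters(u_tun = 10, delta_m = 0.2, delta_s = 0.2,
                         delta_c = 0.2, k_on = 0.05)
  sweep <- vapply(c(1, 3, 10, 30), function(u)
    ths_tuner_ratio(update_params(base, u_in = u)), numeric(1))
  expect_true(all(diff(sweep) > 0))
  ratio_by_integration <- function(u_in) {
    pp <- update_params(base, u_in = u_in)
    tr <- simulate_ode_timecourse(pp, c(0, 0, 0, 0), duration = 5000,
                                  n_points = 4)
    z <- tr[5, ]
    (z$m + z$c) / (z$s + z$c)
  }
  lo <- 1; hi <- 30
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (ratio_by_integration(mid) < 1) lo <- mid else hi <- mid
  }
  cross_oracle <- (lo + hi) / 2
  f <- function(u) ths_tuner_ratio(update_params(base, u_in = u)) - 1
  cross_pkg <- uniroot(f, c(1, 30), tol = 1e-9)$root
  expect_equal(cross_pkg, cross_oracle, tolerance = 1e-6)
})

test_that("fold-change profile: identities, decoupling and pointwise oracle", {
  p <- nominal_params()
  tg <- c(0.1, 1, 10)
  # equal inputs are rejected by the contract (high must exceed low)
  expect_error(fold_change_profile(p, 2, 2, tg), "u_in_high")
  # a switch with no contrast (k_leak = k_act) decouples fold from tuner
  pd <- update_params(p, k_leak = 0.5, k_act = 0.5)
  fd <- fold_change_profile(pd, 0.5, 8, tg)
  expect_equal(fd$fold, rep(fd$fold[1], 3), tolerance = 1e-8)
  # values equal ratios of independent steady-state calls
  fc <- fold_change_profile(p, 0.158, 521, c(1e-4, 0.3, 1.5, 7.6, 38, 190))
  for (r in seq_len(nrow(fc))) {
    hi <- steady_state(update_params(p, u_in = 521, u_tun = fc$tuner_activity[r]))$p
    lo <- steady_state(update_params(p, u_in = 0.158, u_tun = fc$tuner_activity[r]))$p
    expect_equal(fc$fold[r], hi / lo, tolerance = 1e-10)
  }
  # undefined fold reported with the raw pair when the low state is zero
  pz <- update_params(p, k_leak = 0)
  fz <- fold_change_profile(update_params(pz, u_tun = 0), 0, 5, 0)
  expect_true(is.na(fz$fold))
  expect_equal(fz$p_low, 0)
})

test_that("NOT gate response: limits, monotonicity and transition shift", {
  p <- nominal_params()
  g <- gate_parameters()
  # no repressor at all: fully on
  off <- tes_parameters(u_in = 0, u_tun = 0, k_leak = 0)
  expect_equal(not_gate_response(off, g, u_in = 0, u_tun = 0), g$p_out_max)
  # saturating repressor: within 1% of the floor
  sat <- not_gate_response(p, g, u_in = 5000, u_tun = 200)
  expect_lt(sat, g$p_out_min + 0.01 * (g$p_out_max - g$p_out_min))
  # non-increasing in input at fixed tuner
  resp <- not_gate_response(p, g, u_in = c(0.1, 1, 10, 100, 1000), u_tun = 10)
  expect_true(all(diff(resp) <= 1e-9))
  expect_true(all(resp >= g$p_out_min - 1e-12 & resp <= g$p_out_max + 1e-12))
  # the half-maximal input decreases with tuner, matching bisection to 1e-6
  half <- (g$p_out_max + g$p_out_min) / 2
  half_input <- function(u_tun) {
    f <- function(u) not_gate_response(p, g, u_in = u, u_tun = u_tun) - half
    lo <- 1e-4; hi <- 5000
    for (i in 1:50) {
      mid <- sqrt(lo * hi)
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    sqrt(lo * hi)
  }
  k_lo_tuner <- half_input(2)
  k_hi_tuner <- half_input(50)
  expect_lt(k_hi_tuner, k_lo_tuner)
  u <- uniroot(function(u) not_gate_response(p, g, u_in = u, u_tun = 2) - half,
               c(1e-4, 5000), tol = 1e-10)$root
  expect_equal(u, k_lo_tuner, tolerance = 1e-6)
})

test_that("NOR gate is symmetric, additive and truth-table ordered", {
  p <- nominal_params()
  g <- gate_parameters()
  expect_equal(nor_gate_response(p, g, 3.2, 0.7, u_tun = 10),
               nor_gate_response(p, g, 0.7, 3.2, u_tun = 10), tolerance = 1e-12)
  expect_equal(nor_gate_response(p, g, 1, 2, u_tun = 10),
               not_gate_response(p, g, u_in = 3, u_tun = 10), tolerance = 1e-12)
  off <- tes_parameters(u_in = 0, u_tun = 0, k_leak = 0)
  expect_equal(nor_gate_response(off, g, 0, 0, u_tun = 0), g$p_out_max)
  hi <- 500
  o00 <- nor_gate_response(p, g, 0, 0, u_tun = 10)
  o10 <- nor_gate_response(p, g, hi, 0, u_tun = 10)
  o01 <- nor_gate_response(p, g, 0, hi, u_tun = 10)
  o11 <- nor_gate_response(p, g, hi, hi, u_tun = 10)
  expect_gt(o00, o10)
  expect_equal(o10, o01)
  expect_gte(o10, o11)
  # iso-output transition moves to lower inputs at high tuner
  thresh <- 0.5 * g$p_out_max
  contour_input <- function(u_tun) {
    uniroot(function(u) nor_gate_response(p, g, u, 0, u_tun = u_tun) - thresh,
            c(1e-4, 5000), tol = 1e-10)$root
  }
  expect_lt(contour_input(50), contour_input(2))
})

test_that("resource coupling reduces output and vanishes with infinite ribosomes", {
  p <- nominal_params()
  st <- steady_state(p)
  h <- host_parameters()
  cs <- coupled_steady_state(p, h)
  expect_lte(cs$p, st$p)
  expect_gt(attr(cs, "ribosome_fraction"), 0)
  # infinite-resource limit
  big <- coupled_steady_state(p, host_parameters(R_total = 1e12))
  expect_equal(big$p, st$p, tolerance = 1e-3)
  # no construct demand: only the host load remains, p scales exactly by f
  p0 <- update_params(p, k_leak = 0, k_act = 0)
  c0 <- coupled_steady_state(p0, h)
  expect_equal(c0$p, 0)
  # deficit grows monotonically with translation demand
  defs <- vapply(seq(0.2, 2, length.out = 10), function(ka) {
    pp <- update_params(p, k_act = ka)
    steady_state(pp)$p - coupled_steady_state(pp, h)$p
  }, numeric(1))
  expect_true(all(diff(defs) > 0))
})

test_that("DDE model reduces to the ODE and delays the protein rise", {
  p <- nominal_params()
  st <- steady_state(p)
  tr_ode <- simulate_ode_timecourse(p, c(0, 0, 0, 0), duration = 80, n_points = 320)
  tr_dde0 <- simulate_dde_timecourse(p, c(transcription = 0, translation = 0),
                                     initial = c(0, 0, 0, 0), duration = 80,
                                     n_points = 320)
  expect_equal(tr_dde0$p, tr_ode$p, tolerance = 1e-6)

  # constant-input steady initial: flat regardless of delays
  flat <- simulate_dde_timecourse(p, c(transcription = 2, translation = 5),
                                  initial = st, duration = 50, n_points = 50)
  expect_equal(flat$p / st$p, rep(1, 51), tolerance = 1e-6)

  # 5-min translation delay shifts the half-max crossing by the delay
  tr_dde <- simulate_dde_timecourse(p, c(transcription = 0, translation = 5),
                                    initial = c(0, 0, 0, 0), duration = 80,
                                    n_points = 320)
  half <- 0.5 * st$p
  t_ode <- tr_ode$time[min(which(tr_ode$p >= half))]
  t_dde <- tr_dde$time[min(which(tr_dde$p >= half))]
  expect_equal(t_dde - t_ode, 5, tolerance = 0.25)
  # terminal values are delay-independent
  long <- simulate_dde_timecourse(p, c(translation = 5), initial = c(0, 0, 0, 0),
                                  duration = 600, n_points = 60)
  expect_equal(long$p[61], st$p, tolerance = 5e-3)
})
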