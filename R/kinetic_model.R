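#' @useDynLib testune, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median uniroot rnorm runif rlnorm quantile setNames coef
#'   nlminb approx cor IQR qnorm
#' @importFrom utils read.csv write.csv modifyList
NULL

# Hand-written TES ODE right-hand side, state = (m, s, c, p).
# dm/dt = u_in            - k_on m s + k_off c - (delta_m + phi) m
# ds/dt = b u_tun         - k_on m s + k_off c - (delta_s + phi) s
# dc/dt = k_on m s - k_off c            - (delta_c + phi) c
# dp/dt = k_leak m + k_act c            - (delta_p + phi) p
tes_rhs <- function(state, p) {
  m <- state[1]; s <- state[2]; cc <- state[3]; pr <- state[4]
  bind <- p$k_on * m * s - p$k_off * cc
  c(u_in_flux  = p$u_in - bind - (p$delta_m + p$phi) * m,
    s_flux     = p$booster_factor * p$u_tun - bind - (p$delta_s + p$phi) * s,
    c_flux     = bind - (p$delta_c + p$phi) * cc,
    p_flux     = p$k_leak * m + p$k_act * cc - (p$delta_p + p$phi) * pr)
}

new_steady_state <- function(m, s, c, p, params, residual = NA_real_) {
  structure(list(m = m, s = s, c = c, p = p,
                 production_rate = params$k_leak * m + params$k_act * c,
                 residual = residual),
            class = "tes_steady_state")
}

#' @export
print.tes_steady_state <- function(x, ...) {
  cat(sprintf("TES steady state: m=%.4g s=%.4g c=%.4g p=%.4g (production %.4g /min, residual %.2g)\n",
              x$m, x$s, x$c, x$p, x$production_rate, x$residual))
  invisible(x)
}

#' Steady state of the TES model
#'
#' Computes the unique non-negative steady state of the four-species TES ODE
#' system. Because translation is catalytic (it does not consume mRNA), the
#' steady state reduces exactly to a single scalar equation in the net flux
#' `q = (delta_c + phi) * c` routed through the complex, bracketed on
#' `[0, min(u_in, booster_factor * u_tun)]`; the root is found to machine
#' precision and is therefore independent of any initial guess. The residual of
#' the full right-hand side is verified against `tol` (copies/min); if the
#' check fails, long-time integration is used as a fallback before erroring.
#'
#' @param params a [tes_parameters()] object.
#' @param tol absolute tolerance on the steady-state residual
#'   `max |d state/dt|`, in copies/min.
#' @return A `tes_steady_state` with fields `m`, `s`, `c`, `p`,
#'   `production_rate` (`k_leak*m + k_act*c`) and `residual`.
#' @export
steady_state <- function(params, tol = 1e-9) {
  stopifnot(inherits(params, "tes_parameters"))
  p <- params
  dm <- p$delta_m + p$phi
  ds <- p$delta_s + p$phi
  dc <- p$delta_c + p$phi
  dp <- p$delta_p + p$phi
  u_s <- p$booster_factor * p$u_tun

  q_max <- min(p$u_in, u_s)
  m_of <- function(q) (p$u_in - q) / dm
  s_of <- function(q) (u_s - q) / ds

  if (p$k_on == 0 || q_max == 0) {
    q <- 0
  } else {
    if (p$k_off + dc <= 0) {
      stop("no steady state: complex is produced (k_on > 0) but never removed ",
           "(k_off + delta_c + phi = 0)")
    }
    g <- function(q) dc * p$k_on * m_of(q) * s_of(q) / (p$k_off + dc) - q
    if (g(q_max) >= 0) {
      q <- q_max
    } else {
      q <- uniroot(g, c(0, q_max), tol = 1e-13 * max(1, q_max))$root
    }
  }
  m <- m_of(q)
  s <- s_of(q)
  cc <- if (p$k_off + dc > 0) p$k_on * m * s / (p$k_off + dc) else 0
  pr <- (p$k_leak * m + p$k_act * cc) / dp
  st <- c(m, s, cc, pr)
  res <- max(abs(tes_rhs(st, p)))

  if (!is.finite(res) || res > tol) {
    traj <- simulate_ode_timecourse(params, initial = st,
                                    duration = 20 / max(min(dm, ds, dc, dp), 1e-6),
                                    n_points = 10)
    st <- as.numeric(traj[nrow(traj), c("m", "s", "c", "p")])
    res <- max(abs(tes_rhs(st, p)))
    if (!is.finite(res) || res > tol) {
      stop(sprintf("steady-state solve did not converge: residual %.3g > tol %.3g", res, tol))
    }
  }
  new_steady_state(st[1], st[2], st[3], st[4], p, residual = res)
}

#' Integrate the TES ODE model over time
#'
#' Stiff-capable initial-value integration (lsoda) of the TES equations.
#'
#' @param params a [tes_parameters()] object.
#' @param initial numeric length-4 state `(m, s, c, p)`, or a `tes_steady_state`.
#'   Defaults to all zero.
#' @param duration simulated time (min).
#' @param n_points number of output intervals; the trajectory is reported at
#'   `n_points + 1` equally spaced times starting at 0.
#' @param rtol,atol integrator tolerances.
#' @return data.frame with columns `time, m, s, c, p, production_rate`; the
#'   first row equals `initial`.
#' @export
simulate_ode_timecourse <- function(params, initial = c(0, 0, 0, 0),
                                    duration, n_points = 200,
                                    rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "tes_parameters"), duration > 0, n_points >= 1)
  initial <- as_state_vector(initial)
  if (any(initial < 0)) stop("initial state must be non-negative")
  times <- seq(0, duration, length.out = n_points + 1)
  f <- function(t, y, parms) list(tes_rhs(y, params))
  out <- deSolve::lsoda(y = setNames(initial, c("m", "s", "c", "p")),
                        times = times, func = f, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    stop("ODE integration failed near t = ", max(out[, "time"]), " min")
  }
  out <- as.data.frame(out)
  # lsoda can undershoot zero by ~atol; clip within tolerance only
  for (sp in c("m", "s", "c", "p")) {
    neg <- out[[sp]] < 0
    if (any(out[[sp]] < -1e3 * atol)) {
      stop("trajectory went negative beyond tolerance in species ", sp)
    }
    out[[sp]][neg] <- 0
  }
  out$production_rate <- params$k_leak * out$m + params$k_act * out$c
  out
}

as_state_vector <- function(x) {
  if (inherits(x, "tes_steady_state")) return(c(x$m, x$s, x$c, x$p))
  x <- as.numeric(x)
  if (length(x) != 4) stop("state must have 4 entries (m, s, c, p)")
  x
}

#' Steady-state response surface over input and tuner grids
#'
#' Computes the model response function family: one curve of steady-state
#' output versus input-promoter activity per tuner-promoter activity, the
#' model-side analogue of the measured response functions.
#'
#' @param params a [tes_parameters()] object (its `u_in`/`u_tun` are overridden
#'   cell by cell).
#' @param input_grid,tuner_grid strictly increasing, non-negative promoter
#'   activities (RNAP/min).
#' @param output `"protein"` (steady-state protein copies, default) or
#'   `"production_rate"` (protein synthesis flux, /min).
#' @return tidy data.frame `(tuner_activity, input_activity, output, units)`.
#' @export
response_surface <- function(params, input_grid, tuner_grid,
                             output = c("protein", "production_rate")) {
  output <- match.arg(output)
  check_grid(input_grid, "input_grid")
  check_grid(tuner_grid, "tuner_grid")
  grid <- expand.grid(input_activity = input_grid, tuner_activity = tuner_grid)
  vals <- vapply(seq_len(nrow(grid)), function(i) {
    st <- tryCatch(
      steady_state(update_params(params, u_in = grid$input_activity[i],
                                 u_tun = grid$tuner_activity[i])),
      error = function(e) stop("steady_state failed at input=",
                               grid$input_activity[i], ", tuner=",
                               grid$tuner_activity[i], ": ",
                               conditionMessage(e), call. = FALSE))
    if (output == "protein") st$p else st$production_rate
  }, numeric(1))
  data.frame(tuner_activity = grid$tuner_activity,
             input_activity = grid$input_activity,
             output = vals,
             units = if (output == "protein") "copies" else "copies/min")
}

check_grid <- function(g, name) {
  if (!length(g)) stop(name, " must be non-empty")
  if (any(g < 0)) stop(name, " must be non-negative")
  if (length(g) > 1 && any(diff(g) <= 0)) stop(name, " must be strictly increasing")
  invisible(g)
}

#' Steady-state THS transcript to tuner sRNA ratio
#'
#' Ratio of total THS transcript to total tuner sRNA at steady state. By
#' default the mRNA-sRNA complex is counted in both pools,
#' `(m + c) / (s + c)`; `free_only = TRUE` gives `m / s`.
#'
#' @param params a [tes_parameters()] object.
#' @param free_only count only free species.
#' @return the ratio (dimensionless); `NA` with a warning when the sRNA pool is
#'   zero (ratio undefined, not infinite).
#' @export
ths_tuner_ratio <- function(params, free_only = FALSE) {
  st <- steady_state(params)
  num <- if (free_only) st$m else st$m + st$c
  den <- if (free_only) st$s else st$s + st$c
  if (den <= 0) {
    warning("total sRNA pool is zero at steady state; ratio undefined")
    return(NA_real_)
  }
  num / den
}

#' Deterministic on/off fold change across tuner levels
#'
#' For each tuner activity, the ratio of steady-state protein at a high input
#' to that at a low input. The profile is U-shaped: it equals the
#' transcription-rate ratio `u_in_high / u_in_low` in both the leak-dominated
#' (tuner to 0) and fully-activated (tuner to infinity) limits, and dips in
#' between, where the off state is already sRNA-activated while the on state
#' is still sRNA-limited. At every positive tuner level the fold change
#' therefore stays below its leak-limit value: switching translation on
#' compresses the on/off contrast rather than amplifying it.
#'
#' @param params a [tes_parameters()] object.
#' @param u_in_low,u_in_high input-promoter activities (RNAP/min),
#'   `u_in_high > u_in_low >= 0`.
#' @param tuner_grid tuner activities to profile.
#' @return data.frame `(tuner_activity, p_low, p_high, fold)`; `fold` is `NA`
#'   when the low-state output is zero (the raw pair is still returned).
#' @export
fold_change_profile <- function(params, u_in_low, u_in_high, tuner_grid) {
  if (!(u_in_high > u_in_low) || u_in_low < 0) {
    stop("need u_in_high > u_in_low >= 0")
  }
  check_grid(tuner_grid, "tuner_grid")
  rows <- lapply(tuner_grid, function(ut) {
    p_lo <- steady_state(update_params(params, u_in = u_in_low, u_tun = ut))$p
    p_hi <- steady_state(update_params(params, u_in = u_in_high, u_tun = ut))$p
    data.frame(tuner_activity = ut, p_low = p_lo, p_high = p_hi,
               fold = if (p_lo > 0) p_hi / p_lo else NA_real_)
  })
  do.call(rbind, rows)
}

#' Output promoter activity of the TES-driven NOT gate
#'
#' The TES protein output is a repressor of the output promoter; the gate
#' output follows a repression Hill function of the steady-state repressor
#' copy number. The effective repressor transcription input is
#' `u_in + kappa_rt` (read-through from the upstream tuner unit).
#'
#' @param params a [tes_parameters()] object; `u_in` may be overridden.
#' @param gate a [gate_parameters()] object.
#' @param u_in input-promoter activity (RNAP/min); vectorized.
#' @param u_tun tuner-promoter activity (RNAP/min), scalar.
#' @return output promoter activity, in `gate`'s units; always within
#'   `[p_out_min, p_out_max]`.
#' @export
not_gate_response <- function(params, gate, u_in = params$u_in,
                              u_tun = params$u_tun) {
  stopifnot(inherits(gate, "gate_parameters"), length(u_tun) == 1L)
  vapply(u_in, function(u) {
    st <- steady_state(update_params(params, u_in = u + gate$kappa_rt,
                                     u_tun = u_tun))
    repression_hill(st$p, gate)
  }, numeric(1))
}

repression_hill <- function(p, gate) {
  Kn <- gate$K_R^gate$n_R
  gate$p_out_min + (gate$p_out_max - gate$p_out_min) * Kn / (Kn + p^gate$n_R)
}

#' Output promoter activity of the TES-driven NOR gate
#'
#' Two tandem input promoters transcribe the same repressor unit; their RNAP
#' fluxes add, so the NOR output equals the NOT response at effective input
#' `u_a + u_b`. The response is symmetric in its two inputs and reproduces the
#' NOR truth table ordering at default parameters.
#'
#' @inheritParams not_gate_response
#' @param u_a,u_b activities of input promoters A and B (RNAP/min); recycled
#'   elementwise.
#' @export
nor_gate_response <- function(params, gate, u_a, u_b, u_tun = params$u_tun) {
  stopifnot(all(u_a >= 0), all(u_b >= 0))
  not_gate_response(params, gate, u_in = u_a + u_b, u_tun = u_tun)
}

#' Steady state under shared-ribosome resource coupling
#'
#' Couples the TES to a lumped model of the host's translational resources.
#' Translation proceeds at a fraction `f = R_free / (K_rib + R_free)` of its
#' maximal rate, where the free ribosome pool solves the self-consistent
#' allocation balance
#' `R_total = R_free + f * (host_demand + k_leak*m + k_act*c)`,
#' i.e. bound ribosomes are proportional to the total translational demand.
#' Because translation is catalytic, the RNA steady state is unaffected and
#' the coupled protein output is `f` times the uncoupled one, capturing the
#' retroactivity-like drop in output when the construct burdens the cell.
#'
#' @param params a [tes_parameters()] object.
#' @param host a [host_parameters()] object.
#' @param tol fixed-point tolerance on the allocation balance.
#' @param max_iter iteration cap.
#' @return A `tes_steady_state` with attributes `ribosome_fraction` (`f`) and
#'   `R_free`.
#' @export
coupled_steady_state <- function(params, host, tol = 1e-9, max_iter = 200) {
  stopifnot(inherits(host, "host_parameters"))
  un <- steady_state(params)
  demand <- host$host_demand + params$k_leak * un$m + params$k_act * un$c
  f <- 1
  for (it in seq_len(max_iter)) {
    # balance is quadratic in R_free at fixed demand; solve the positive root
    b <- host$K_rib + demand - host$R_total
    R_free <- (-b + sqrt(b^2 + 4 * host$K_rib * host$R_total)) / 2
    f_new <- R_free / (host$K_rib + R_free)
    if (abs(f_new - f) < tol) {
      f <- f_new
      break
    }
    f <- f_new
  }
  resid <- abs(host$R_total - R_free - f * demand)
  if (resid > max(tol, 1e-6 * host$R_total)) {
    stop(sprintf("ribosome allocation fixed point did not converge: residual %.3g", resid))
  }
  eff <- update_params(params, k_leak = params$k_leak * f,
                       k_act = params$k_act * f)
  st <- new_steady_state(un$m, un$s, un$c, un$p * f, eff,
                         residual = un$residual)
  attr(st, "ribosome_fraction") <- f
  attr(st, "R_free") <- R_free
  st
}

#' Integrate the delay-differential variant of the TES model
#'
#' Identical to the ODE model except that mature transcript appears a fixed
#' time after initiation and protein appears a fixed time after its template
#' state, with the history held constant at the initial state. Constant
#' promoter inputs make the steady state delay-independent.
#'
#' @param params a [tes_parameters()] object.
#' @param delays named numeric `c(transcription = , translation = )` in min.
#'   The transcription delay shifts promoter flux terms (no effect for the
#'   constant inputs used here); the translation delay evaluates the protein
#'   production term at the lagged `(m, c)` state.
#' @inheritParams simulate_ode_timecourse
#' @return data.frame as [simulate_ode_timecourse()].
#' @export
simulate_dde_timecourse <- function(params,
                                    delays = c(transcription = 0, translation = 0),
                                    initial = c(0, 0, 0, 0),
                                    duration, n_points = 200,
                                    rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "tes_parameters"), duration > 0)
  if (any(delays < 0)) stop("delays must be >= 0")
  tau_tx <- if ("transcription" %in% names(delays)) delays[["transcription"]] else 0
  tau_tl <- if ("translation" %in% names(delays)) delays[["translation"]] else 0
  initial <- as_state_vector(initial)
  if (all(c(tau_tx, tau_tl) == 0)) {
    return(simulate_ode_timecourse(params, initial, duration, n_points,
                                   rtol = rtol, atol = atol))
  }
  times <- seq(0, duration, length.out = n_points + 1)
  lagged <- function(t, tau, idx, y) {
    if (tau <= 0 || t - tau <= 0) {
      if (t - tau <= 0 && tau > 0) initial[idx] else y[idx]
    } else {
      deSolve::lagvalue(t - tau, idx)
    }
  }
  f <- function(t, y, parms) {
    d <- tes_rhs(y, params)
    m_lag <- lagged(t, tau_tl, 1L, y)
    c_lag <- lagged(t, tau_tl, 3L, y)
    d[4] <- params$k_leak * m_lag + params$k_act * c_lag -
      (params$delta_p + params$phi) * y[4]
    list(d)
  }
  out <- deSolve::dede(y = setNames(initial, c("m", "s", "c", "p")),
                       times = times, func = f, parms = NULL,
                       rtol = rtol, atol = atol)
  out <- as.data.frame(out)
  out$production_rate <- params$k_leak * out$m + params$k_act * out$c
  out
}
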