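#' Hill response functions
#'
#' Activation: `y = y_min + (y_max - y_min) x^n / (K^n + x^n)`;
#' repression: `y = y_min + (y_max - y_min) K^n / (K^n + x^n)`.
#' `K` is the input activity at half-maximal output (the transition point) and
#' `n` the Hill coefficient.
#'
#' @param x input promoter activity (RPU or RNAP/min).
#' @param y_min,y_max output floor and ceiling (a.u.).
#' @param K transition point (input units).
#' @param n Hill coefficient.
#' @export
hill_activation <- function(x, y_min, y_max, K, n) {
  y_min + (y_max - y_min) * x^n / (K^n + x^n)
}

#' @rdname hill_activation
#' @export
hill_repression <- function(x, y_min, y_max, K, n) {
  y_min + (y_max - y_min) * K^n / (K^n + x^n)
}

#' Measured or simulated response curve
#'
#' @param input_activity input promoter activities (positive; repeated values
#'   are allowed and represent replicate measurements fitted jointly).
#' @param output output values (median YFP a.u., or model output), same length.
#' @param tuner_activity tuner promoter activity label (RPU).
#' @param design device identifier.
#' @return A `response_curve`.
#' @export
response_curve <- function(input_activity, output, tuner_activity = NA_real_,
                           design = "TES") {
  stopifnot(length(input_activity) == length(output))
  if (any(input_activity <= 0)) stop("input_activity grid must be positive")
  if (length(unique(input_activity)) < 4L) {
    stop("need >= 4 distinct input levels to fit a 4-parameter Hill function")
  }
  structure(list(input_activity = as.numeric(input_activity),
                 output = as.numeric(output),
                 tuner_activity = tuner_activity, design = design),
            class = "response_curve")
}

#' Fit an activation Hill function to a response curve
#'
#' Bounded nonlinear least squares of the activation Hill form to the curve's
#' output values, with residuals taken on a log10 scale (fluorescence medians
#' span decades and response functions are viewed on log axes).
#' Initialization: `y_min = min(y)`, `y_max = max(y)`, `K` at the geometric
#' median of the input grid, `n = 1`. Bounds: `y_min, y_max` in
#' `[0, 10 max(y)]`, `n` in `[0.3, 6]`, `K` in `[min(x)/10, 10 max(x)]`.
#'
#' A fit is flagged unreliable (values still returned) when the optimizer does
#' not converge, `K` lands on its bracket boundary, or the data's rank trend
#' contradicts the fitted orientation. A constant curve returns
#' `y_min = y_max = y` with `K = NA` (unidentifiable).
#'
#' @param curve a [response_curve()].
#' @return A `hill_fit`: `y_min`, `y_max`, `K`, `n`, `orientation`,
#'   `residual_norm` (log10-scale RSS), `reliable`, `reason`.
#' @export
fit_hill_activation <- function(curve) {
  fit_hill(curve, orientation = "activation")
}

#' Fit a repression Hill function to a response curve
#'
#' As [fit_hill_activation()] with the repression form (used for NOT/NOR gate
#' response functions).
#'
#' @inheritParams fit_hill_activation
#' @export
fit_hill_repression <- function(curve) {
  fit_hill(curve, orientation = "repression")
}

fit_hill <- function(curve, orientation) {
  stopifnot(inherits(curve, "response_curve"))
  x <- curve$input_activity
  y <- curve$output
  if (any(y < 0)) stop("outputs must be non-negative for log-scale fitting")

  if (diff(range(y)) <= 1e-9 * max(abs(y), 1e-300)) {
    return(new_hill_fit(y_min = y[1], y_max = y[1], K = NA_real_, n = NA_real_,
                        orientation = orientation, residual_norm = 0,
                        reliable = FALSE, reason = "constant curve: K unidentifiable"))
  }

  model <- if (orientation == "activation") hill_activation else hill_repression
  lower <- c(y_min = 0, y_max = 0, K = min(x) / 10, n = 0.3)
  upper <- c(y_min = 10 * max(y), y_max = 10 * max(y), K = 10 * max(x), n = 6)
  start <- c(y_min = max(min(y), 1e-6),
             y_max = max(y),
             K = exp(median(log(x))),
             n = 1)
  resid_fn <- function(par) {
    yhat <- model(x, par[1], par[2], par[3], par[4])
    log10(pmax(yhat, 1e-12)) - log10(pmax(y, 1e-12))
  }
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  par <- fit$par
  converged <- fit$info %in% 1:4
  rss <- sum(resid_fn(par)^2)

  reliable <- TRUE
  reason <- ""
  if (!converged) {
    reliable <- FALSE
    reason <- paste0("optimizer did not converge (info ", fit$info, ")")
  }
  k_lo <- min(x) / 10
  k_hi <- 10 * max(x)
  if (par["K"] <= k_lo * (1 + 1e-6) || par["K"] >= k_hi * (1 - 1e-6)) {
    reliable <- FALSE
    reason <- paste(reason, "K at bracket boundary", sep = if (nzchar(reason)) "; " else "")
  }
  trend <- suppressWarnings(cor(x, y, method = "spearman"))
  expected <- if (orientation == "activation") 1 else -1
  if (is.finite(trend) && trend * expected < 0) {
    reliable <- FALSE
    reason <- paste(reason, "data trend contradicts fitted orientation",
                    sep = if (nzchar(reason)) "; " else "")
  }
  new_hill_fit(par["y_min"], par["y_max"], par["K"], par["n"],
               orientation, residual_norm = sqrt(rss),
               reliable = reliable, reason = reason)
}

new_hill_fit <- function(y_min, y_max, K, n, orientation, residual_norm,
                         reliable, reason = "") {
  # report floor/ceiling in canonical order regardless of optimizer labelling
  lo <- min(y_min, y_max)
  hi <- max(y_min, y_max)
  structure(list(y_min = unname(lo), y_max = unname(hi), K = unname(K),
                 n = unname(n), orientation = orientation,
                 residual_norm = unname(residual_norm),
                 reliable = reliable, reason = reason),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit (%s): y_min=%.4g y_max=%.4g K=%.4g n=%.3g  residual=%.3g%s\n",
              x$orientation, x$y_min, x$y_max, x$K, x$n, x$residual_norm,
              if (!x$reliable) paste0("  [UNRELIABLE: ", x$reason, "]") else ""))
  invisible(x)
}

#' Evaluate a fitted Hill function
#'
#' @param fit a `hill_fit`.
#' @param x input activities.
#' @export
predict_hill <- function(fit, x) {
  f <- if (fit$orientation == "activation") hill_activation else hill_repression
  f(x, fit$y_min, fit$y_max, fit$K, fit$n)
}

#' Device performance metrics between on and off input states
#'
#' Computes, per biological replicate and then as mean +/- SD across
#' replicates: dynamic range (absolute difference of the on- and off-state
#' medians, a.u.), fold change (larger/smaller of the two medians, so >= 1 for
#' both activating and repressing devices), and — when event-level
#' distributions are supplied — the fraction of intersection between the on
#' and off distributions.
#'
#' @param medians data.frame with columns `input_activity`, `replicate`,
#'   `median` (corrected medians, a.u.).
#' @param on_state,off_state input activities selecting the two states
#'   (matched within a relative tolerance of 1e-6).
#' @param on_events,off_events optional lists of [event_sample()]s, one per
#'   replicate in the same order, for the intersection metric.
#' @param n_bins shared bins for the intersection histograms.
#' @return A `device_metrics`: each metric is `c(mean, sd)` over replicates;
#'   `per_replicate` holds the underlying values.
#' @export
device_metrics <- function(medians, on_state, off_state,
                           on_events = NULL, off_events = NULL, n_bins = 256) {
  stopifnot(is.data.frame(medians),
            all(c("input_activity", "replicate", "median") %in% names(medians)))
  pick <- function(state, label) {
    rows <- medians[abs(medians$input_activity - state) <=
                      1e-6 * max(state, 1e-300), , drop = FALSE]
    if (!nrow(rows)) {
      stop("no rows at ", label, " input state (input_activity = ", state, ")")
    }
    rows[order(rows$replicate), ]
  }
  on <- pick(on_state, "on")
  off <- pick(off_state, "off")
  if (nrow(on) != nrow(off)) {
    stop("on and off states have different replicate counts")
  }
  dr <- abs(on$median - off$median)
  fc <- pmax(on$median, off$median) / pmin(on$median, off$median)

  inter <- NULL
  if (!is.null(on_events) || !is.null(off_events)) {
    if (length(on_events) != length(off_events)) {
      stop("on_events and off_events must have the same replicate count")
    }
    inter <- vapply(seq_along(on_events), function(r) {
      pair <- histogram_pair(off_events[[r]]$yfp, on_events[[r]]$yfp,
                             n_bins = n_bins)
      intersection_fraction(pair)
    }, numeric(1))
  }
  msd <- function(v) c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0)
  structure(list(dynamic_range = msd(dr),
                 fold_change = msd(fc),
                 intersection = if (!is.null(inter)) msd(inter) else NULL,
                 per_replicate = list(dynamic_range = dr, fold_change = fc,
                                      intersection = inter),
                 n_replicates = nrow(on)),
            class = "device_metrics")
}

#' @export
print.device_metrics <- function(x, ...) {
  cat(sprintf("Device metrics over %d replicates:\n", x$n_replicates))
  cat(sprintf("  dynamic range: %.4g +/- %.2g a.u.\n",
              x$dynamic_range[1], x$dynamic_range[2]))
  cat(sprintf("  fold change:   %.4g +/- %.2g\n",
              x$fold_change[1], x$fold_change[2]))
  if (!is.null(x$intersection)) {
    cat(sprintf("  intersection:  %.3f +/- %.2g\n",
                x$intersection[1], x$intersection[2]))
  }
  invisible(x)
}

#' Span of Hill transition points across tuner levels
#'
#' @param fits list of `hill_fit`s, one per tuner level. Unreliable fits are
#'   excluded (and reported); at least 2 reliable fits are required.
#' @return list with `K_min`, `K_max`, `ratio` (`K_max / K_min`) and
#'   `excluded` (indices of unreliable fits).
#' @export
k_range <- function(fits) {
  stopifnot(is.list(fits), all(vapply(fits, inherits, logical(1), "hill_fit")))
  ok <- vapply(fits, function(f) isTRUE(f$reliable) && is.finite(f$K), logical(1))
  if (sum(ok) < 2L) {
    stop("k_range needs >= 2 reliable Hill fits (have ", sum(ok), ")")
  }
  Ks <- vapply(fits[ok], `[[`, numeric(1), "K")
  list(K_min = min(Ks), K_max = max(Ks), ratio = max(Ks) / min(Ks),
       excluded = which(!ok))
}

#' Calibrate a sensor: inducer concentration to RPU
#'
#' Divides the sensor's corrected medians by the RPU standard's median and fits
#' an activation Hill function over inducer concentration, yielding a
#' forward (concentration to RPU) and inverse (RPU to concentration) mapping.
#'
#' @param inducer_conc inducer concentrations (>= 0; at most one zero, which is
#'   used for the basal point but excluded from the positive-grid fit check).
#' @param sensor_medians corrected sensor medians (a.u.), one per concentration.
#' @param rpu_standard_median corrected median of the RPU standard (> 0).
#' @return A `sensor_calibration`: the `hill_fit` plus `forward(conc)` and
#'   `inverse(rpu)` functions and the calibration table.
#' @export
sensor_calibration <- function(inducer_conc, sensor_medians, rpu_standard_median) {
  if (rpu_standard_median <= 0) stop("rpu_standard_median must be positive")
  stopifnot(length(inducer_conc) == length(sensor_medians),
            all(inducer_conc >= 0))
  rpu <- sensor_medians / rpu_standard_median
  pos <- inducer_conc > 0
  curve <- response_curve(inducer_conc[pos], rpu[pos], design = "sensor")
  fit <- fit_hill_activation(curve)
  # anchor the basal level on the zero-concentration point when present
  if (any(!pos)) fit$y_min <- min(fit$y_min, mean(rpu[!pos]))
  forward <- function(conc) hill_activation(conc, fit$y_min, fit$y_max, fit$K, fit$n)
  inverse <- function(r) {
    r <- pmin(pmax(r, fit$y_min), fit$y_max)
    frac <- (r - fit$y_min) / (fit$y_max - fit$y_min)
    frac <- pmin(pmax(frac, 1e-12), 1 - 1e-12)
    fit$K * (frac / (1 - frac))^(1 / fit$n)
  }
  structure(list(fit = fit, forward = forward, inverse = inverse,
                 table = data.frame(inducer_conc = inducer_conc, rpu = rpu)),
            class = "sensor_calibration")
}
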