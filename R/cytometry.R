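#' Single-cell fluorescence event sample
#'
#' Container for per-event flow-cytometry measurements: a fluorescence channel
#' (YFP, arbitrary units) and optional forward/side scatter channels used for
#' density gating, plus condition metadata.
#'
#' @param yfp per-event fluorescence values (finite).
#' @param fsc,ssc optional scatter channels, same length as `yfp`.
#' @param condition named list/vector of metadata (design, input_activity,
#'   tuner_activity, replicate, ...).
#' @return An `event_sample` with fields `yfp`, `fsc`, `ssc`, `condition`,
#'   `n_events`.
#' @export
event_sample <- function(yfp, fsc = NULL, ssc = NULL, condition = list()) {
  yfp <- as.numeric(yfp)
  if (length(yfp) < 1L) stop("an event sample needs n_events >= 1")
  if (any(!is.finite(yfp))) stop("fluorescence values must be finite")
  for (ch in list(fsc = fsc, ssc = ssc)) {
    if (!is.null(ch) && length(ch) != length(yfp)) {
      stop("scatter channels must match the number of events")
    }
  }
  structure(list(yfp = yfp, fsc = fsc, ssc = ssc,
                 condition = condition, n_events = length(yfp)),
            class = "event_sample")
}

#' @export
print.event_sample <- function(x, ...) {
  cat(sprintf("Event sample: %d events, median YFP %.4g a.u.%s\n",
              x$n_events, median(x$yfp),
              if (!is.null(attr(x, "gate"))) " (gated)" else ""))
  invisible(x)
}

#' Bin two samples on shared histogram edges
#'
#' Builds the `histogram_pair` consumed by [intersection_fraction()]. Default
#' edges are `n_bins` log-spaced bins spanning the pooled 0.1st-99.9th
#' percentile range of both samples (stable for ~1e5 events spanning decades);
#' out-of-range events are counted in the end bins so no mass is lost.
#'
#' @param x,y numeric event values (e.g. YFP fluorescence).
#' @param n_bins number of bins when `edges` is not supplied.
#' @param scale `"log"` (default; requires positive percentile range) or
#'   `"linear"`.
#' @param edges optional explicit shared bin edges (monotone increasing).
#' @return A `histogram_pair`: list with `bin_edges`, `x_counts`, `y_counts`.
#' @export
histogram_pair <- function(x, y, n_bins = 256, scale = c("log", "linear"),
                           edges = NULL) {
  scale <- match.arg(scale)
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (is.null(edges)) {
    pooled <- c(x, y)
    qs <- quantile(pooled, c(0.001, 0.999), names = FALSE, type = 7)
    if (scale == "log") {
      qs[1] <- max(qs[1], min(pooled[pooled > 0], na.rm = TRUE))
      if (!all(qs > 0)) stop("log-scale binning requires positive values")
      if (qs[2] <= qs[1]) qs[2] <- qs[1] * 1.001
      edges <- exp(seq(log(qs[1]), log(qs[2]), length.out = n_bins + 1))
    } else {
      if (qs[2] <= qs[1]) qs[2] <- qs[1] + max(abs(qs[1]), 1) * 1e-6
      edges <- seq(qs[1], qs[2], length.out = n_bins + 1)
    }
  }
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  nb <- length(edges) - 1L
  bin_of <- function(v) pmin(pmax(findInterval(v, edges, all.inside = TRUE), 1L), nb)
  structure(list(bin_edges = edges,
                 x_counts = tabulate(bin_of(x), nbins = nb),
                 y_counts = tabulate(bin_of(y), nbins = nb)),
            class = "histogram_pair")
}

#' Fraction of intersection between two histograms
#'
#' Overlap statistic between two binned single-cell distributions on identical
#' bin edges. The default normalizes both histograms to unit mass and returns
#' `sum_i min(x_i, y_i)` — a symmetric fraction in `[0, 1]` that is 1 for
#' identical histograms and 0 for disjoint supports. `normalize = FALSE`
#' returns `sum_i min(x_i, y_i) / sum_i x_i` on raw counts. `literal = TRUE`
#' returns the per-bin-denominator form `sum_i min(x_i, y_i) / x_i` (kept for
#' auditability; it is not a fraction — it sums to the number of occupied bins
#' for identical histograms).
#'
#' @param pair a [histogram_pair()] (or any list with `bin_edges`, `x_counts`,
#'   `y_counts` on shared edges).
#' @param normalize normalize both histograms to unit mass first (default).
#' @param literal evaluate the per-bin-denominator form instead.
#' @return the intersection statistic.
#' @export
intersection_fraction <- function(pair, normalize = TRUE, literal = FALSE) {
  x <- pair$x_counts
  y <- pair$y_counts
  if (length(x) != length(y)) stop("histograms must share identical bin edges")
  if (length(pair$bin_edges) != length(x) + 1L) {
    stop("bin_edges must have length(counts) + 1")
  }
  if (any(x < 0) || any(y < 0)) stop("histogram counts must be non-negative")
  if (sum(x) <= 0) stop("reference histogram (x) has zero total count")
  if (literal) {
    keep <- x > 0
    return(sum(pmin(x[keep], y[keep]) / x[keep]))
  }
  if (normalize) {
    if (sum(y) <= 0) stop("histogram y has zero total count")
    x <- x / sum(x)
    y <- y / sum(y)
  }
  sum(pmin(x, y)) / sum(x)
}

#' Density gating on scatter channels
#'
#' Retains the events falling in the densest region of the 2-D
#' forward/side-scatter distribution, emulating automated density gating of a
#' homogeneous cell subpopulation: both channels are asinh-transformed
#' (a logicle-like compression, configurable cofactor), binned on a
#' `bins x bins` grid, the bin-count surface is smoothed with a Gaussian
#' kernel of `sigma` bins, and events are ranked by the smoothed density of
#' their bin (ties broken by event order, so the gate is deterministic).
#'
#' @param sample an [event_sample()] with `fsc` and `ssc` present.
#' @param fraction fraction of events to retain.
#' @param bins grid resolution per axis.
#' @param sigma Gaussian smoothing bandwidth, in bins.
#' @param cofactor asinh cofactor for the scatter transform.
#' @return The gated `event_sample`; retains exactly
#'   `round(fraction * n_events)` events, carries a `gate` attribute with the
#'   gate settings, and a `retained` attribute with the original event indices.
#' @export
density_gate <- function(sample, fraction = 0.5, bins = 1024, sigma = 10,
                         cofactor = 150) {
  stopifnot(inherits(sample, "event_sample"))
  if (is.null(sample$fsc)) stop("density_gate requires the 'fsc' channel")
  if (is.null(sample$ssc)) stop("density_gate requires the 'ssc' channel")
  stopifnot(fraction > 0, fraction <= 1)
  n <- sample$n_events
  k <- round(fraction * n)
  if (fraction == 1 || k >= n) return(sample)

  tx <- asinh(sample$fsc / cofactor)
  ty <- asinh(sample$ssc / cofactor)
  ex <- seq(min(tx), max(tx), length.out = bins + 1)
  ey <- seq(min(ty), max(ty), length.out = bins + 1)
  ix <- pmin(pmax(findInterval(tx, ex, all.inside = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(ty, ey, all.inside = TRUE), 1L), bins)

  H <- matrix(tabulate((iy - 1L) * bins + ix, nbins = bins * bins), bins, bins)
  sm <- gaussian_smooth_2d(H, sigma)

  dens <- sm[cbind(ix, iy)]
  ord <- order(dens, seq_len(n), decreasing = c(TRUE, FALSE), method = "radix")
  retained <- sort(ord[seq_len(k)])

  out <- event_sample(sample$yfp[retained],
                      fsc = sample$fsc[retained],
                      ssc = sample$ssc[retained],
                      condition = sample$condition)
  attr(out, "gate") <- list(type = "density2d", fraction = fraction,
                            bins = bins, sigma = sigma, cofactor = cofactor)
  attr(out, "retained") <- retained
  out
}

# separable zero-padded Gaussian blur; stats::filter runs columnwise in C
gaussian_smooth_2d <- function(H, sigma) {
  if (sigma <= 0) return(H)
  half <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-half:half)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  blur_cols <- function(M) {
    pad <- matrix(0, half, ncol(M))
    out <- stats::filter(rbind(pad, M, pad), kern, sides = 2)
    matrix(out[(half + 1):(half + nrow(M)), ], nrow(M), ncol(M))
  }
  t(blur_cols(t(blur_cols(H))))
}

#' Autofluorescence-corrected sample median
#'
#' Subtracts the mean of the autofluorescence-control replicate medians from
#' the sample median. A non-positive result is clamped to `floor` and flagged
#' via the `"clamped"` attribute.
#'
#' @param sample an [event_sample()], or a precomputed numeric median.
#' @param control_medians medians of the gated autofluorescence-control
#'   replicates (typically 3).
#' @param floor clamp value for non-positive corrected medians (a.u.).
#' @return corrected median (a.u.) with logical attribute `clamped`.
#' @export
autofluorescence_correct <- function(sample, control_medians, floor = 0.01) {
  if (length(control_medians) < 1L || any(!is.finite(control_medians))) {
    stop("control_medians must be a non-empty finite vector")
  }
  med <- if (inherits(sample, "event_sample")) median(sample$yfp) else as.numeric(sample)
  corrected <- med - mean(control_medians)
  clamped <- corrected <= 0
  if (clamped) corrected <- floor
  structure(corrected, clamped = clamped)
}

#' Convert a corrected median to relative promoter units (RPU)
#'
#' @param corrected_median autofluorescence-corrected sample median (a.u.).
#' @param rpu_standard_median corrected median of the RPU standard strain
#'   (a.u., must be positive).
#' @return activity in RPU.
#' @export
to_rpu <- function(corrected_median, rpu_standard_median) {
  if (!is.numeric(rpu_standard_median) || rpu_standard_median <= 0) {
    stop("rpu_standard_median must be positive")
  }
  as.numeric(corrected_median) / rpu_standard_median
}

#' Summary statistics of an event sample
#'
#' @param sample an [event_sample()].
#' @return list with `median` (interpolated), `robust_cv`
#'   (IQR / 1.349 / median — a Gaussian-consistent robust CV) and `n_events`.
#' @export
sample_summary <- function(sample) {
  stopifnot(inherits(sample, "event_sample"))
  med <- median(sample$yfp)
  iqr <- IQR(sample$yfp, type = 7)
  list(median = med,
       robust_cv = if (med != 0) (iqr / (2 * qnorm(0.75))) / med else NA_real_,
       n_events = sample$n_events)
}
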