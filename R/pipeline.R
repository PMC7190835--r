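#' Run the full characterization pipeline on a synthetic dataset
#'
#' Gate -> autofluorescence-correct -> RPU-normalize -> Hill fit -> device
#' metrics, mirroring how measured flow-cytometry data are processed:
#'
#' 1. every sample (conditions and controls) is density-gated on its scatter
#'    channels;
#' 2. the mean of the gated autofluorescence-control medians is subtracted
#'    from every gated sample median;
#' 3. the corrected RPU-standard median converts corrected medians to RPU;
#' 4. per tuner level, a Hill function (activation for the TES, repression for
#'    NOT gates) is fitted jointly to the replicate medians;
#' 5. dynamic range, fold change and distribution intersection are computed
#'    between the on and off input states, per replicate.
#'
#' @param dataset a `synthetic_dataset` (or any list with the same shape).
#' @param gate_fraction fraction of events retained by the density gate.
#' @param gate_bins,gate_sigma density-gate grid resolution and smoothing
#'   (use 1024/10 for full-resolution gating; smaller grids give near-identical
#'   gates at a fraction of the cost and scale `sigma` proportionally).
#' @param on_state,off_state input activities (RPU) defining the on and off
#'   states for the metrics; default to the extremes of the input grid.
#' @param n_bins histogram bins for the intersection metric.
#' @return A `tes_analysis`: `medians` (tidy table of corrected medians and
#'   RPU), `fits` (per tuner level), `metrics` (per tuner level),
#'   `k_range`, `control_medians`, `rpu_standard_au`.
#' @export
analyze_dataset <- function(dataset, gate_fraction = 0.5, gate_bins = 1024,
                            gate_sigma = gate_bins * 10 / 1024,
                            on_state = NULL, off_state = NULL, n_bins = 256) {
  spec <- dataset$spec
  gate1 <- function(s) density_gate(s, fraction = gate_fraction,
                                    bins = gate_bins, sigma = gate_sigma)
  auto_g <- lapply(dataset$controls$autofluorescence, gate1)
  std_g <- lapply(dataset$controls$rpu_standard, gate1)
  control_medians <- vapply(auto_g, function(s) median(s$yfp), numeric(1))
  std_corr <- vapply(std_g, function(s)
    as.numeric(autofluorescence_correct(s, control_medians)), numeric(1))
  std_au <- mean(std_corr)

  gated <- lapply(dataset$samples, gate1)
  meta <- lapply(gated, `[[`, "condition")
  med_corr <- vapply(gated, function(s)
    as.numeric(autofluorescence_correct(s, control_medians)), numeric(1))

  medians <- data.frame(
    design = vapply(meta, function(m) as.character(m$design), character(1)),
    replicate = vapply(meta, function(m) as.integer(m$replicate), integer(1)),
    input_activity_rpu = vapply(meta, function(m) as.numeric(m$input_activity), numeric(1)),
    tuner_activity_rpu = vapply(meta, function(m) as.numeric(m$tuner_activity), numeric(1)),
    median_yfp_au = unname(med_corr),
    row.names = NULL)
  medians$output_rpu <- to_rpu(medians$median_yfp_au, std_au)
  if (spec$device == "NOR") {
    medians$input_b_activity_rpu <-
      vapply(meta, function(m) as.numeric(m$input_b_activity), numeric(1))
    return(structure(list(medians = medians, fits = NULL, metrics = NULL,
                          k_range = NULL, control_medians = control_medians,
                          rpu_standard_au = std_au, device = spec$device),
                     class = "tes_analysis"))
  }

  fits <- lapply(sort(unique(medians$tuner_activity_rpu)), function(t) {
    rows <- medians[medians$tuner_activity_rpu == t, ]
    curve <- response_curve(rows$input_activity_rpu, rows$median_yfp_au,
                            tuner_activity = t, design = spec$design)
    if (spec$device == "TES") fit_hill_activation(curve) else fit_hill_repression(curve)
  })
  names(fits) <- sort(unique(medians$tuner_activity_rpu))

  if (is.null(on_state)) {
    on_state <- max(medians$input_activity_rpu)
  }
  if (is.null(off_state)) off_state <- min(medians$input_activity_rpu)
  sel_events <- function(t, state) {
    idx <- which(
      vapply(meta, function(m) {
        isTRUE(all.equal(as.numeric(m$tuner_activity), t)) &&
          isTRUE(all.equal(as.numeric(m$input_activity), state))
      }, logical(1)))
    idx <- idx[order(vapply(meta[idx], function(m) as.integer(m$replicate), integer(1)))]
    gated[idx]
  }
  metrics <- lapply(sort(unique(medians$tuner_activity_rpu)), function(t) {
    rows <- medians[medians$tuner_activity_rpu == t,
                    c("input_activity_rpu", "replicate", "median_yfp_au")]
    names(rows) <- c("input_activity", "replicate", "median")
    device_metrics(rows, on_state = on_state, off_state = off_state,
                   on_events = sel_events(t, on_state),
                   off_events = sel_events(t, off_state), n_bins = n_bins)
  })
  names(metrics) <- names(fits)

  kr <- tryCatch(k_range(fits), error = function(e) NULL)
  structure(list(medians = medians, fits = fits, metrics = metrics,
                 k_range = kr, control_medians = control_medians,
                 rpu_standard_au = std_au, device = spec$device),
            class = "tes_analysis")
}

#' @export
print.tes_analysis <- function(x, ...) {
  cat(sprintf("%s characterization: %d medians, %d tuner levels\n",
              x$device, nrow(x$medians),
              length(unique(x$medians$tuner_activity_rpu))))
  if (!is.null(x$k_range)) {
    cat(sprintf("  K range: %.3g-%.3g RPU (ratio %.2f)\n",
                x$k_range$K_min, x$k_range$K_max, x$k_range$ratio))
  }
  invisible(x)
}

#' Table-1-style metric summary of an analysis
#'
#' One row per tuner level with dynamic range, fold change and intersection as
#' mean +/- SD over replicates.
#'
#' @param analysis a `tes_analysis` from [analyze_dataset()].
#' @return data.frame.
#' @export
metrics_table <- function(analysis) {
  stopifnot(inherits(analysis, "tes_analysis"))
  if (is.null(analysis$metrics)) stop("analysis has no per-tuner metrics")
  do.call(rbind, lapply(names(analysis$metrics), function(t) {
    m <- analysis$metrics[[t]]
    data.frame(tuner_activity_rpu = as.numeric(t),
               dynamic_range = m$dynamic_range[1],
               dynamic_range_sd = m$dynamic_range[2],
               fold_change = m$fold_change[1],
               fold_change_sd = m$fold_change[2],
               intersection = if (!is.null(m$intersection)) m$intersection[1] else NA_real_,
               intersection_sd = if (!is.null(m$intersection)) m$intersection[2] else NA_real_,
               row.names = NULL)
  }))
}
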