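#' Convert a synthetic dataset to a long-format event table
#'
#' Long-format CSV is the canonical interchange for event-level data: one row
#' per event, with condition metadata repeated.
#'
#' @param dataset a `synthetic_dataset`.
#' @param include_controls include the autofluorescence and RPU-standard
#'   samples (design labels `autofluorescence` / `rpu_standard`).
#' @return data.frame with columns `design, replicate, input_activity_rpu,
#'   tuner_activity_rpu, yfp_au, fsc, ssc`.
#' @export
events_table <- function(dataset, include_controls = TRUE) {
  one <- function(s) {
    m <- s$condition
    data.frame(
      design = as.character(m$design %||% NA),
      replicate = as.integer(m$replicate %||% NA),
      input_activity_rpu = as.numeric(m$input_activity %||% NA),
      tuner_activity_rpu = as.numeric(m$tuner_activity %||% NA),
      yfp_au = s$yfp,
      fsc = if (is.null(s$fsc)) NA_real_ else s$fsc,
      ssc = if (is.null(s$ssc)) NA_real_ else s$ssc)
  }
  samples <- dataset$samples
  if (include_controls) {
    samples <- c(samples, dataset$controls$autofluorescence,
                 dataset$controls$rpu_standard)
  }
  do.call(rbind, lapply(samples, one))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

event_schema <- c("design", "replicate", "input_activity_rpu",
                  "tuner_activity_rpu", "yfp_au")

#' Read or write long-format event tables
#'
#' Strict schema validation: missing required columns are named in the error.
#' CSV round trips are lossless for the numeric payload.
#'
#' @param path CSV file path.
#' @param table data.frame to write.
#' @param required required column names.
#' @return `read_events_csv` returns the validated data.frame.
#' @export
read_events_csv <- function(path, required = event_schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("event table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  tab
}

#' @rdname read_events_csv
#' @export
write_events_csv <- function(table, path) {
  stopifnot(is.data.frame(table))
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Rebuild event samples from a long-format table
#'
#' Inverse of [events_table()]: groups rows by condition and returns a list of
#' [event_sample()]s plus control lists, sufficient input for
#' [analyze_dataset()].
#'
#' @param tab a validated event table (see [read_events_csv()]).
#' @param spec optional [synthetic_dataset_spec()] to attach.
#' @return a list shaped like a `synthetic_dataset` (without a manifest).
#' @export
table_to_samples <- function(tab, spec = NULL) {
  missing <- setdiff(event_schema, names(tab))
  if (length(missing)) {
    stop("event table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  key <- paste(tab$design, tab$replicate, tab$input_activity_rpu,
               tab$tuner_activity_rpu, sep = "|")
  groups <- split(seq_len(nrow(tab)), key)
  mk <- function(idx) {
    r1 <- tab[idx[1], ]
    event_sample(tab$yfp_au[idx],
                 fsc = if (all(is.finite(tab$fsc[idx]))) tab$fsc[idx],
                 ssc = if (all(is.finite(tab$ssc[idx]))) tab$ssc[idx],
                 condition = list(design = r1$design, replicate = r1$replicate,
                                  input_activity = r1$input_activity_rpu,
                                  tuner_activity = r1$tuner_activity_rpu))
  }
  samples <- lapply(groups, mk)
  is_auto <- vapply(samples, function(s) identical(s$condition$design, "autofluorescence"), logical(1))
  is_std <- vapply(samples, function(s) identical(s$condition$design, "rpu_standard"), logical(1))
  list(samples = samples[!is_auto & !is_std],
       controls = list(autofluorescence = unname(samples[is_auto]),
                       rpu_standard = unname(samples[is_std])),
       spec = spec)
}

#' Read a run configuration (YAML or JSON)
#'
#' Unknown top-level keys are rejected. The resolved configuration (defaults
#' filled in) is what [run_command()] writes next to its outputs.
#'
#' @param path YAML/JSON config file.
#' @return a named list with class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a named list of configuration values.
#' @export
as_run_config <- function(cfg) {
  known <- c("command", "seed", "out_dir", "unit_system", "rpu_to_rnap",
             "model", "simulate", "fit", "synth", "analyze", "intersect",
             "respond")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg$seed <- cfg$seed %||% 1
  cfg$out_dir <- cfg$out_dir %||% "."
  cfg$unit_system <- cfg$unit_system %||% "RPU"
  cfg$rpu_to_rnap <- cfg$rpu_to_rnap %||% 79
  structure(cfg, class = "run_config")
}

params_from_config <- function(block) {
  if (is.null(block)) return(tes_parameters())
  known <- names(formals(tes_parameters))
  unknown <- setdiff(names(block), known)
  if (length(unknown)) {
    stop("unknown model parameter(s): ", paste(unknown, collapse = ", "))
  }
  do.call(tes_parameters, block)
}

#' Execute a configured run
#'
#' Dispatches on `config$command`:
#' * `simulate` — ODE (default), DDE, SSA or tau-leap time course to
#'   `trajectory.csv`;
#' * `respond` — steady-state response surface to `response_surface.csv`;
#' * `synth` — synthetic dataset to `events.csv` plus `manifest.json`;
#' * `analyze` — pipeline on an event CSV to `medians.csv` and `metrics.csv`;
#' * `intersect` — intersection fraction between two event CSVs to
#'   `intersection.json`.
#'
#' Every run writes `resolved_config.json` (the fully resolved configuration,
#' including the seed) next to its outputs, so any artifact can be reproduced.
#'
#' @param config a `run_config` (see [read_run_config()]).
#' @return invisible named vector of output paths.
#' @export
run_command <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cmd <- config$command
  if (is.null(cmd) || !cmd %in% c("simulate", "respond", "synth", "analyze", "intersect")) {
    stop("config$command must be one of simulate/respond/synth/analyze/intersect")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outs <- c()
  if (cmd == "simulate") {
    blk <- config$simulate %||% list()
    params <- params_from_config(config$model)
    method <- blk$method %||% "ode"
    duration <- blk$duration %||% 100
    n_points <- blk$n_points %||% 100
    initial <- blk$initial %||% c(0, 0, 0, 0)
    traj <- switch(method,
      ode = simulate_ode_timecourse(params, initial, duration, n_points),
      dde = simulate_dde_timecourse(params,
              delays = unlist(blk$delays %||% c(transcription = 0, translation = 0)),
              initial = initial, duration = duration, n_points = n_points),
      ssa = ,
      tauleap = {
        net <- build_tes_network(params)
        tr <- if (method == "ssa") {
          simulate_ssa(net, initial, duration, n_points, seed = config$seed)
        } else {
          simulate_tauleap(net, initial, duration, n_points,
                           epsilon = blk$epsilon %||% 0.03, seed = config$seed)
        }
        cbind(data.frame(time = tr$times), as.data.frame(tr$states))
      },
      stop("unknown simulate method: ", method))
    p <- file.path(config$out_dir, "trajectory.csv")
    write.csv(as.data.frame(traj), p, row.names = FALSE)
    outs["trajectory"] <- p
  } else if (cmd == "respond") {
    blk <- config$respond %||% list()
    params <- params_from_config(config$model)
    surf <- response_surface(params,
                             input_grid = unlist(blk$input_grid %||%
                               c(1e-4, 0.06, 0.3, 1.5, 7.6, 38, 190)),
                             tuner_grid = unlist(blk$tuner_grid %||%
                               c(1e-4, 0.06, 0.3, 1.5, 7.6, 38, 190)),
                             output = blk$output %||% "protein")
    surf$design <- blk$design %||% "TES"
    p <- file.path(config$out_dir, "response_surface.csv")
    write.csv(surf, p, row.names = FALSE)
    outs["response_surface"] <- p
  } else if (cmd == "synth") {
    blk <- config$synth %||% list()
    blk$seed <- blk$seed %||% config$seed
    spec <- do.call(synthetic_dataset_spec, blk)
    ds <- generate_device_dataset(spec)
    pe <- file.path(config$out_dir, "events.csv")
    write_events_csv(events_table(ds), pe)
    pm <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(ds$manifest, pm, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    outs[c("events", "manifest")] <- c(pe, pm)
  } else if (cmd == "analyze") {
    blk <- config$analyze %||% list()
    if (is.null(blk$events)) stop("analyze requires analyze$events (CSV path)")
    tab <- read_events_csv(blk$events)
    ds <- table_to_samples(tab)
    ds$spec <- list(device = blk$device %||% "TES")
    an <- analyze_dataset(ds,
                          gate_fraction = blk$gate_fraction %||% 0.5,
                          gate_bins = blk$gate_bins %||% 1024)
    pm <- file.path(config$out_dir, "medians.csv")
    write.csv(an$medians, pm, row.names = FALSE)
    outs["medians"] <- pm
    if (!is.null(an$metrics)) {
      pt <- file.path(config$out_dir, "metrics.csv")
      write.csv(metrics_table(an), pt, row.names = FALSE)
      outs["metrics"] <- pt
    }
  } else if (cmd == "intersect") {
    blk <- config$intersect %||% list()
    if (is.null(blk$x) || is.null(blk$y)) {
      stop("intersect requires intersect$x and intersect$y (CSV paths)")
    }
    xs <- read_events_csv(blk$x, required = "yfp_au")
    ys <- read_events_csv(blk$y, required = "yfp_au")
    pair <- histogram_pair(xs$yfp_au, ys$yfp_au,
                           n_bins = blk$n_bins %||% 256)
    H <- intersection_fraction(pair)
    p <- file.path(config$out_dir, "intersection.json")
    jsonlite::write_json(list(intersection = H), p, auto_unbox = TRUE, digits = NA)
    outs["intersection"] <- p
  }
  pc <- file.path(config$out_dir, "resolved_config.json")
  jsonlite::write_json(unclass(config), pc, auto_unbox = TRUE, digits = NA)
  outs["resolved_config"] <- pc
  invisible(outs)
}
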