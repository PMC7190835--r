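#' Kinetic parameters of the tunable expression system (TES)
#'
#' Bundles every rate constant of the two-promoter TES motif: an input promoter
#' transcribes a toehold-switch (THS) mRNA `m`, a tuner promoter transcribes a
#' small RNA `s` complementary to the THS toehold, the two hybridize into a
#' translationally active complex `c`, and protein `p` is produced from both the
#' closed mRNA (leak) and the opened complex.
#'
#' Default rates are nominal values for exponentially growing *E. coli*:
#' an mRNA half-life of about 2 min, a more stable tuner sRNA (half-life
#' ~7 min), a stable reporter protein removed only by dilution at a 30-min
#' doubling time, a fast toehold-mediated hybridization rate of
#' 0.2 molecule^-1 min^-1 (about 6e6 M^-1 s^-1 in a ~1 fL cell, so that sRNA
#' fate is binding-dominated at RNAP-flux scales of a few per minute), and a
#' 100-fold span between leak and activated translation initiation.
#'
#' @param u_in input-promoter transcription rate (RNAP/min, i.e. transcripts
#'   per minute per cell).
#' @param u_tun tuner-promoter transcription rate (RNAP/min).
#' @param k_on THS-mRNA/sRNA hybridization rate (molecule^-1 min^-1).
#' @param k_off complex dissociation rate (min^-1). Defaults to 0: branch
#'   migration is treated as irreversible.
#' @param k_leak translation rate from the free, closed THS mRNA
#'   (protein mRNA^-1 min^-1).
#' @param k_act translation rate from the sRNA-opened complex
#'   (protein complex^-1 min^-1). Must be at least `k_leak`.
#' @param delta_m,delta_s,delta_c,delta_p degradation rates of mRNA, sRNA,
#'   complex and protein (min^-1). The complex default follows `delta_m`
#'   (degrades as a unit at the mRNA rate).
#' @param phi dilution rate from cell growth (min^-1).
#' @param booster_factor multiplier on `u_tun` representing the high-copy
#'   sRNA booster plasmid (dimensionless, >= 1; the booster design uses 5).
#' @return An object of class `tes_parameters` (a validated named list).
#' @examples
#' p <- tes_parameters(u_in = 1.5, u_tun = 38)
#' steady_state(p)$p
#' @export
tes_parameters <- function(u_in = 1.5,
                           u_tun = 38,
                           k_on = 0.2,
                           k_off = 0,
                           k_leak = 0.02,
                           k_act = 2,
                           delta_m = 0.3466,
                           delta_s = 0.1,
                           delta_c = delta_m,
                           delta_p = 0,
                           phi = 0.0231,
                           booster_factor = 1) {
  p <- list(u_in = u_in, u_tun = u_tun, k_on = k_on, k_off = k_off,
            k_leak = k_leak, k_act = k_act,
            delta_m = delta_m, delta_s = delta_s, delta_c = delta_c,
            delta_p = delta_p, phi = phi, booster_factor = booster_factor)
  validate_tes_parameters(p)
  structure(p, class = "tes_parameters")
}

validate_tes_parameters <- function(p) {
  for (f in names(p)) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("field '", f, "' must be a single finite number", call. = FALSE)
    }
    if (v < 0) stop("field '", f, "' must be non-negative", call. = FALSE)
  }
  if (p$delta_m + p$phi <= 0) stop("delta_m + phi must be > 0", call. = FALSE)
  if (p$delta_s + p$phi <= 0) stop("delta_s + phi must be > 0", call. = FALSE)
  if (p$delta_p + p$phi <= 0) stop("delta_p + phi must be > 0", call. = FALSE)
  if (p$k_act < p$k_leak) {
    stop("k_act must be >= k_leak (the opened switch translates at least as fast as the closed one)",
         call. = FALSE)
  }
  if (p$booster_factor < 1) stop("booster_factor must be >= 1", call. = FALSE)
  invisible(p)
}

#' Modify a TES parameter set
#'
#' Returns a copy of `params` with the named fields replaced, re-validated.
#'
#' @param params a [tes_parameters()] object.
#' @param ... fields to replace, e.g. `u_in = 0.5`.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "tes_parameters"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(params))
  if (length(bad)) stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
  params[names(repl)] <- repl
  validate_tes_parameters(params)
  structure(params, class = "tes_parameters")
}

#' @export
print.tes_parameters <- function(x, ...) {
  cat("TES kinetic parameters (per-minute units)\n")
  print(unlist(x))
  invisible(x)
}

#' Parameters of the repressor stage of a NOT/NOR gate
#'
#' The TES protein output is a repressor (e.g. PhlF) binding the output
#' promoter; the output promoter activity follows a repression Hill function of
#' the repressor copy number.
#'
#' @param p_out_max maximal output-promoter activity (RPU or RNAP/min).
#' @param p_out_min fully repressed output-promoter activity (same units).
#' @param K_R repressor copies at half repression (molecules).
#' @param n_R repression Hill coefficient (dimensionless).
#' @param kappa_rt transcriptional read-through rate added to the repressor
#'   mRNA transcription when the upstream tuner unit is active (RNAP/min).
#'   Default 0; a positive value models read-through from the tuner unit
#'   elevating repressor expression.
#' @return An object of class `gate_parameters`.
#' @export
gate_parameters <- function(p_out_max = 10,
                            p_out_min = 0.05,
                            K_R = 150,
                            n_R = 2,
                            kappa_rt = 0) {
  g <- list(p_out_max = p_out_max, p_out_min = p_out_min,
            K_R = K_R, n_R = n_R, kappa_rt = kappa_rt)
  for (f in names(g)) {
    v <- g[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("field '", f, "' must be a single finite number", call. = FALSE)
    }
  }
  if (g$p_out_min < 0) stop("p_out_min must be >= 0", call. = FALSE)
  if (g$p_out_max <= g$p_out_min) stop("p_out_max must be > p_out_min", call. = FALSE)
  if (g$K_R <= 0) stop("K_R must be > 0", call. = FALSE)
  if (g$n_R <= 0) stop("n_R must be > 0", call. = FALSE)
  if (g$kappa_rt < 0) stop("kappa_rt must be >= 0", call. = FALSE)
  structure(g, class = "gate_parameters")
}

#' Host ribosome-pool parameters for the resource-coupled model
#'
#' Lumped description of the shared translational resource: a total ribosome
#' pool, an aggregate demand from endogenous genes, and the half-saturation of
#' translation with respect to free ribosomes.
#'
#' @param R_total total ribosome pool (molecules).
#' @param host_demand lumped ribosome demand of endogenous genes (molecules,
#'   same effective units as the construct's translational flux).
#' @param K_rib free-ribosome half-saturation of translation (molecules).
#' @return An object of class `host_parameters`.
#' @export
host_parameters <- function(R_total = 15000,
                            host_demand = 10000,
                            K_rib = 1000) {
  h <- list(R_total = R_total, host_demand = host_demand, K_rib = K_rib)
  for (f in names(h)) {
    v <- h[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("field '", f, "' must be a single finite non-negative number", call. = FALSE)
    }
  }
  if (h$R_total <= 0) stop("R_total must be > 0", call. = FALSE)
  if (h$K_rib <= 0) stop("K_rib must be > 0", call. = FALSE)
  structure(h, class = "host_parameters")
}

#' Convert relative promoter units (RPU) to RNAP flux
#'
#' The mechanistic model works in RNAP/min while experimental characterization
#' works in RPU. The conversion factor is not a physical constant; the default
#' of 79 RNAP/min per RPU places the top of the experimental tuner range
#' (2.6 RPU) near the top of the model tuner grid (190 RNAP/min).
#'
#' @param rpu promoter activity in RPU.
#' @param rpu_to_rnap conversion factor (RNAP/min per RPU).
#' @return activity in RNAP/min.
#' @export
rpu_to_rnap_flux <- function(rpu, rpu_to_rnap = 79) {
  stopifnot(is.numeric(rpu), all(rpu >= 0), rpu_to_rnap > 0)
  rpu * rpu_to_rnap
}

#' @rdname rpu_to_rnap_flux
#' @param rnap activity in RNAP/min.
#' @export
rnap_flux_to_rpu <- function(rnap, rpu_to_rnap = 79) {
  stopifnot(is.numeric(rnap), all(rnap >= 0), rpu_to_rnap > 0)
  rnap / rpu_to_rnap
}
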