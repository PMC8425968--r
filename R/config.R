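#' Default model configuration
#'
#' One nested list holding every tunable parameter of the circuit model and
#' the trial protocol.  The defaults reproduce the wild-type condition; the
#' calibration endpoints are the bump observables (single stable bump,
#' wild-type FWHM near 1.86 rad, bump angular speed matching the body
#' rotation speed under unilateral PB drive).  See the package vignette for
#' the calibration rationale.
#'
#' @param ... Named overrides merged over the defaults (top level only).
#' @return A nested list of class \code{ringmem_config}.
#' @export
ringmem_config <- function(...) {
  cfg <- list(
    lif = lif_params(),
    kinetics = synapse_kinetics(),
    # maximum conductance per unit synaptic weight, nS; gaba applies to the
    # EIP-ring global inhibition, gaba_gate to the C-ring/P-ring gating
    # projections
    gains = list(nmda = 1.6, gaba = 3.0, gaba_c_gate = 1.0,
                 gaba_p_gate = 0.55, gaba_ring_self = 3.0,
                 nmda_ring = 1.6, nmda_pen = 2.8),
    # independent Poisson background to every EIP/PEI/PEN unit
    background = list(rate_hz = 900, g_inc_ns = 0.05),
    # landmark input to matching PB glomeruli (stimulus stage)
    visual = list(rate_hz = 1200, g_inc_ns = 0.6),
    # unilateral PB input during body rotation
    rotation = list(rate_hz = 3200, g_inc_ns = 0.131),
    # protocol gating drive to C-ring / P-ring pools; during rotation the
    # P-ring keeps a partial drive so the shifter circuit is only partially
    # disinhibited (full disinhibition diffuses the bump)
    ring_gate_current_na = 0.3,
    ring_gate_partial_na = 0.145,
    # tonic depolarization of the always-active EIP-ring pool; the
    # suppression / photoactivation currents act against this baseline
    ring_eip_tonic_na = 0.175,
    # condition-specific currents
    currents = list(eip_ring_suppression_na = -0.04,
                    p_ring_suppression_na = -0.25,
                    photoactivation_na = 0.2),
    integration = list(dt_ms = 0.1, rate_bin_ms = 100),
    markov = markov_params())
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  class(cfg) <- c("ringmem_config", "list")
  cfg
}

#' Write a configuration to structured text (JSON)
#' @param config A \code{ringmem_config}.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a configuration written by \code{\link{write_config}}
#' @param path Input path.
#' @return A \code{ringmem_config}.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- ringmem_config()
  plain <- setdiff(names(raw), c("lif", "kinetics", "markov"))
  for (nm in intersect(plain, names(cfg))) cfg[[nm]] <- raw[[nm]]
  if (!is.null(raw$lif))
    cfg$lif <- do.call(lif_params, raw$lif[names(formals(lif_params))])
  if (!is.null(raw$markov))
    cfg$markov <- markov_params(raw$markov$p_fr, raw$markov$p_rf,
                                raw$markov$step_ms,
                                raw$markov$rotation_speed_deg_s,
                                raw$markov$forward_speed_mm_s)
  if (!is.null(raw$kinetics)) {
    k <- raw$kinetics
    cfg$kinetics <- synapse_kinetics(
      nmda_tau_ms = k$tau_ms[k$receptor == "nmda"],
      nmda_erev_mv = k$erev_mv[k$receptor == "nmda"],
      gaba_tau_ms = k$tau_ms[k$receptor == "gaba"],
      gaba_erev_mv = k$erev_mv[k$receptor == "gaba"],
      ext_tau_ms = k$tau_ms[k$receptor == "ext"],
      ext_erev_mv = k$erev_mv[k$receptor == "ext"],
      nmda_alpha = k$alpha[k$receptor == "nmda"],
      gaba_alpha = k$alpha[k$receptor == "gaba"])
  }
  cfg
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
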