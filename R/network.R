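#' Leaky integrate-and-fire neuron parameters
#'
#' Standard cortical-style defaults; the bump observables are calibrated via
#' synaptic gains and drive rates, not via these microparameters (see the
#' package vignette).
#'
#' @param tau_m_ms Membrane time constant (default 20 ms).
#' @param v_rest_mv Resting potential (default -70 mV).
#' @param v_thr_mv Spike threshold (default -50 mV).
#' @param v_reset_mv Post-spike reset (default -55 mV).
#' @param t_ref_ms Absolute refractory period (default 2 ms).
#' @param c_m_nf Membrane capacitance (default 0.1 nF, giving an input
#'   resistance of 200 Mohm and a rheobase of 0.1 nA).
#' @return An object of class \code{lif_params}.
#' @export
lif_params <- function(tau_m_ms = 20, v_rest_mv = -70, v_thr_mv = -50,
                       v_reset_mv = -55, t_ref_ms = 2, c_m_nf = 0.1) {
  if (v_thr_mv <= v_reset_mv) stopf("threshold must exceed reset")
  if (tau_m_ms <= 0 || t_ref_ms <= 0 || c_m_nf <= 0)
    stopf("time constants and capacitance must be > 0")
  structure(list(tau_m_ms = tau_m_ms, v_rest_mv = v_rest_mv,
                 v_thr_mv = v_thr_mv, v_reset_mv = v_reset_mv,
                 t_ref_ms = t_ref_ms, c_m_nf = c_m_nf),
            class = "lif_params")
}

#' Analytic firing rate of a LIF neuron under constant current
#'
#' Closed-form f-I curve used as an independent oracle for the integrator:
#' \eqn{f = 1 / (t_{ref} + \tau \ln\frac{IR - (V_{reset}-V_{rest})}
#' {IR - (V_{thr}-V_{rest})})}, zero below rheobase.
#'
#' @param i_na Injected current in nA.
#' @param lif A \code{\link{lif_params}}.
#' @return Firing rate in spikes/s.
#' @export
lif_rate_analytic <- function(i_na, lif = lif_params()) {
  R <- lif$tau_m_ms / lif$c_m_nf  # Mohm; I(nA) * R(Mohm) = mV
  drive <- i_na * R
  thr <- lif$v_thr_mv - lif$v_rest_mv
  res <- lif$v_reset_mv - lif$v_rest_mv
  ifelse(drive <= thr, 0,
         1000 / (lif$t_ref_ms +
                   lif$tau_m_ms * log((drive - res) / (drive - thr))))
}

#' Synaptic receptor kinetics
#'
#' Single-exponential conductance decay.  Excitatory interactions between
#' EIP, PEI, and PEN are NMDA-like and slow (stabilizing the bump); ring
#' neuron inhibition is GABAergic and fast; external spike drives use a fast
#' excitatory receptor.
#'
#' @param nmda_tau_ms,nmda_erev_mv NMDA decay and reversal (100 ms, 0 mV).
#' @param gaba_tau_ms,gaba_erev_mv GABA decay and reversal (10 ms, -85 mV;
#'   below rest so that ring-neuron inhibition is subtractive, which is what
#'   bounds the recurrent excitation of the attractor).
#' @param ext_tau_ms,ext_erev_mv External-input receptor (10 ms, 0 mV).
#' @param nmda_alpha,gaba_alpha Saturation increments of the per-synapse
#'   gating variable (\code{s += alpha * (1 - s)} per presynaptic spike); a
#'   synapse's conductance therefore saturates at its maximum weight.  The
#'   default 0.2 keeps synapses near-linear below ~100 spikes/s, which the
#'   shifter circuit needs to transmit rate asymmetries.  External drives
#'   are linear (no saturation).
#' @return An object of class \code{synapse_kinetics}: data.frame with rows
#'   \code{nmda}, \code{gaba}, \code{ext}.
#' @export
synapse_kinetics <- function(nmda_tau_ms = 100, nmda_erev_mv = 0,
                             gaba_tau_ms = 10, gaba_erev_mv = -85,
                             ext_tau_ms = 10, ext_erev_mv = 0,
                             nmda_alpha = 0.2, gaba_alpha = 0.2) {
  if (any(c(nmda_tau_ms, gaba_tau_ms, ext_tau_ms) <= 0))
    stopf("decay time constants must be > 0")
  if (nmda_erev_mv <= gaba_erev_mv)
    stopf("NMDA reversal must exceed GABA reversal")
  out <- data.frame(receptor = c("nmda", "gaba", "ext"),
                    tau_ms = c(nmda_tau_ms, gaba_tau_ms, ext_tau_ms),
                    erev_mv = c(nmda_erev_mv, gaba_erev_mv, ext_erev_mv),
                    alpha = c(nmda_alpha, gaba_alpha, 0))
  rownames(out) <- out$receptor
  class(out) <- c("synapse_kinetics", "data.frame")
  out
}

# the cells a valid weight table must contain (source, target, class)
.required_weight_cells <- data.frame(
  source = c("EIP", "EIP", "EIP",
             "PEI", "PEI", "PEI",
             "PEN", "PEN", "PEN",
             "RingEIP", "RingEIP", "RingPEI", "RingPEN"),
  target = c("PEI", "PEN", "RingEIP",
             "EIP", "EIP", "EIP",
             "EIP", "EIP", "EIP",
             "EIP", "RingEIP", "PEI", "PEN"),
  class = c("uniform", "uniform", "uniform",
            "central", "peripheral", "atypical",
            "central", "peripheral", "atypical",
            "uniform", "uniform", "uniform", "uniform"),
  stringsAsFactors = FALSE)

#' Synaptic weight table between neuron types
#'
#' Dimensionless weights between the six populations.  The defaults are the
#' published connectome-constrained values; projections from PB to EB carry
#' three weights for the central, peripheral, and atypical connection
#' classes.
#'
#' @param entries A data.frame with columns \code{source}, \code{target},
#'   \code{class} (one of \code{central}, \code{peripheral},
#'   \code{atypical}, \code{uniform}), \code{weight}.  Defaults to the
#'   published table.
#' @return An object of class \code{weight_table}.
#' @export
weight_table <- function(entries = NULL) {
  if (is.null(entries)) {
    entries <- .required_weight_cells
    entries$weight <- c(4.0, 4.0, 1.0,
                        8.0, 4.0, 4.0,
                        10.0, 5.0, 15.0,
                        3.0, 1.6, 10.0, 10.0)
  }
  key <- function(d) paste(d$source, d$target, d$class, sep = ":")
  missing <- setdiff(key(.required_weight_cells), key(entries))
  if (length(missing) > 0)
    stopf("weight table is missing cell(s): %s",
          paste(missing, collapse = ", "))
  if (any(entries$weight < 0)) stopf("weights must be >= 0")
  class(entries) <- c("weight_table", "data.frame")
  entries
}

wt_get <- function(wt, source, target, class) {
  i <- which(wt$source == source & wt$target == target & wt$class == class)
  if (length(i) != 1L)
    stopf("weight table cell %s:%s:%s not found", source, target, class)
  wt$weight[i]
}

#' EB-PB ring topology
#'
#' Index maps between 18 EB wedges and the 9 glomeruli of each PB side.
#' EIP units are indexed in PB order (even wedge \eqn{w} is EIP
#' \eqn{w/2}, odd wedge \eqn{w} is EIP \eqn{9 + (w-1)/2}), so each
#' glomerulus projects to an \emph{adjacent} wedge pair: left glomerulus
#' \eqn{j} targets central wedge \eqn{2j+3} and peripheral wedge
#' \eqn{2j+4}; right glomerulus \eqn{j} targets central \eqn{2j+2} and
#' peripheral \eqn{2j+1} (all mod 18).  In EIP indices this reproduces the
#' published examples: left glomerulus 0 projects centrally to EIP10 and
#' peripherally to EIP2.  The two glomeruli whose peripheral target wraps
#' the ring seam (left 7 at wedge 0, right 8 at wedge 17, i.e.
#' PEI7/PEI8 -> EIP0/EIP17) carry the atypical connection class instead:
#' for PEI the atypical weight replaces the peripheral one; for PEN the
#' atypical connection is the unit's only EB output, its larger weight
#' compensating the missing central+peripheral pair so total PEN drive per
#' wedge is uniform around the ring.  PEN units receive their EIP input
#' offset by one wedge (+1 on the left side, -1 on the right), so
#' unilateral PB drive shifts the bump clockwise (left) or
#' counterclockwise (right).
#'
#' @param n_wedges Number of EB wedges (18).
#' @param n_glomeruli Glomeruli per PB side (9).
#' @param ring_pool_size Units per ring-neuron population (8).
#' @param shift_offset Wedge offset of the PEN input map per side (1).
#' @param eip_arbor_halfwidth PEI dendritic arbor half-width in wedges: a
#'   PEI glomerulus receives EIP input from all wedges within this circular
#'   distance of its wedge identity.  This sets the width of the activity
#'   bump; 2 gives the published wild-type FWHM scale.
#' @param pen_arbor_halfwidth Arbor half-width of the PEN input map
#'   (default 0): the shifter needs an input footprint narrower than its
#'   output offset, otherwise unilateral drive produces no net motion.
#' @return An object of class \code{ebpb_topology}.
#' @export
ebpb_topology <- function(n_wedges = 18L, n_glomeruli = 9L,
                          ring_pool_size = 8L, shift_offset = 1L,
                          eip_arbor_halfwidth = 2L,
                          pen_arbor_halfwidth = 0L) {
  stopifnot(n_wedges == 2L * n_glomeruli)
  j <- 0:(n_glomeruli - 1L)
  mk_side <- function(side) {
    # left glomeruli carry odd central wedges with the peripheral one wedge
    # counterclockwise; right glomeruli the even centrals with the
    # peripheral clockwise.  The PEN input offset points away from each
    # side's output pair (no self-loops); at the calibrated operating point
    # unilateral left-PB drive rotates the bump clockwise and right-PB
    # drive counterclockwise.
    central <- if (side == "right") (2L * j + 3L) %% n_wedges
    else (2L * j + 2L) %% n_wedges
    peripheral <- if (side == "right") (2L * j + 4L) %% n_wedges
    else (2L * j + 1L) %% n_wedges
    # the glomerulus whose peripheral wedge wraps the seam carries the
    # atypical connection class (right j=7 -> wedge 0, left j=8 -> wedge 17)
    atypical <- if (side == "right") j == 7L else j == 8L
    data.frame(side = side, glomerulus = j,
               wedge = central,
               central_target = central,
               peripheral_target = ifelse(atypical, NA_integer_, peripheral),
               atypical_target = ifelse(atypical, peripheral, NA_integer_))
  }
  topo <- structure(list(n_wedges = n_wedges, n_glomeruli = n_glomeruli,
                         ring_pool_size = ring_pool_size,
                         shift_offset = shift_offset,
                         eip_arbor_halfwidth = as.integer(eip_arbor_halfwidth),
                         pen_arbor_halfwidth = as.integer(pen_arbor_halfwidth),
                         glomeruli = rbind(mk_side("left"),
                                           mk_side("right"))),
                    class = "ebpb_topology")
  validate_topology(topo)
  topo
}

#' EIP unit index of an EB wedge (PB ordering)
#'
#' Even wedge \eqn{w} maps to EIP \eqn{w/2}; odd wedge \eqn{w} to EIP
#' \eqn{9 + (w-1)/2}.  Under this ordering the published example
#' connections (PEI0 to EIP10 centrally and EIP2 peripherally) land on
#' adjacent wedges 3 and 4.
#'
#' @param wedge 0-based wedge index (vectorized).
#' @return 0-based EIP unit index.
#' @export
eip_index_of_wedge <- function(wedge) {
  ifelse(wedge %% 2L == 0L, wedge %/% 2L, 9L + (wedge - 1L) %/% 2L)
}

validate_topology <- function(topo) {
  g <- topo$glomeruli
  anchor <- function(cond, what) {
    if (!cond) stopf("topology anchor violated: %s", what)
  }
  idx <- eip_index_of_wedge
  g0 <- g[g$glomerulus == 0L, ]
  anchor(any(idx(g0$central_target) == 10L &
               idx(g0$peripheral_target) == 2L),
         "a glomerulus 0 must target EIP10 centrally and EIP2 peripherally")
  atyp <- g[!is.na(g$atypical_target), ]
  anchor(nrow(atyp) == 2L &&
           setequal(idx(atyp$atypical_target), c(0L, 17L)) &&
           setequal(atyp$glomerulus, c(7L, 8L)),
         "atypical connections must be glomeruli 7/8 -> EIP0/EIP17")
  anchor(all(is.na(atyp$peripheral_target)),
         "atypical units carry no separate peripheral target")
  typ <- g[is.na(g$atypical_target), ]
  anchor(all(!is.na(typ$central_target)) &&
           all(!is.na(typ$peripheral_target)),
         "every typical glomerulus needs one central and one peripheral target")
  for (s in c("left", "right")) {
    anchor(!anyDuplicated(g$central_target[g$side == s]),
           "central targets must tile each side")
    per <- c(g$peripheral_target[g$side == s],
             g$atypical_target[g$side == s])
    anchor(!anyDuplicated(per[!is.na(per)]),
           "peripheral/atypical targets must tile each side")
  }
  # adjacency: central and second target are neighboring wedges
  second <- ifelse(is.na(g$peripheral_target), g$atypical_target,
                   g$peripheral_target)
  d <- pmin((g$central_target - second) %% topo$n_wedges,
            (second - g$central_target) %% topo$n_wedges)
  anchor(all(d == 1L), "central and peripheral wedges must be adjacent")
  invisible(topo)
}

# population layout: global 0-based neuron ids
population_layout <- function(topo) {
  nw <- topo$n_wedges; ng <- topo$n_glomeruli; np <- topo$ring_pool_size
  pops <- data.frame(
    population = c("EIP", "PEI", "PEN", "RingEIP", "RingC", "RingP"),
    n = c(nw, 2L * ng, 2L * ng, np, np, np))
  pops$first <- cumsum(c(0L, pops$n[-nrow(pops)]))
  pops
}

#' Build the EB-PB spiking network
#'
#' Instantiates one spiking unit per labeled neuron index (EIP0..17, PEI and
#' PEN 0..8 per PB side) and small homogeneous pools for the three ring
#' populations, and realizes every weight-table cell as conductance synapses
#' according to the topology.
#'
#' @param weights A \code{\link{weight_table}}.
#' @param topology An \code{\link{ebpb_topology}}.
#' @param lif A \code{\link{lif_params}}.
#' @param kinetics A \code{\link{synapse_kinetics}}.
#' @param gains Named list of conductance gains in nS per unit weight:
#'   \code{nmda}, \code{gaba} (calibrated defaults from
#'   \code{\link{ringmem_config}}).
#' @param seed Default integration seed stored with the network.
#' @return An object of class \code{ebpb_network} with the neuron table,
#'   synapse arrays, parameters, and receptor table.
#' @export
build_network <- function(weights = weight_table(),
                          topology = ebpb_topology(),
                          lif = lif_params(),
                          kinetics = synapse_kinetics(),
                          gains = ringmem_config()$gains,
                          seed = 1L) {
  weights <- weight_table(weights)  # revalidate
  validate_topology(topology)
  pops <- population_layout(topology)
  id_of <- function(pop, idx) pops$first[pops$population == pop] + idx
  g <- topology$glomeruli
  nw <- topology$n_wedges
  # PEI/PEN unit ids: left block then right block, each 0..8
  pb_id <- function(pop, side, j)
    id_of(pop, ifelse(side == "left", j, topology$n_glomeruli + j))

  neurons <- data.frame(
    neuron_id = 0:(sum(pops$n) - 1L),
    population = rep(pops$population, pops$n),
    index = unlist(lapply(pops$n, function(n) 0:(n - 1L))),
    stringsAsFactors = FALSE)
  neurons$side <- NA_character_
  neurons$wedge <- NA_integer_
  neurons$wedge[neurons$population == "EIP"] <-
    neurons$index[neurons$population == "EIP"]
  for (p in c("PEI", "PEN")) {
    sel <- neurons$population == p
    neurons$side[sel] <- rep(c("left", "right"),
                             each = topology$n_glomeruli)
    neurons$wedge[sel] <- c(g$wedge[g$side == "left"],
                            g$wedge[g$side == "right"])
  }

  rec_id <- c(nmda = 0L, gaba = 1L, ext = 2L)
  syn <- list(pre = integer(0), post = integer(0), rec = integer(0),
              w = numeric(0), class = character(0), label = character(0))
  add_syn <- function(pre, post, receptor, w, class, label) {
    syn$pre <<- c(syn$pre, pre); syn$post <<- c(syn$post, post)
    syn$rec <<- c(syn$rec, rep(rec_id[[receptor]], length(pre)))
    syn$w <<- c(syn$w, rep_len(w, length(pre)))
    syn$class <<- c(syn$class, rep(class, length(pre)))
    syn$label <<- c(syn$label, rep(label, length(pre)))
  }

  w_eip_pei <- wt_get(weights, "EIP", "PEI", "uniform")
  w_eip_pen <- wt_get(weights, "EIP", "PEN", "uniform")
  w_eip_ring <- wt_get(weights, "EIP", "RingEIP", "uniform")
  w_pei <- c(central = wt_get(weights, "PEI", "EIP", "central"),
             peripheral = wt_get(weights, "PEI", "EIP", "peripheral"),
             atypical = wt_get(weights, "PEI", "EIP", "atypical"))
  w_pen <- c(central = wt_get(weights, "PEN", "EIP", "central"),
             peripheral = wt_get(weights, "PEN", "EIP", "peripheral"),
             atypical = wt_get(weights, "PEN", "EIP", "atypical"))
  w_ring_eip <- wt_get(weights, "RingEIP", "EIP", "uniform")
  w_ring_ring <- wt_get(weights, "RingEIP", "RingEIP", "uniform")
  w_cring <- wt_get(weights, "RingPEI", "PEI", "uniform")
  w_pring <- wt_get(weights, "RingPEN", "PEN", "uniform")

  off <- topology$shift_offset
  hw <- topology$eip_arbor_halfwidth
  arbor <- (-hw):hw
  eip_at <- function(wedges) id_of("EIP", wedges %% nw)
  for (r in seq_len(nrow(g))) {
    side <- g$side[r]; j <- g$glomerulus[r]
    is_atyp <- !is.na(g$atypical_target[r])
    pei <- pb_id("PEI", side, j); pen <- pb_id("PEN", side, j)
    # PEI: central everywhere, plus peripheral (typical) or the
    # seam-wrapping atypical connection (end units)
    pei_home <- g$central_target[r]
    add_syn(pei, eip_at(pei_home), "nmda", w_pei[["central"]], "central",
            "PEI->EIP")
    if (is_atyp) {
      add_syn(pei, eip_at(g$atypical_target[r]), "nmda",
              w_pei[["atypical"]], "atypical", "PEI->EIP")
    } else {
      add_syn(pei, eip_at(g$peripheral_target[r]), "nmda",
              w_pei[["peripheral"]], "peripheral", "PEI->EIP")
    }
    # PEN: central everywhere (each side must tile all wedges or the
    # shifting chain breaks at the seam), plus peripheral (typical) or the
    # seam-wrapping atypical connection (end units).  The atypical weight
    # leaves the two seam wedges with extra PEN drive; removing the end
    # units' central connection to even it out destabilizes the bump in
    # every rotation epoch, so the hotspot is kept and its effect (a mild
    # pull toward the seam while the shifter is engaged) is documented.
    pen_home <- g$central_target[r]
    add_syn(pen, eip_at(pen_home), "nmda", w_pen[["central"]], "central",
            "PEN->EIP")
    if (is_atyp) {
      add_syn(pen, eip_at(g$atypical_target[r]), "nmda",
              w_pen[["atypical"]], "atypical", "PEN->EIP")
    } else {
      add_syn(pen, eip_at(g$peripheral_target[r]), "nmda",
              w_pen[["peripheral"]], "peripheral", "PEN->EIP")
    }
    # EIP -> PB (forward), over the dendritic arbor around each unit's home
    # wedge; PEN input offset by +/- shift_offset so that unilateral drive
    # shifts the bump
    add_syn(eip_at(pei_home + arbor), rep(pei, length(arbor)), "nmda",
            w_eip_pei, "uniform", "EIP->PEI")
    pen_hw <- if (is.null(topology$pen_arbor_halfwidth)) 0L
    else topology$pen_arbor_halfwidth
    pen_arbor <- (-pen_hw):pen_hw
    pen_base <- if (side == "left") pen_home + off else pen_home - off
    add_syn(eip_at(pen_base + pen_arbor), rep(pen, length(pen_arbor)),
            "nmda", w_eip_pen, "uniform", "EIP->PEN")
  }
  eip_ids <- id_of("EIP", 0:(nw - 1L))
  ring_eip <- id_of("RingEIP", 0:(topology$ring_pool_size - 1L))
  ring_c <- id_of("RingC", 0:(topology$ring_pool_size - 1L))
  ring_p <- id_of("RingP", 0:(topology$ring_pool_size - 1L))
  for (e in eip_ids)
    add_syn(rep(e, length(ring_eip)), ring_eip, "nmda", w_eip_ring,
            "uniform", "EIP->RingEIP")
  for (rr in ring_eip) {
    add_syn(rep(rr, length(eip_ids)), eip_ids, "gaba", w_ring_eip,
            "uniform", "RingEIP->EIP")
    others <- setdiff(ring_eip, rr)
    add_syn(rep(rr, length(others)), others, "gaba", w_ring_ring,
            "uniform", "RingEIP->RingEIP")
  }
  pei_ids <- neurons$neuron_id[neurons$population == "PEI"]
  pen_ids <- neurons$neuron_id[neurons$population == "PEN"]
  for (rr in ring_c)
    add_syn(rep(rr, length(pei_ids)), pei_ids, "gaba", w_cring, "uniform",
            "RingC->PEI")
  for (rr in ring_p)
    add_syn(rep(rr, length(pen_ids)), pen_ids, "gaba", w_pring, "uniform",
            "RingP->PEN")

  gain_of <- c(`0` = gains$nmda, `1` = gains$gaba, `2` = 1)
  syn_g <- syn$w * gain_of[as.character(syn$rec)]
  # the two behavioral gating projections have their own inhibitory gains:
  # the C-ring must shut the strongly driven PEI down outright, while the
  # P-ring's partial gate must leave PEN modulable by EIP + rotation input
  gain_c <- if (is.null(gains$gaba_c_gate)) gains$gaba else gains$gaba_c_gate
  gain_p <- if (is.null(gains$gaba_p_gate)) gains$gaba else gains$gaba_p_gate
  is_c <- syn$label == "RingC->PEI"
  is_p <- syn$label == "RingP->PEN"
  syn_g[is_c] <- syn$w[is_c] * gain_c
  syn_g[is_p] <- syn$w[is_p] * gain_p
  # EIP-ring mutual inhibition has its own (weaker) gain: it must not
  # clamp the pool so hard that the photoactivation current cannot raise
  # the pool rate into the bump-abolishing range
  gain_s <- if (is.null(gains$gaba_ring_self)) gains$gaba
  else gains$gaba_ring_self
  is_s <- syn$label == "RingEIP->RingEIP"
  syn_g[is_s] <- syn$w[is_s] * gain_s
  # the EIP -> EIP-ring drive likewise: with the full NMDA gain the pool
  # rate is slaved to EIP activity and the tonic/photoactivation currents
  # lose control over the global inhibition level
  gain_r <- if (is.null(gains$nmda_ring)) gains$nmda else gains$nmda_ring
  is_r <- syn$label == "EIP->RingEIP"
  syn_g[is_r] <- syn$w[is_r] * gain_r
  # the shifter's input gain: EIP drive alone must lift near-bump PEN over
  # the partial P-ring gate (bump support through rotations in darkness),
  # while the photoactivated gate still overrides it
  gain_pen <- if (is.null(gains$nmda_pen)) gains$nmda else gains$nmda_pen
  is_pen <- syn$label == "EIP->PEN"
  syn_g[is_pen] <- syn$w[is_pen] * gain_pen
  structure(list(neurons = neurons, pops = pops,
                 synapses = data.frame(pre = syn$pre, post = syn$post,
                                       receptor = syn$rec, weight = syn$w,
                                       g_inc_ns = unname(syn_g),
                                       class = syn$class,
                                       label = syn$label),
                 topology = topology, weights = weights, lif = lif,
                 kinetics = kinetics, gains = gains, seed = seed),
            class = "ebpb_network")
}

#' @export
print.ebpb_network <- function(x, ...) {
  cat(sprintf("EB-PB network: %d neurons, %d synapses\n",
              nrow(x$neurons), nrow(x$synapses)))
  print(x$pops[, c("population", "n")], row.names = FALSE)
  invisible(x)
}

# neuron ids of a population (0-based)
pop_ids <- function(network, population,
                    side = NULL) {
  n <- network$neurons
  sel <- n$population == population
  if (!is.null(side)) sel <- sel & !is.na(n$side) & n$side == side
  n$neuron_id[sel]
}
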