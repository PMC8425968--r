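#' Create an empty drive schedule
#'
#' A drive schedule collects piecewise-constant Poisson spike drives and
#' constant-current drives that are applied during integration.
#'
#' @return An object of class \code{drive_schedule}.
#' @export
drive_schedule <- function() {
  structure(list(poisson = matrix(numeric(0), 0, 6,
                                  dimnames = list(NULL,
                                                  c("neuron", "receptor",
                                                    "t_on", "t_off", "rate_hz",
                                                    "g_inc_ns"))),
                 current = matrix(numeric(0), 0, 4,
                                  dimnames = list(NULL,
                                                  c("neuron", "t_on", "t_off",
                                                    "i_na")))),
            class = "drive_schedule")
}

#' Add an independent Poisson spike drive to a set of neurons
#'
#' @param schedule A \code{\link{drive_schedule}}.
#' @param neuron_ids 0-based neuron ids.
#' @param receptor Receptor name (\code{"nmda"}, \code{"gaba"},
#'   \code{"ext"}).
#' @param t_on_ms,t_off_ms Active window.
#' @param rate_hz Poisson rate per neuron (must be >= 0).
#' @param g_inc_ns Conductance increment per input spike.
#' @return The extended schedule.
#' @export
add_poisson_drive <- function(schedule, neuron_ids, receptor, t_on_ms,
                              t_off_ms, rate_hz, g_inc_ns) {
  if (rate_hz < 0) stopf("rate must be >= 0")
  if (!receptor %in% c("nmda", "gaba", "ext"))
    stopf("unknown receptor '%s'", receptor)
  rec <- c(nmda = 0, gaba = 1, ext = 2)[[receptor]]
  if (rate_hz == 0 || length(neuron_ids) == 0 || t_off_ms <= t_on_ms)
    return(schedule)
  schedule$poisson <- rbind(schedule$poisson,
                            cbind(neuron_ids, rec, t_on_ms, t_off_ms,
                                  rate_hz, g_inc_ns))
  schedule
}

#' Add a constant current drive to a set of neurons
#'
#' @inheritParams add_poisson_drive
#' @param i_na Current in nA (positive depolarizing).
#' @return The extended schedule.
#' @export
add_current_drive <- function(schedule, neuron_ids, t_on_ms, t_off_ms,
                              i_na) {
  if (i_na == 0 || length(neuron_ids) == 0 || t_off_ms <= t_on_ms)
    return(schedule)
  schedule$current <- rbind(schedule$current,
                            cbind(neuron_ids, t_on_ms, t_off_ms, i_na))
  schedule
}

ring_population_name <- function(population) {
  map <- c("EIP-ring" = "RingEIP", "C-ring" = "RingC", "P-ring" = "RingP",
           RingEIP = "RingEIP", RingC = "RingC", RingP = "RingP")
  if (!population %in% names(map))
    stopf("unknown ring population '%s'", population)
  map[[population]]
}

#' Apply a constant current to a ring-neuron population
#'
#' Negative currents model long-term suppression (hyperpolarization),
#' positive currents model optogenetic photoactivation.
#'
#' @param schedule A \code{\link{drive_schedule}}.
#' @param network An \code{ebpb_network}.
#' @param population \code{"EIP-ring"}, \code{"C-ring"}, or \code{"P-ring"}
#'   (aliases \code{RingEIP}/\code{RingC}/\code{RingP}).
#' @param current_na Constant current in nA.
#' @param window_ms \code{c(on, off)} in ms.
#' @return The extended schedule.
#' @export
apply_ring_modulation <- function(schedule, network, population, current_na,
                                  window_ms) {
  ids <- pop_ids(network, ring_population_name(population))
  add_current_drive(schedule, ids, window_ms[1L], window_ms[2L], current_na)
}

# the PEI units (both sides) whose output wedge best matches an azimuth;
# used to anchor the bump at the landmark direction.  The landmark stream
# targets the stabilizing pathway only: routing it through PEN would
# bypass the P-ring gate whenever the shifter is disinhibited.
visual_target_ids <- function(network, azimuth_deg) {
  w <- azimuth_wedge(azimuth_deg)
  g <- network$topology$glomeruli
  nw <- network$topology$n_wedges
  circ_d <- function(a, b) pmin((a - b) %% nw, (b - a) %% nw)
  ids <- integer(0)
  for (side in c("left", "right")) {
    gs <- g[g$side == side, ]
    j <- gs$glomerulus[which.min(circ_d(gs$wedge, w))]
    nn <- network$neurons
    pick <- nn$population == "PEI" & !is.na(nn$side) & nn$side == side &
      (nn$index %% network$topology$n_glomeruli) == j
    ids <- c(ids, nn$neuron_id[pick])
  }
  ids
}

#' Deliver landmark (visual) input
#'
#' Sends Poisson spike input to the PB glomeruli whose mapped EB wedge
#' matches the landmark azimuth, which ignites an activity bump at the cued
#' wedge.
#'
#' @param schedule A \code{\link{drive_schedule}}.
#' @param network An \code{ebpb_network}.
#' @param azimuth_deg Landmark azimuth in [0, 360).
#' @param rate_hz Poisson rate (>= 0).
#' @param window_ms \code{c(on, off)} in ms.
#' @param g_inc_ns Conductance increment per spike (default from
#'   \code{\link{ringmem_config}}).
#' @return The extended schedule.
#' @export
deliver_visual_input <- function(schedule, network, azimuth_deg, rate_hz,
                                 window_ms,
                                 g_inc_ns = ringmem_config()$visual$g_inc_ns) {
  if (rate_hz < 0) stopf("rate must be >= 0")
  ids <- visual_target_ids(network, azimuth_deg)
  add_poisson_drive(schedule, ids, "ext", window_ms[1L], window_ms[2L],
                    rate_hz, g_inc_ns)
}

#' Deliver unilateral PB (rotation feedback) input
#'
#' Poisson input to all PEN units of one PB side.  Left-side input shifts
#' the bump clockwise (decreasing azimuth), right-side input
#' counterclockwise.
#'
#' @inheritParams deliver_visual_input
#' @param side \code{"left"} or \code{"right"}.
#' @return The extended schedule.
#' @export
deliver_rotation_input <- function(schedule, network,
                                   side = c("left", "right"), rate_hz,
                                   window_ms,
                                   g_inc_ns = ringmem_config()$rotation$g_inc_ns) {
  side <- match.arg(side)
  ids <- pop_ids(network, "PEN", side = side)
  add_poisson_drive(schedule, ids, "ext", window_ms[1L], window_ms[2L],
                    rate_hz, g_inc_ns)
}

#' Add background drive to all EIP/PEI/PEN units
#'
#' Independent Poisson excitation giving the suppression currents a
#' baseline to act against; ring pools receive no background drive.
#'
#' @param schedule A \code{\link{drive_schedule}}.
#' @param network An \code{ebpb_network}.
#' @param t_on_ms,t_off_ms Window.
#' @param background List with \code{rate_hz} and \code{g_inc_ns}.
#' @return The extended schedule.
#' @export
add_background_drive <- function(schedule, network, t_on_ms, t_off_ms,
                                 background = ringmem_config()$background) {
  ids <- c(pop_ids(network, "EIP"), pop_ids(network, "PEI"),
           pop_ids(network, "PEN"))
  add_poisson_drive(schedule, ids, "ext", t_on_ms, t_off_ms,
                    background$rate_hz, background$g_inc_ns)
}

#' Integrate the network
#'
#' Runs the fixed-step exponential-Euler integrator over the given drive
#' schedule and returns the spike record.
#'
#' @param network An \code{ebpb_network}.
#' @param duration_ms Total duration (a multiple of \code{dt_ms}).
#' @param schedule A \code{\link{drive_schedule}}.
#' @param dt_ms Time step (default 0.1 ms; must be positive and no longer
#'   than the refractory period).
#' @param seed Integer seed (default: the network's stored seed).
#' @param record_v_ids Optional neuron ids whose membrane potential is
#'   recorded.
#' @param record_stride_ms Sampling interval of the membrane record.
#' @return A list of class \code{spike_record} with \code{spikes}
#'   (data.frame \code{neuron_id}, \code{population}, \code{time_ms}),
#'   \code{v} (matrix, if requested), \code{duration_ms}, \code{dt_ms}.
#' @export
integrate_network <- function(network, duration_ms, schedule = drive_schedule(),
                              dt_ms = 0.1, seed = network$seed,
                              record_v_ids = integer(0),
                              record_stride_ms = 1) {
  lif <- network$lif
  if (dt_ms <= 0 || dt_ms > lif$t_ref_ms)
    stopf("dt must be in (0, refractory period]")
  if (abs(duration_ms / dt_ms - round(duration_ms / dt_ms)) > 1e-6)
    stopf("duration must be a multiple of dt")
  n <- nrow(network$neurons)
  rep_n <- function(x) rep_len(x, n)
  res <- .lif_run(n,
                  rep_n(lif$tau_m_ms), rep_n(lif$v_rest_mv),
                  rep_n(lif$v_thr_mv), rep_n(lif$v_reset_mv),
                  rep_n(lif$t_ref_ms), rep_n(lif$c_m_nf),
                  network$kinetics$tau_ms, network$kinetics$erev_mv,
                  network$kinetics$alpha,
                  as.integer(network$synapses$pre),
                  as.integer(network$synapses$post),
                  as.integer(network$synapses$receptor),
                  as.numeric(network$synapses$g_inc_ns),
                  schedule$poisson, schedule$current,
                  duration_ms, dt_ms, as.integer(seed),
                  rep_n(lif$v_rest_mv),
                  as.integer(record_v_ids),
                  max(1L, as.integer(round(record_stride_ms / dt_ms))))
  spikes <- data.frame(neuron_id = res$neuron_id,
                       population = network$neurons$population[
                         res$neuron_id + 1L],
                       time_ms = res$time_ms)
  structure(list(spikes = spikes, v = res$v, duration_ms = duration_ms,
                 dt_ms = dt_ms, seed = seed),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("Spike record: %d spikes over %.1f s\n", nrow(x$spikes),
              x$duration_ms / 1000))
  invisible(x)
}

#' EIP wedge-by-time rate profile of a simulation
#'
#' @param network The \code{ebpb_network} that produced the record.
#' @param sim A \code{spike_record}.
#' @param bin_ms Bin width (default 100).
#' @return A \code{\link{rate_profile}}.
#' @export
eip_rate_profile <- function(network, sim, bin_ms = 100) {
  wedge_of <- rep(NA_integer_, nrow(network$neurons))
  eip <- network$neurons$population == "EIP"
  wedge_of[network$neurons$neuron_id[eip] + 1L] <-
    network$neurons$wedge[eip]
  rate_profile(sim$spikes, wedge_of, sim$duration_ms, bin_ms,
               n_wedges = network$topology$n_wedges)
}

#' Serialize a spike record to delimited text
#' @param sim A \code{spike_record}.
#' @param path Output path.
#' @export
write_spikes <- function(sim, path) {
  utils::write.table(sim$spikes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
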