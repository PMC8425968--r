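#' Conditions supported by the trial protocol
#' @export
protocol_conditions <- function() {
  c("wildtype", "eip_suppress", "p_suppress",
    "eip_photo_stim", "eip_photo_post", "p_photo_stim", "p_photo_post")
}

#' Specification of a simulated trial protocol
#'
#' A trial covers the stimulus stage (landmark visible) followed by the
#' poststimulus stage (landmark off, movement feedback only).  Suppression
#' conditions apply a constant negative current to a ring population for
#' the whole trial; photoactivation conditions apply +0.20 nA either during
#' the last 30 s of the stimulus stage (\code{*_photo_stim}) or for 10 s
#' starting 20 s into the poststimulus stage (\code{*_photo_post}).
#'
#' @param condition One of \code{\link{protocol_conditions}}.
#' @param stim_s,post_s Stage durations in seconds (defaults 60 and 90).
#' @param landmark_azimuths_deg Landmark azimuths (default \code{c(0, 180)}).
#' @param n_trials Number of trials for batch runs.
#' @param seed Batch seed.
#' @return An object of class \code{protocol_spec}, including the computed
#'   \code{manipulation_window_s} (\code{NULL} for whole-trial or no
#'   manipulation).
#' @export
protocol_spec <- function(condition = "wildtype", stim_s = 60, post_s = 90,
                          landmark_azimuths_deg = c(0, 180), n_trials = 1L,
                          seed = 1L) {
  condition <- match.arg(condition, protocol_conditions())
  window <- switch(condition,
                   eip_photo_stim = , p_photo_stim = c(stim_s - 30, stim_s),
                   eip_photo_post = ,
                   p_photo_post = c(stim_s + 20, stim_s + 30),
                   NULL)
  structure(list(condition = condition, stim_s = stim_s, post_s = post_s,
                 landmark_azimuths_deg = landmark_azimuths_deg,
                 manipulation_window_s = window,
                 n_trials = as.integer(n_trials), seed = seed),
            class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf("Protocol: %s, %g s stimulus + %g s poststimulus, %d trial(s)\n",
              x$condition, x$stim_s, x$post_s, x$n_trials))
  if (!is.null(x$manipulation_window_s))
    cat(sprintf("  photoactivation window: %g-%g s\n",
                x$manipulation_window_s[1L], x$manipulation_window_s[2L]))
  invisible(x)
}

# collapse consecutive equal values into (value, t_on, t_off) runs
step_runs <- function(values, step_ms) {
  r <- rle(values)
  ends <- cumsum(r$lengths)
  data.frame(value = r$values,
             t_on = (ends - r$lengths) * step_ms,
             t_off = ends * step_ms)
}

# piecewise-linear heading (degrees, unwrapped) sampled at arbitrary times
heading_at <- function(behavior, t_s) {
  hs <- unwrap_deg(behavior$heading_deg)
  n <- length(hs)
  step <- behavior$step_s
  # heading at the end of the last step
  last <- hs[n] + (behavior$state[n] == "rotation") *
    behavior$rotation_direction[n] * behavior$params$rotation_speed_deg_s *
    step
  stats::approx(c(behavior$time_s, n * step), c(hs, last), xout = t_s,
                rule = 2)$y
}

#' Build the full drive schedule of one trial
#'
#' Exposed mainly for inspection and testing; \code{\link{run_trial}} calls
#' this internally.  Gating follows the behavior state step by step:
#' forward movement drives the P-ring pool (suppressing the shifter
#' circuit), rotation drives the C-ring pool and sends unilateral PB input
#' on the side matching the rotation direction.  During the stimulus stage
#' the landmark stream targets the PB glomeruli matching the landmark
#' bearing relative to the current heading.
#'
#' @param network An \code{ebpb_network}.
#' @param protocol A \code{\link{protocol_spec}}.
#' @param behavior A \code{behavior_sequence} covering the trial.
#' @param config A \code{\link{ringmem_config}}.
#' @return A \code{\link{drive_schedule}}.
#' @export
build_trial_schedule <- function(network, protocol, behavior,
                                 config = ringmem_config()) {
  dur_ms <- (protocol$stim_s + protocol$post_s) * 1000
  stim_ms <- protocol$stim_s * 1000
  step_ms <- behavior$params$step_ms
  sched <- drive_schedule()
  sched <- add_background_drive(sched, network, 0, dur_ms,
                                config$background)
  # the EIP-ring pool is tonically active for the whole trial; suppression
  # and photoactivation currents act against this baseline
  sched <- apply_ring_modulation(sched, network, "EIP-ring",
                                 config$ring_eip_tonic_na, c(0, dur_ms))
  gate <- config$ring_gate_current_na

  # state gating: full P-ring drive during forward bouts; during rotation
  # the C-ring gate is on and the P-ring keeps only a partial drive, so the
  # shifter circuit is partially (not fully) disinhibited
  st <- step_runs(as.character(behavior$state), step_ms)
  for (i in seq_len(nrow(st))) {
    win <- c(st$t_on[i], min(st$t_off[i], dur_ms))
    if (st$value[i] == "forward") {
      sched <- apply_ring_modulation(sched, network, "P-ring", gate, win)
    } else {
      sched <- apply_ring_modulation(sched, network, "C-ring", gate, win)
      sched <- apply_ring_modulation(sched, network, "P-ring",
                                     config$ring_gate_partial_na, win)
    }
  }
  # unilateral PB input during rotation: CCW body rotation (+1) -> left PB
  # (clockwise bump shift); CW body rotation (-1) -> right PB
  side_code <- ifelse(behavior$state == "rotation",
                      ifelse(behavior$rotation_direction > 0, "left",
                             "right"), "none")
  sr <- step_runs(side_code, step_ms)
  for (i in seq_len(nrow(sr))) {
    if (sr$value[i] == "none") next
    sched <- deliver_rotation_input(sched, network, sr$value[i],
                                    config$rotation$rate_hz,
                                    c(sr$t_on[i], min(sr$t_off[i], dur_ms)),
                                    config$rotation$g_inc_ns)
  }
  # landmark stream during the stimulus stage, bearing-relative
  cue_az <- wrap360(-behavior$heading_deg)
  cue_wedge <- azimuth_wedge(cue_az)
  cr <- step_runs(cue_wedge, step_ms)
  for (i in seq_len(nrow(cr))) {
    if (cr$t_on[i] >= stim_ms) break
    sched <- deliver_visual_input(sched, network,
                                  wedge_center_deg(cr$value[i]),
                                  config$visual$rate_hz,
                                  c(cr$t_on[i], min(cr$t_off[i], stim_ms)),
                                  config$visual$g_inc_ns)
  }
  # condition-specific ring currents
  cur <- config$currents
  cond <- protocol$condition
  win_ms <- protocol$manipulation_window_s * 1000
  sched <- switch(cond,
    wildtype = sched,
    eip_suppress = apply_ring_modulation(sched, network, "EIP-ring",
                                         cur$eip_ring_suppression_na,
                                         c(0, dur_ms)),
    p_suppress = apply_ring_modulation(sched, network, "P-ring",
                                       cur$p_ring_suppression_na,
                                       c(0, dur_ms)),
    eip_photo_stim = ,
    eip_photo_post = apply_ring_modulation(sched, network, "EIP-ring",
                                           cur$photoactivation_na, win_ms),
    p_photo_stim = ,
    p_photo_post = apply_ring_modulation(sched, network, "P-ring",
                                         cur$photoactivation_na, win_ms))
  sched
}

#' Run one simulated trial
#'
#' Generates a Markov behavior sequence, gates the circuit with it, applies
#' the condition-specific manipulations, integrates the spiking network,
#' and computes the EIP rate profile and bump trace.
#'
#' @param protocol A \code{\link{protocol_spec}}.
#' @param config A \code{\link{ringmem_config}}.
#' @param seed Trial seed (defaults to the protocol seed).
#' @param keep_spikes Keep the raw spike record (default \code{FALSE}; the
#'   rate profile is always kept).
#' @return An object of class \code{trial_record}.
#' @export
run_trial <- function(protocol, config = ringmem_config(),
                      seed = protocol$seed, keep_spikes = FALSE) {
  dur_s <- protocol$stim_s + protocol$post_s
  network <- build_network(lif = config$lif, kinetics = config$kinetics,
                           gains = config$gains, seed = seed)
  behavior <- generate_behavior(dur_s, config$markov,
                                seed = derive_seed(seed, 1))
  sched <- build_trial_schedule(network, protocol, behavior, config)
  sim <- integrate_network(network, dur_s * 1000, sched,
                           dt_ms = config$integration$dt_ms,
                           seed = derive_seed(seed, 2))
  profile <- eip_rate_profile(network, sim,
                              bin_ms = config$integration$rate_bin_ms)
  bump <- bump_trace(profile, smooth_ms = 500)
  structure(list(profile = profile, bump = bump,
                 heading_at_bins_deg = heading_at(behavior, profile$time_s),
                 behavior = behavior, protocol = protocol,
                 condition = protocol$condition, seed = seed,
                 bump_sign = -1,
                 spikes = if (keep_spikes) sim$spikes else NULL),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("Trial (%s, seed %s): bump present in %.0f%% of bins\n",
              x$condition, format(x$seed), 100 * mean(x$bump$present)))
  invisible(x)
}

#' Scalar bump metrics of one trial
#'
#' @param trial A \code{trial_record}.
#' @return A one-row data.frame: presence fractions per stage, FWHM over
#'   the whole trial (\code{NA} when undefined), mean heading-bump
#'   deviation (\code{NA} when the bump is absent at start), and the
#'   bump-lost flag.
#' @export
trial_metrics <- function(trial) {
  stim_s <- trial$protocol$stim_s
  tt <- trial$bump$time_s
  stim_sel <- tt < stim_s
  # deviation starts at the first bin with a detected bump
  first <- which(trial$bump$present)[1L]
  dev <- if (is.na(first)) NULL else tryCatch({
    tr2 <- trial
    tr2$bump <- trial$bump[first:nrow(trial$bump), ]
    tr2$heading_at_bins_deg <-
      trial$heading_at_bins_deg[first:nrow(trial$bump)]
    heading_bump_deviation(tr2)
  }, error = function(e) NULL)
  fwhm <- tryCatch(bump_fwhm(trial$profile), error = function(e) NA_real_)
  data.frame(condition = trial$condition, seed = trial$seed,
             present_stim = mean(trial$bump$present[stim_sel]),
             present_post = mean(trial$bump$present[!stim_sel]),
             fwhm_rad = fwhm,
             mean_deviation_deg = if (is.null(dev)) NA_real_
                                  else dev$mean_deviation_deg,
             bump_lost = bump_loss_fraction(list(trial)) > 0)
}

#' Run a batch of trials for one condition
#'
#' Per-trial seeds are derived deterministically from the batch seed.  A
#' failing trial is recorded (with its error message) and skipped.
#'
#' @param protocol A \code{\link{protocol_spec}} with \code{n_trials} set.
#' @param config A \code{\link{ringmem_config}}.
#' @param progress Print per-trial timing (default \code{FALSE}).
#' @return An object of class \code{condition_batch}: list with
#'   \code{trials} (list of \code{trial_record}s), \code{summary}
#'   (data.frame of \code{\link{trial_metrics}} rows), \code{failures}.
#' @export
run_condition_batch <- function(protocol, config = ringmem_config(),
                                progress = FALSE) {
  stopifnot(protocol$n_trials >= 1L)
  trials <- list()
  failures <- list()
  rows <- list()
  for (k in seq_len(protocol$n_trials)) {
    sk <- derive_seed(protocol$seed, 100 + k)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(run_trial(protocol, config, seed = sk),
                    error = function(e)
                      simpleError(sprintf("trial %d: %s", k,
                                          conditionMessage(e))))
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- res
      next
    }
    trials[[length(trials) + 1L]] <- res
    rows[[length(rows) + 1L]] <- cbind(trial = k, trial_metrics(res))
    if (progress)
      message(sprintf("  trial %d/%d (%s) %.1f s", k, protocol$n_trials,
                      protocol$condition,
                      proc.time()[["elapsed"]] - t0))
  }
  structure(list(trials = trials,
                 summary = do.call(rbind, rows),
                 failures = failures, protocol = protocol),
            class = "condition_batch")
}

#' @export
print.condition_batch <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Batch: %s, %d/%d trials ok\n", x$protocol$condition,
              length(x$trials), x$protocol$n_trials))
  if (!is.null(s))
    cat(sprintf("  bump present: stim %.0f%%, post %.0f%%; FWHM %.2f rad; lost %.0f%%\n",
                100 * mean(s$present_stim), 100 * mean(s$present_post),
                mean(s$fwhm_rad, na.rm = TRUE), 100 * mean(s$bump_lost)))
  invisible(x)
}

#' Trial-averaged FWHM of a batch
#'
#' @param batch A \code{condition_batch}.
#' @return List with \code{mean_rad}, \code{sem_rad}, \code{n}.
#' @export
batch_fwhm <- function(batch) {
  v <- batch$summary$fwhm_rad
  v <- v[!is.na(v)]
  list(mean_rad = mean(v), sem_rad = stats::sd(v) / sqrt(length(v)),
       n = length(v))
}
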