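#' Parameters for the synthetic free-walking fly generator
#'
#' The generator emulates the two-state Markov locomotion of platform
#' flies: forward bouts translate the fly at constant speed and constant
#' heading; rotation bouts turn in place.  A tunable fraction of rotation
#' bouts aim at the nearer fixation target (a screen azimuth), producing
#' landmark fixation; aimed headings are corrupted by wrapped Gaussian
#' noise so that even full bias does not collapse the direction histogram
#' onto a single quantile.
#'
#' @param markov A \code{\link{markov_params}}.
#' @param fixation_bias Probability that a rotation bout aims at a target;
#'   scalar, or one value per stage (named \code{pre}, \code{stim},
#'   \code{post}).  0 gives an isotropic random walk, 1 aims every bout.
#' @param fixation_targets_deg Screen azimuths of the targets; a vector
#'   applied to all stages, or a list with one vector per stage.
#' @param schedule Stage durations in seconds.
#' @param frame_rate_hz Sampling rate of the track (default 20).
#' @param aim_noise_sd_deg SD of the aiming noise (default 10).
#' @param forward_jitter_sd_deg Per-frame heading jitter during forward
#'   bouts (default 25).  Real walking flies wiggle; without it the
#'   direction histogram of an unbiased walk is far lumpier than real
#'   prestimulus data and the null fixation strength is inflated.
#' @param rotation_translation Fraction of the forward speed kept while
#'   turning (default 0.6): flies arc rather than pivot in place, which
#'   sweeps the movement direction during rotations and keeps the null
#'   fixation strength near the empirical control level.
#' @param position_noise_sd_mm Independent per-frame centroid noise
#'   (default 0.2 mm), emulating video tracking error.  It decorrelates
#'   consecutive movement directions the way real tracking data do;
#'   without it the null fixation strength is several times the empirical
#'   control mean.
#' @param seed Integer seed.
#' @return An object of class \code{synthetic_fly_params}.
#' @export
synthetic_fly_params <- function(markov = markov_params(),
                                 fixation_bias = 0,
                                 fixation_targets_deg = c(0, 180),
                                 schedule = c(pre = 90, stim = 60, post = 90),
                                 frame_rate_hz = 20,
                                 aim_noise_sd_deg = 10,
                                 forward_jitter_sd_deg = 25,
                                 rotation_translation = 0.6,
                                 position_noise_sd_mm = 0.2,
                                 seed = 1L) {
  stages <- names(schedule)
  bias <- if (length(fixation_bias) == 1L)
    stats::setNames(rep(fixation_bias, length(stages)), stages)
  else fixation_bias[stages]
  stopifnot(all(bias >= 0 & bias <= 1))
  targets <- if (is.list(fixation_targets_deg)) fixation_targets_deg[stages]
  else stats::setNames(rep(list(fixation_targets_deg), length(stages)),
                       stages)
  structure(list(markov = markov, bias = bias, targets = targets,
                 schedule = schedule, frame_rate_hz = frame_rate_hz,
                 aim_noise_sd_deg = aim_noise_sd_deg,
                 forward_jitter_sd_deg = forward_jitter_sd_deg,
                 rotation_translation = rotation_translation,
                 position_noise_sd_mm = position_noise_sd_mm,
                 seed = seed),
            class = "synthetic_fly_params")
}

#' Generate a synthetic fly track
#'
#' @param params A \code{\link{synthetic_fly_params}}.
#' @param geometry An \code{\link{arena_geometry}}.
#' @return A \code{\link{fly_track}} with stage labels from the schedule.
#' @export
synth_track <- function(params = synthetic_fly_params(),
                        geometry = arena_geometry()) {
  mk <- params$markov
  fs <- params$frame_rate_hz
  dt <- 1 / fs
  step_s <- mk$step_ms / 1000
  frames_per_step <- max(1L, round(step_s * fs))
  total_s <- sum(params$schedule)
  n_steps <- floor(total_s / step_s)
  edges <- cumsum(params$schedule)
  stage_of_time <- function(t)
    names(params$schedule)[findInterval(t, c(0, edges[-length(edges)] +
                                               1e-12))]
  R <- geometry$platform_radius_mm
  Rs <- geometry$screen_radius_mm
  with_seed(params$seed, {
    # Markov state chain at step resolution
    p_rot <- mk$p_fr / (mk$p_fr + mk$p_rf)
    state <- integer(n_steps)  # 1 forward, 2 rotation
    state[1L] <- if (stats::runif(1) < p_rot) 2L else 1L
    for (k in seq_len(n_steps - 1L)) {
      p_switch <- if (state[k] == 1L) mk$p_fr else mk$p_rf
      state[k + 1L] <- if (stats::runif(1) < p_switch) 3L - state[k]
      else state[k]
    }
    n_frames <- n_steps * frames_per_step
    x <- numeric(n_frames + 1L); y <- numeric(n_frames + 1L)
    heading <- 0
    x[1L] <- 0; y[1L] <- 0
    turn_rate <- 0       # deg/s during the current rotation bout
    target_heading <- NA # aimed bouts stop turning when reached
    f <- 1L
    for (k in seq_len(n_steps)) {
      t_k <- (k - 1L) * step_s
      new_bout <- k == 1L || state[k] != state[k - 1L]
      if (state[k] == 2L && new_bout) {
        stg <- stage_of_time(t_k)
        aimed <- stats::runif(1) < params$bias[[stg]]
        if (aimed) {
          tg <- params$targets[[stg]]
          # bearing from current position to each target's screen point
          bearing <- vapply(tg, function(az) {
            px <- Rs * cos(deg2rad(az)) - x[f]
            py <- Rs * sin(deg2rad(az)) - y[f]
            rad2deg(atan2(py, px))
          }, numeric(1))
          dev <- wrap180(bearing - heading)
          pick <- which.min(abs(dev))
          target_heading <- bearing[pick] +
            stats::rnorm(1, 0, params$aim_noise_sd_deg)
          turn_rate <- sign(wrap180(target_heading - heading)) *
            mk$rotation_speed_deg_s
        } else {
          target_heading <- NA
          turn_rate <- (if (stats::runif(1) < 0.5) -1 else 1) *
            mk$rotation_speed_deg_s
        }
      }
      for (j in seq_len(frames_per_step)) {
        if (state[k] == 1L) {
          heading <- heading +
            stats::rnorm(1, 0, params$forward_jitter_sd_deg)
          dx <- mk$forward_speed_mm_s * dt * cos(deg2rad(heading))
          dy <- mk$forward_speed_mm_s * dt * sin(deg2rad(heading))
          nx <- x[f] + dx; ny <- y[f] + dy
          if (nx^2 + ny^2 > R^2) {
            # clamp to the rim and turn onto the nearer tangent: flies
            # follow the platform edge rather than bounce off it, which
            # makes unbiased walks circulate and sweep all directions
            rr <- sqrt(nx^2 + ny^2)
            nx <- nx * (2 * R - rr) / rr
            ny <- ny * (2 * R - rr) / rr
            pos_az <- rad2deg(atan2(ny, nx))
            tangents <- pos_az + c(90, -90)
            heading <- tangents[which.min(abs(wrap180(tangents - heading)))]
          }
          x[f + 1L] <- nx; y[f + 1L] <- ny
        } else {
          dh <- turn_rate * dt
          if (!is.na(target_heading)) {
            remaining <- wrap180(target_heading - heading)
            if (abs(dh) >= abs(remaining)) {
              dh <- remaining
              turn_rate <- 0
            }
          }
          heading <- heading + dh
          # flies keep translating while turning (arcing paths); without
          # this the direction histogram is built from frozen forward
          # headings only and the null fixation strength is far above
          # what real prestimulus flies show
          spd <- mk$forward_speed_mm_s * params$rotation_translation
          nx <- x[f] + spd * dt * cos(deg2rad(heading))
          ny <- y[f] + spd * dt * sin(deg2rad(heading))
          if (nx^2 + ny^2 > R^2) {
            rr <- sqrt(nx^2 + ny^2)
            nx <- nx * (2 * R - rr) / rr
            ny <- ny * (2 * R - rr) / rr
          }
          x[f + 1L] <- nx; y[f + 1L] <- ny
        }
        f <- f + 1L
      }
    }
    time_s <- (0:n_frames) * dt
    if (params$position_noise_sd_mm > 0) {
      x <- x + stats::rnorm(length(x), 0, params$position_noise_sd_mm)
      y <- y + stats::rnorm(length(y), 0, params$position_noise_sd_mm)
      # observed positions stay on the platform
      rr <- sqrt(x^2 + y^2)
      over <- rr > R
      if (any(over)) {
        x[over] <- x[over] * R / rr[over]
        y[over] <- y[over] * R / rr[over]
      }
    }
    fly_track(time_s, x, y, schedule = params$schedule)
  })
}

#' Generate a cohort of independent synthetic flies
#'
#' @param n Number of flies (>= 1).
#' @param params A \code{\link{synthetic_fly_params}} template; each fly
#'   gets a seed derived from \code{params$seed}.
#' @param geometry An \code{\link{arena_geometry}}.
#' @return List of \code{\link{fly_track}}s.
#' @export
synth_cohort <- function(n, params = synthetic_fly_params(),
                         geometry = arena_geometry()) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(k) {
    p <- params
    p$seed <- derive_seed(params$seed, k)
    synth_track(p, geometry)
  })
}

#' Per-stage fixation statistics of one track
#'
#' The full trajectory pipeline: movement directions, sliding-window
#' histograms per stage, fixation density toward the landmark pair,
#' stage-pooled direction histogram, fixation strength and deviation
#' angle, and the performance index (post minus pre fixation density).
#'
#' @param track A \code{\link{fly_track}}.
#' @param geometry An \code{\link{arena_geometry}}.
#' @param pair_deg Landmark pair for the fixation density.
#' @param ... Passed to \code{\link{movement_directions}}.
#' @return A list with \code{per_stage} (data.frame: stage, FD, FS,
#'   sigma_f_deg, n_epochs) and \code{PI}.
#' @export
analyze_track <- function(track, geometry = arena_geometry(),
                          pair_deg = c(0, 180), ...) {
  dirs <- movement_directions(track, geometry, ...)
  stages <- levels(track$stage)
  edges <- c(0, cumsum(tapply(rep(1, nrow(track)), track$stage, length)))
  rows <- list()
  fd <- stats::setNames(rep(NA_real_, length(stages)), stages)
  for (stg in stages) {
    tt <- track$time_s[track$stage == stg]
    if (length(tt) == 0L) next
    h <- direction_histograms(dirs, t_start = min(tt), t_end = max(tt),
                              stage = stg)
    fd_s <- tryCatch(fixation_density(h, pair_deg),
                     error = function(e) NA_real_)
    fd[stg] <- fd_s
    sel <- dirs$stage == stg
    pooled <- if (any(sel))
      tabulate(direction_bin(dirs$theta_deg[sel]), 12L) / sum(sel)
    else rep(NA_real_, 12L)
    fg <- if (all(is.finite(pooled))) fixation_geometry(pooled)
    else list(FS = NA_real_, sigma_f_deg = NA_real_)
    rows[[stg]] <- data.frame(stage = stg, FD = fd_s, FS = fg$FS,
                              sigma_f_deg = fg$sigma_f_deg,
                              n_epochs = nrow(h$p))
  }
  list(per_stage = do.call(rbind, rows),
       PI = if (!is.na(fd["post"]) && !is.na(fd["pre"]))
         performance_index(fd[["post"]], fd[["pre"]]) else NA_real_)
}

#' Parameters of the synthetic bump-profile generator
#'
#' A von Mises shaped wedge profile with known center trace, width, peak
#' rate, and additive Gaussian noise; ground truth is recorded so that the
#' bump estimators can be checked for recovery.
#'
#' @param center_deg Bump center per time bin (recycled), degrees.
#' @param kappa Von Mises concentration (sets the width; the analytic FWHM
#'   is \code{2*acos(1 + log(0.5)/kappa)} radians when defined).
#' @param peak_hz Peak rate (> 0, unless exactly 0 to emulate no bump).
#' @param noise_sd_hz SD of additive truncated Gaussian noise.
#' @param n_bins Number of time bins.
#' @param bin_ms Bin width.
#' @param n_wedges Ring size (default 18).
#' @param seed Integer seed.
#' @return An object of class \code{synthetic_bump_params}.
#' @export
synthetic_bump_params <- function(center_deg = 190, kappa = 2.5,
                                  peak_hz = 40, noise_sd_hz = 0,
                                  n_bins = 100L, bin_ms = 100,
                                  n_wedges = 18L, seed = 1L) {
  if (peak_hz < 0) stopf("peak rate must be >= 0")
  structure(list(center_deg = center_deg, kappa = kappa, peak_hz = peak_hz,
                 noise_sd_hz = noise_sd_hz, n_bins = as.integer(n_bins),
                 bin_ms = bin_ms, n_wedges = as.integer(n_wedges),
                 seed = seed),
            class = "synthetic_bump_params")
}

#' Analytic FWHM of the generating von Mises shape
#' @param kappa Concentration parameter.
#' @return FWHM in radians (\code{2*pi} when the shape never falls below
#'   half maximum).
#' @export
vm_fwhm <- function(kappa) {
  arg <- 1 + log(0.5) / kappa
  if (arg <= -1) 2 * pi else 2 * acos(arg)
}

#' Generate a synthetic wedge-by-time rate profile
#'
#' @param params A \code{\link{synthetic_bump_params}}.
#' @return A \code{\link{rate_profile}} with attribute \code{ground_truth}
#'   (list: center trace, kappa, peak, analytic FWHM).
#' @export
synth_rate_profile <- function(params = synthetic_bump_params()) {
  centers <- wedge_center_deg(0:(params$n_wedges - 1L))
  cc <- rep_len(params$center_deg, params$n_bins)
  rates <- with_seed(params$seed, {
    m <- outer(centers, cc, function(w, c0)
      params$peak_hz * exp(params$kappa * (cos(deg2rad(w - c0)) - 1)))
    if (params$noise_sd_hz > 0)
      m <- pmax(m + matrix(stats::rnorm(length(m), 0, params$noise_sd_hz),
                           nrow(m)), 0)
    m
  })
  out <- structure(list(rates = rates, bin_ms = params$bin_ms,
                        time_s = (seq_len(params$n_bins) - 0.5) *
                          params$bin_ms / 1000,
                        wedge_center_deg = centers, units_per_wedge = 1L),
                   class = "rate_profile")
  attr(out, "ground_truth") <- list(center_deg = cc, kappa = params$kappa,
                                    peak_hz = params$peak_hz,
                                    fwhm_rad = vm_fwhm(params$kappa))
  out
}
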