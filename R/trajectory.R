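#' Movement directions of a track projected onto the screen
#'
#' For each pair of consecutive frames the displacement vector is computed;
#' the movement direction \eqn{\theta} is the azimuth of the point where the
#' forward ray from the current position intersects the screen circle.  This
#' position-dependent projection is the default; the simpler velocity-vector
#' azimuth is available via \code{convention = "velocity"}.  Frames whose
#' displacement falls below \code{move_threshold_mm} are treated as
#' stationary and yield no direction sample.
#'
#' @param track A \code{\link{fly_track}}.
#' @param geometry An \code{\link{arena_geometry}}.
#' @param convention \code{"screen"} (ray-screen intersection) or
#'   \code{"velocity"} (displacement azimuth).
#' @param move_threshold_mm Minimum per-frame displacement counted as
#'   movement (default 0.25 mm, well below fly walking speeds at 20-25 fps).
#' @return A \code{data.frame} with columns \code{time_s} (time of the second
#'   frame of each pair), \code{theta_deg}, and \code{stage}.
#' @export
movement_directions <- function(track, geometry = arena_geometry(),
                                convention = c("screen", "velocity"),
                                move_threshold_mm = 0.25) {
  convention <- match.arg(convention)
  n <- nrow(track)
  if (n < 2L) stopf("need at least 2 samples")
  dx <- diff(track$x_mm); dy <- diff(track$y_mm)
  disp <- sqrt(dx^2 + dy^2)
  moving <- disp >= move_threshold_mm
  x0 <- track$x_mm[-1L]; y0 <- track$y_mm[-1L]
  if (convention == "screen") {
    R <- geometry$screen_radius_mm
    ux <- dx / disp; uy <- dy / disp
    # forward ray from (x0,y0) along (ux,uy) meets circle of radius R at
    # t = -p.u + sqrt((p.u)^2 + R^2 - |p|^2)  (positive root)
    pu <- x0 * ux + y0 * uy
    t_hit <- -pu + sqrt(pmax(pu^2 + R^2 - (x0^2 + y0^2), 0))
    theta <- wrap360(rad2deg(atan2(y0 + t_hit * uy, x0 + t_hit * ux)))
  } else {
    theta <- wrap360(rad2deg(atan2(dy, dx)))
  }
  out <- data.frame(time_s = track$time_s[-1L],
                    theta_deg = theta,
                    stage = track$stage[-1L])
  out[moving, , drop = FALSE]
}

# quantile index 1..12 for bin centers 0, 30, ..., 330 (bins [c-15, c+15))
direction_bin <- function(theta_deg) {
  (floor(wrap360(theta_deg + 15) / 30) %% 12L) + 1L
}

#' Quantile centers of the 12-bin direction histogram (degrees)
#' @export
direction_bin_centers <- function() seq(0, 330, by = 30)

#' Sliding-window direction histograms
#'
#' Computes the fraction of movement-direction samples falling in each of 12
#' 30-degree quantiles, every \code{step_s} seconds over a sliding window of
#' \code{window_s} seconds.  Epoch \eqn{k} covers
#' \eqn{[t0 + (k-1) step, t0 + (k-1) step + window)}; the number of epochs in
#' a stage of duration \eqn{T} is \eqn{floor((T - window)/step) + 1}.
#'
#' @param directions Output of \code{\link{movement_directions}}, or a
#'   data.frame with \code{time_s} and \code{theta_deg}.
#' @param t_start,t_end Stage boundaries in seconds (defaults: span of the
#'   direction samples' stage, see \code{stage}).
#' @param stage If given, restrict to samples of this stage and use the
#'   stage's time span implied by \code{t_start}/\code{t_end}.
#' @param window_s,step_s Sliding window length and step (defaults 15 and 5).
#' @return A list with \code{epoch_time_s} (window start times), \code{p}
#'   (epochs x 12 probability matrix; rows of empty epochs are \code{NA}),
#'   and \code{n} (sample count per epoch).
#' @export
direction_histograms <- function(directions, t_start = NULL, t_end = NULL,
                                 stage = NULL, window_s = 15, step_s = 5) {
  d <- directions
  if (!is.null(stage)) d <- d[d$stage == stage, , drop = FALSE]
  if (is.null(t_start)) t_start <- if (nrow(d)) min(d$time_s) else 0
  if (is.null(t_end)) t_end <- if (nrow(d)) max(d$time_s) else t_start
  dur <- t_end - t_start
  n_epoch <- max(0L, floor((dur - window_s) / step_s) + 1L)
  p <- matrix(NA_real_, n_epoch, 12L)
  cnt <- integer(n_epoch)
  if (n_epoch == 0L)
    return(list(epoch_time_s = numeric(0), p = p, n = cnt))
  starts <- t_start + (seq_len(n_epoch) - 1L) * step_s
  bins <- direction_bin(d$theta_deg)
  for (k in seq_len(n_epoch)) {
    sel <- d$time_s >= starts[k] & d$time_s < starts[k] + window_s
    cnt[k] <- sum(sel)
    if (cnt[k] > 0L)
      p[k, ] <- tabulate(bins[sel], nbins = 12L) / cnt[k]
  }
  list(epoch_time_s = starts, p = p, n = cnt)
}

#' Fixation density toward a landmark pair
#'
#' The fraction of epochs in which the summed probability of moving toward
#' the two paired quantiles exceeds 1/6, the chance level for two of twelve
#' quantiles under isotropic movement.  The inequality is strict, so an
#' exactly uniform histogram never counts.  Epochs without any movement
#' sample are excluded from the denominator.
#'
#' @param histograms Output of \code{\link{direction_histograms}}.
#' @param pair_deg The two opposed quantile centers (default \code{c(0, 180)}).
#' @param threshold Occupancy threshold (default 1/6).
#' @return Fixation density in \eqn{[0, 1]}.
#' @export
fixation_density <- function(histograms, pair_deg = c(0, 180),
                             threshold = 1 / 6) {
  p <- histograms$p
  keep <- rowSums(is.na(p)) == 0L
  if (!any(keep)) stopf("fixation density undefined: no occupied epochs")
  idx <- direction_bin(pair_deg)
  pp <- p[keep, idx[1L]] + p[keep, idx[2L]]
  mean(pp > threshold)
}

#' Performance index
#'
#' The difference in fixation density between the poststimulus and the
#' prestimulus stage; positive values indicate orientation working memory.
#'
#' @param fd_post Fixation density of the poststimulus (3rd) stage.
#' @param fd_pre Fixation density of the prestimulus (1st) stage.
#' @return \code{fd_post - fd_pre}, in \eqn{[-1, 1]}.
#' @export
performance_index <- function(fd_post, fd_pre) {
  stopifnot(fd_post >= 0, fd_post <= 1, fd_pre >= 0, fd_pre <= 1)
  fd_post - fd_pre
}

#' Estimated memory duration from a performance index
#'
#' The performance index multiplied by the duration of the poststimulus
#' stage: the extra time spent fixating that is attributable to the earlier
#' landmark exposure.
#'
#' @param pi_value Performance index.
#' @param post_duration_s Duration of the poststimulus stage in seconds.
#' @return Estimated memory duration in seconds.
#' @export
memory_duration <- function(pi_value, post_duration_s) {
  pi_value * post_duration_s
}

#' Radar pairing of a 12-bin direction histogram
#'
#' Quantiles 180 degrees apart are averaged, making the radar plot
#' point-symmetric.  Under isotropic movement each paired value is 1/12, so
#' the summed occupancy of a pair is 1/6.
#'
#' @param p A 12-bin probability vector (centers 0, 30, ..., 330).
#' @return Named vector of 6 paired values at centers 0, 30, 60, 90, -60,
#'   -30 (the full point-symmetric 12-bin version is
#'   \code{rep(radar_profile(p), 2)}).
#' @export
radar_profile <- function(p) {
  stopifnot(length(p) == 12L)
  v <- (p[1:6] + p[7:12]) / 2
  names(v) <- c("0", "30", "60", "90", "-60", "-30")
  v
}

#' Fixation deviation angle and fixation strength
#'
#' From a 12-bin direction histogram (paired internally as in the radar
#' plot), finds the axis \eqn{\sigma_f} minimizing the second moment
#' \eqn{M(\sigma) = \sum_i p(\theta_i)^2 \sin^2(\theta_i - \sigma)} in closed
#' form, and the fixation strength \eqn{FS = 1 - M_{min}/M_{max}}.
#'
#' The closed form solves \eqn{dM/d\sigma = 0} via
#' \eqn{\sin(2\sigma + \phi) = 0} with \eqn{\cos\phi = A/K},
#' \eqn{\sin\phi = B/K},
#' \eqn{A = 2p(0)^2 + p(30)^2 - p(60)^2 - 2p(90)^2 + p(-30)^2 - p(-60)^2},
#' \eqn{B = \sqrt{3}(p(-30)^2 - p(30)^2 + p(-60)^2 - p(60)^2)},
#' \eqn{K = \sqrt{A^2 + B^2}}.  The two stationary axes are
#' \eqn{-\phi/2} and \eqn{90 - \phi/2}; \eqn{M} is evaluated at both and the
#' minimizer is \eqn{\sigma_f}.
#'
#' @param p A 12-bin probability vector, or a 6-element paired vector.
#' @return A list with \code{sigma_f_deg} (axial angle in (-90, 90];
#'   \code{NA} when isotropic), \code{FS}, \code{M_min}, \code{M_max},
#'   \code{A}, \code{B}, \code{K}, \code{phi_deg}, and \code{isotropic}.
#' @export
fixation_geometry <- function(p) {
  if (length(p) == 12L) q6 <- unname(radar_profile(p))
  else if (length(p) == 6L) q6 <- unname(p)
  else stopf("p must have 12 (raw) or 6 (paired) bins")
  if (any(q6 < 0)) stopf("histogram values must be >= 0")
  A <- 2 * q6[1]^2 + q6[2]^2 - q6[3]^2 - 2 * q6[4]^2 + q6[6]^2 - q6[5]^2
  B <- sqrt(3) * (q6[6]^2 - q6[2]^2 + q6[5]^2 - q6[3]^2)
  K <- sqrt(A^2 + B^2)
  # M over all 12 quantiles with paired values (each pair contributes twice)
  q12 <- rep(q6, 2L)
  th <- deg2rad(seq(0, 330, by = 30))
  M_of <- function(sigma_deg)
    sum(q12^2 * sin(th - deg2rad(sigma_deg))^2)
  if (K < .Machine$double.eps * sum(q6^2 + 1)) {
    return(list(sigma_f_deg = NA_real_, FS = 0,
                M_min = M_of(0), M_max = M_of(0),
                A = A, B = B, K = K, phi_deg = NA_real_, isotropic = TRUE))
  }
  phi <- rad2deg(atan2(B, A))
  cand <- c(-phi / 2, 90 - phi / 2)
  M_cand <- vapply(cand, M_of, numeric(1))
  i_min <- which.min(M_cand)
  list(sigma_f_deg = wrap90(cand[i_min]),
       FS = 1 - M_cand[i_min] / M_cand[3L - i_min],
       M_min = M_cand[i_min], M_max = M_cand[3L - i_min],
       A = A, B = B, K = K, phi_deg = phi, isotropic = FALSE)
}

#' Fixation-strength criterion from control statistics
#'
#' The significance criterion is set two standard deviations above the mean
#' fixation strength of control flies during the prestimulus stage.
#'
#' @param control_mean,control_sd Mean and SD of control FS values.
#' @param n_sd Number of standard deviations (default 2).
#' @return The FS criterion.
#' @export
fs_criterion <- function(control_mean = 0.0544, control_sd = 0.0273,
                         n_sd = 2) {
  control_mean + n_sd * control_sd
}

#' Classify fixation by the FS criterion
#'
#' @param FS Fixation strength in \eqn{[0, 1]}.
#' @param criterion Threshold (default \code{fs_criterion()} = 0.1090);
#'   classification is strict (\code{FS > criterion}).
#' @return Logical.
#' @export
classify_fixation <- function(FS, criterion = fs_criterion()) {
  stopifnot(all(FS >= 0 & FS <= 1))
  FS > criterion
}

#' Locomotion metrics of a track
#'
#' Activity level is the percentage of frames in which the fly moved (frame
#' displacement at or above the movement threshold); speed is total movement
#' distance divided by total movement duration, over moving frames only.
#'
#' @param track A \code{\link{fly_track}}.
#' @param move_threshold_mm Per-frame displacement threshold (default 0.25).
#' @param by_stage Compute per stage (default) or over the whole track.
#' @return A data.frame with \code{stage}, \code{activity_pct},
#'   \code{speed_mm_s} (\code{NA} when no frame moved), \code{n_frames}.
#' @export
locomotion_metrics <- function(track, move_threshold_mm = 0.25,
                               by_stage = TRUE) {
  dx <- diff(track$x_mm); dy <- diff(track$y_mm); dt <- diff(track$time_s)
  disp <- sqrt(dx^2 + dy^2)
  moving <- disp >= move_threshold_mm
  stg <- track$stage[-1L]
  one <- function(sel) {
    if (!any(sel)) return(c(activity = NA_real_, speed = NA_real_, n = 0))
    act <- 100 * mean(moving[sel])
    mv <- sel & moving
    spd <- if (any(mv)) sum(disp[mv]) / sum(dt[mv]) else NA_real_
    c(activity = act, speed = spd, n = sum(sel))
  }
  groups <- if (by_stage) levels(droplevels(stg)) else "all"
  rows <- lapply(groups, function(g) {
    sel <- if (by_stage) !is.na(stg) & stg == g else rep(TRUE, length(stg))
    one(sel)
  })
  m <- do.call(rbind, rows)
  data.frame(stage = groups, activity_pct = m[, "activity"],
             speed_mm_s = m[, "speed"], n_frames = m[, "n"])
}

#' Escape rate in the laser-avoidance vision test
#'
#' @param n_escapes Number of successful escapes.
#' @param n_events Total number of laser approach events (must be >= 1).
#' @return Escape rate in percent.
#' @export
escape_rate <- function(n_escapes, n_events) {
  if (n_events < 1) stopf("need at least one event")
  if (n_escapes < 0 || n_escapes > n_events)
    stopf("n_escapes must be between 0 and n_events")
  100 * n_escapes / n_events
}
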