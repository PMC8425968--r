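#' Wedge-to-azimuth map of the ellipsoid body discretization
#'
#' The EB is discretized into 18 wedges; wedge \eqn{i} (0-based) covers
#' \eqn{[20i, 20(i+1))} degrees, so its center azimuth is \eqn{20i + 10}.
#'
#' @param wedge 0-based wedge index (vectorized).
#' @return Center azimuth in degrees.
#' @export
wedge_center_deg <- function(wedge) wrap360(20 * wedge + 10)

#' Wedge index containing an azimuth
#' @param azimuth_deg Azimuth in degrees.
#' @return 0-based wedge index in 0..17.
#' @export
azimuth_wedge <- function(azimuth_deg) floor(wrap360(azimuth_deg) / 20) %% 18L

#' Wedge-by-time firing-rate profile from a spike record
#'
#' Pools spikes of the EIP units of each wedge into time bins and converts
#' counts to rates.  An empty spike record yields an all-zero profile.
#'
#' @param spikes A data.frame with columns \code{neuron_id} and
#'   \code{time_ms} (as returned by \code{\link{integrate_network}}),
#'   restricted by the caller to the units of interest.
#' @param wedge_of Integer vector mapping \code{neuron_id} to a 0-based
#'   wedge index (\code{NA} for units not pooled).
#' @param duration_ms Total duration covered by the record.
#' @param bin_ms Bin width in ms (default 100).
#' @param n_wedges Number of wedges (default 18).
#' @param units_per_wedge Number of pooled units per wedge (default computed
#'   from \code{wedge_of}).
#' @return An object of class \code{rate_profile}: list with \code{rates}
#'   (wedges x bins matrix, spikes/s), \code{bin_ms}, \code{time_s} (bin
#'   centers), and \code{wedge_center_deg}.
#' @export
rate_profile <- function(spikes, wedge_of, duration_ms, bin_ms = 100,
                         n_wedges = 18L, units_per_wedge = NULL) {
  if (bin_ms <= 0) stopf("bin_ms must be > 0")
  n_bins <- max(1L, floor(duration_ms / bin_ms + 1e-9))
  if (is.null(units_per_wedge)) {
    tab <- tabulate(wedge_of + 1L, nbins = n_wedges)
    units_per_wedge <- if (any(tab > 0)) max(tab) else 1L
  }
  counts <- matrix(0, n_wedges, n_bins)
  if (nrow(spikes) > 0) {
    w <- wedge_of[spikes$neuron_id + 1L]
    b <- pmin(floor(spikes$time_ms / bin_ms) + 1L, n_bins)
    ok <- !is.na(w)
    if (any(ok)) {
      flat <- (b[ok] - 1L) * n_wedges + w[ok] + 1L
      tab <- tabulate(flat, nbins = n_wedges * n_bins)
      counts <- matrix(tab, n_wedges, n_bins)
    }
  }
  rates <- counts / (bin_ms / 1000) / units_per_wedge
  structure(list(rates = rates, bin_ms = bin_ms,
                 time_s = (seq_len(n_bins) - 0.5) * bin_ms / 1000,
                 wedge_center_deg = wedge_center_deg(0:(n_wedges - 1L)),
                 units_per_wedge = units_per_wedge),
            class = "rate_profile")
}

#' @export
print.rate_profile <- function(x, ...) {
  cat(sprintf("Rate profile: %d wedges x %d bins of %g ms, peak %.1f Hz\n",
              nrow(x$rates), ncol(x$rates), x$bin_ms, max(x$rates)))
  invisible(x)
}

# is the TRUE-set of a logical ring vector one contiguous circular arc?
ring_contiguous <- function(flag) {
  n <- length(flag)
  k <- sum(flag)
  if (k == 0L) return(FALSE)
  if (k == n) return(TRUE)
  # rotate so a FALSE is first, then TRUEs must be consecutive
  first_false <- which(!flag)[1L]
  rot <- flag[c(first_false:n, seq_len(first_false - 1L))]
  idx <- which(rot)
  all(diff(idx) == 1L)
}

#' Detect an activity bump in one rate vector
#'
#' A bump is present when the peak rate reaches the absolute threshold and
#' dominates the ring-wide median, and the super-half-maximum region is one
#' contiguous circular arc spanning less than half the ring.  The bump
#' position is the rate-weighted circular mean over that region.
#'
#' @param rates Rate vector over wedges (one time bin), spikes/s.
#' @param centers_deg Wedge center azimuths (default the 18-wedge map).
#' @param min_peak_hz Absolute peak threshold (default 5 spikes/s).
#' @param median_factor Required ratio of peak to ring-wide median
#'   (default 3).
#' @return A list with \code{present}, \code{position_deg} (\code{NA} when
#'   absent), \code{amplitude_hz}, and \code{region} (logical arc mask).
#' @export
detect_bump <- function(rates, centers_deg = wedge_center_deg(0:17),
                        min_peak_hz = 5, median_factor = 3) {
  stopifnot(length(rates) == length(centers_deg))
  peak <- max(rates)
  region <- rates >= peak / 2
  ok <- peak >= min_peak_hz &&
    peak >= median_factor * stats::median(rates) &&
    ring_contiguous(region) &&
    sum(region) < length(rates) / 2
  if (!ok)
    return(list(present = FALSE, position_deg = NA_real_,
                amplitude_hz = peak, region = region))
  list(present = TRUE,
       position_deg = circ_mean_deg(centers_deg[region], rates[region]),
       amplitude_hz = peak, region = region)
}

# brute-force oracle used by the test suite: exhaustive search over all
# circular arcs for the super-half-max set; kept in the package so tests
# exercise the same entry points a user would
detect_bump_oracle <- function(rates, centers_deg = wedge_center_deg(0:17),
                               min_peak_hz = 5, median_factor = 3) {
  n <- length(rates)
  peak <- max(rates)
  target <- which(rates >= peak / 2)
  found <- NULL
  for (start in seq_len(n)) {
    for (len in seq_len(n - 1L)) {
      arc <- ((start - 1L) + seq_len(len) - 1L) %% n + 1L
      if (length(arc) == length(target) && setequal(arc, target)) {
        found <- arc
        break
      }
    }
    if (!is.null(found)) break
  }
  ok <- peak >= min_peak_hz && peak >= median_factor * stats::median(rates) &&
    !is.null(found) && length(found) < n / 2
  if (!ok) return(list(present = FALSE, position_deg = NA_real_))
  list(present = TRUE,
       position_deg = circ_mean_deg(centers_deg[found], rates[found]))
}

#' Per-bin bump metrics of a rate profile
#'
#' @param profile A \code{\link{rate_profile}}.
#' @param smooth_ms Optional moving-average window applied to each wedge's
#'   rate trace before detection (default 0 = none); single-unit wedges at
#'   tens of spikes/s need a few hundred ms to beat Poisson bin noise.
#' @param ... Passed to \code{\link{detect_bump}}.
#' @return A data.frame with one row per time bin: \code{time_s},
#'   \code{present}, \code{position_deg}, \code{amplitude_hz}.
#' @export
bump_trace <- function(profile, smooth_ms = 0, ...) {
  if (smooth_ms > 0) {
    k <- max(1L, round(smooth_ms / profile$bin_ms))
    if (k > 1L && ncol(profile$rates) > k) {
      sm <- t(apply(profile$rates, 1L, function(v) {
        f <- as.numeric(stats::filter(v, rep(1 / k, k), sides = 2))
        f[is.na(f)] <- v[is.na(f)]
        f
      }))
      profile$rates <- sm
    }
  }
  res <- apply(profile$rates, 2L, function(v)
    detect_bump(v, profile$wedge_center_deg, ...)[c("present",
                                                    "position_deg",
                                                    "amplitude_hz")])
  data.frame(time_s = profile$time_s,
             present = vapply(res, `[[`, logical(1), "present"),
             position_deg = vapply(res, `[[`, numeric(1), "position_deg"),
             amplitude_hz = vapply(res, `[[`, numeric(1), "amplitude_hz"))
}

#' Full width at half maximum of the time-averaged, bump-aligned profile
#'
#' Each time bin with a detected bump is circularly shifted so its bump sits
#' at the ring center; the aligned columns are averaged and the angular
#' width at half the averaged peak is found by linear interpolation between
#' wedge centers.
#'
#' @param profile A \code{\link{rate_profile}}.
#' @param window_s Optional \code{c(start, end)} restricting the time bins.
#' @param min_present Minimum fraction of bins with a detectable bump
#'   (default 0.8); below this the metric is undefined and an error is
#'   raised.
#' @param smooth_ms Temporal smoothing used for the detection pass only
#'   (see \code{\link{bump_trace}}); the averaged profile itself is built
#'   from the raw columns.
#' @param ... Passed to \code{\link{detect_bump}}.
#' @return FWHM in radians.
#' @export
bump_fwhm <- function(profile, window_s = NULL, min_present = 0.8,
                      smooth_ms = 0, ...) {
  tr <- bump_trace(profile, smooth_ms = smooth_ms, ...)
  keep <- rep(TRUE, nrow(tr))
  if (!is.null(window_s))
    keep <- tr$time_s >= window_s[1L] & tr$time_s < window_s[2L]
  if (!any(keep)) stopf("empty window")
  if (mean(tr$present[keep]) < min_present)
    stopf("bump FWHM undefined: bump present in %.0f%% < %.0f%% of bins",
          100 * mean(tr$present[keep]), 100 * min_present)
  cols <- which(keep & tr$present)
  n <- nrow(profile$rates)
  center_idx <- floor(n / 2)  # align bump onto this wedge
  acc <- numeric(n)
  for (j in cols) {
    shift <- (azimuth_wedge(tr$position_deg[j]) - center_idx) %% n
    acc <- acc + profile$rates[((seq_len(n) - 1L + shift) %% n) + 1L, j]
  }
  avg <- acc / length(cols)
  fwhm_of_profile(avg, step_deg = 360 / n)
}

# angular FWHM (radians) of a ring profile sampled at equally spaced wedge
# centers, by linear interpolation around the global peak
fwhm_of_profile <- function(avg, step_deg) {
  n <- length(avg)
  m <- which.max(avg)
  half <- avg[m] / 2
  cross <- function(dirn) {
    for (k in seq_len(n - 1L)) {
      i0 <- ((m - 1L + dirn * (k - 1L)) %% n) + 1L
      i1 <- ((m - 1L + dirn * k) %% n) + 1L
      if (avg[i1] < half) {
        frac <- (avg[i0] - half) / (avg[i0] - avg[i1])
        return((k - 1L + frac) * step_deg)
      }
    }
    NA_real_  # never drops below half: width is the whole ring
  }
  up <- cross(+1L)
  dn <- cross(-1L)
  if (is.na(up) || is.na(dn)) return(2 * pi)
  deg2rad(up + dn)
}

#' Deviation between accumulated bump angle and accumulated heading
#'
#' Both traces are unwrapped to accumulated angles; the deviation at each
#' time is the absolute difference of the accumulated changes since the
#' start (a common offset between the traces is therefore ignored).  The
#' bump position is smoothed with a moving average before unwrapping.  If
#' the bump is lost mid-trace (absent for at least \code{loss_gap_s}
#' seconds), the deviation is reported up to the loss time and flagged.
#'
#' @param bump A data.frame from \code{\link{bump_trace}} (columns
#'   \code{time_s}, \code{present}, \code{position_deg}), or a
#'   \code{trial_record} (whose stored bump sign convention is then used).
#' @param heading_deg Heading at the same time base, degrees.
#' @param bump_sign +1 when the bump azimuth co-rotates with the heading,
#'   -1 when it counter-rotates (the EB convention; trial records store it).
#' @param smooth_ms Moving-average window for the bump position (default
#'   500 ms).
#' @param loss_gap_s Gap length that counts as bump loss (default 2 s).
#' @return A list with \code{time_s}, \code{deviation_deg} (NA after loss),
#'   \code{mean_deviation_deg} (time-mean up to loss), \code{lost}, and
#'   \code{loss_time_s}.
#' @export
heading_bump_deviation <- function(bump, heading_deg, bump_sign = 1,
                                   smooth_ms = 500, loss_gap_s = 2) {
  if (inherits(bump, "trial_record")) {
    tr <- bump
    bump_sign <- tr$bump_sign
    heading_deg <- tr$heading_at_bins_deg
    bump <- tr$bump
  }
  stopifnot(nrow(bump) == length(heading_deg))
  if (!isTRUE(bump$present[1L])) stopf("bump absent at trace start")
  dt <- if (nrow(bump) > 1L) diff(bump$time_s[1:2]) else 1
  # loss time: first absence run of >= loss_gap_s
  r <- rle(bump$present)
  ends <- cumsum(r$lengths)
  loss_idx <- NA_integer_
  for (i in seq_along(r$lengths)) {
    if (!r$values[i] && r$lengths[i] * dt >= loss_gap_s) {
      loss_idx <- ends[i] - r$lengths[i]  # last present index before loss
      break
    }
  }
  lost <- !is.na(loss_idx)
  upto <- if (lost) loss_idx else nrow(bump)
  pos <- bump$position_deg[seq_len(upto)]
  pres <- bump$present[seq_len(upto)]
  # bridge short gaps by linear interpolation on the unwrapped trace
  unw <- rep(NA_real_, upto)
  unw[pres] <- unwrap_deg(pos[pres])
  if (any(!pres))
    unw <- stats::approx(which(pres), unw[pres], xout = seq_len(upto),
                         rule = 2)$y
  k <- max(1L, round(smooth_ms / 1000 / dt))
  if (k > 1L && upto > k)
    unw <- stats::filter(unw, rep(1 / k, k), sides = 2) |>
      (\(v) { v[is.na(v)] <- unw[is.na(v)]; as.numeric(v) })()
  head_unw <- unwrap_deg(heading_deg[seq_len(upto)])
  dev <- abs(bump_sign * (unw - unw[1L]) - (head_unw - head_unw[1L]))
  out_dev <- rep(NA_real_, nrow(bump))
  out_dev[seq_len(upto)] <- dev
  list(time_s = bump$time_s, deviation_deg = out_dev,
       mean_deviation_deg = mean(dev), lost = lost,
       loss_time_s = if (lost) bump$time_s[loss_idx + 1L] else NA_real_)
}

#' Fraction of trials that lose the bump in a window
#'
#' A trial counts as lost when the bump-present flag is false for a
#' continuous run of at least \code{min_loss_s} seconds within the window.
#'
#' @param trials List of \code{trial_record}s, or of \code{bump_trace}
#'   data.frames.
#' @param window_s Optional \code{c(start, end)} in seconds.
#' @param min_loss_s Minimum absence run (default 2 s).
#' @return Percentage of trials in \eqn{[0, 100]}.
#' @export
bump_loss_fraction <- function(trials, window_s = NULL, min_loss_s = 2) {
  if (length(trials) == 0L) stopf("need at least one trial")
  lost_one <- function(x) {
    b <- if (inherits(x, "trial_record")) x$bump else x
    keep <- rep(TRUE, nrow(b))
    if (!is.null(window_s))
      keep <- b$time_s >= window_s[1L] & b$time_s < window_s[2L]
    pres <- b$present[keep]
    if (length(pres) == 0L) return(FALSE)
    dt <- if (nrow(b) > 1L) diff(b$time_s[1:2]) else 1
    r <- rle(pres)
    any(!r$values & r$lengths * dt >= min_loss_s)
  }
  100 * mean(vapply(trials, lost_one, logical(1)))
}
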