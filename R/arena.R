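#' Arena geometry for the Buridan-style platform
#'
#' Describes the circular walking platform surrounded by a cylindrical LED
#' screen on which two dark vertical stripes serve as landmarks.  Angles are
#' screen azimuths in degrees, counterclockwise positive, with 0 degrees at
#' the first landmark.
#'
#' @param platform_radius_mm Radius of the walking platform (default 42.5,
#'   i.e. an 85 mm diameter platform).
#' @param screen_radius_mm Radius of the surrounding screen (default 100,
#'   i.e. a 200 mm diameter display).
#' @param landmark_azimuths_deg Azimuths of the landmark centers.
#' @param landmark_width_deg Angular width of each landmark stripe.
#' @return An object of class \code{arena_geometry}.
#' @export
arena_geometry <- function(platform_radius_mm = 42.5,
                           screen_radius_mm = 100,
                           landmark_azimuths_deg = c(0, 180),
                           landmark_width_deg = 30) {
  if (screen_radius_mm <= platform_radius_mm)
    stopf("screen radius (%g) must exceed platform radius (%g)",
          screen_radius_mm, platform_radius_mm)
  structure(list(platform_radius_mm = platform_radius_mm,
                 screen_radius_mm = screen_radius_mm,
                 landmark_azimuths_deg = wrap360(landmark_azimuths_deg),
                 landmark_width_deg = landmark_width_deg),
            class = "arena_geometry")
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat("Arena: platform r =", x$platform_radius_mm, "mm, screen r =",
      x$screen_radius_mm, "mm, landmarks at",
      paste0(x$landmark_azimuths_deg, collapse = "/"), "deg\n")
  invisible(x)
}

#' Construct a trajectory (track) object
#'
#' A track holds timestamped planar positions of one fly on the platform,
#' optionally labeled by task stage (\code{pre}, \code{stim}, \code{post}).
#'
#' @param time_s Sample times in seconds, strictly increasing.
#' @param x_mm,y_mm Positions in mm, origin at the platform center.
#' @param stage Optional per-sample stage factor; if \code{NULL}, stages are
#'   assigned from \code{schedule}.
#' @param schedule Stage durations in seconds, named \code{pre}, \code{stim},
#'   \code{post}; used only when \code{stage} is missing.
#' @return A \code{data.frame} of class \code{fly_track} with columns
#'   \code{time_s}, \code{x_mm}, \code{y_mm}, \code{stage}.
#' @export
fly_track <- function(time_s, x_mm, y_mm, stage = NULL,
                      schedule = c(pre = 90, stim = 60, post = 90)) {
  n <- length(time_s)
  if (length(x_mm) != n || length(y_mm) != n)
    stopf("time/x/y lengths differ")
  if (n > 1 && any(diff(time_s) <= 0))
    stopf("time_s must be strictly increasing")
  if (is.null(stage)) {
    edges <- cumsum(c(0, schedule))
    stage <- cut(time_s, breaks = c(edges[-length(edges)], Inf),
                 labels = names(schedule), right = FALSE)
  }
  out <- data.frame(time_s = time_s, x_mm = x_mm, y_mm = y_mm,
                    stage = factor(stage, levels = c("pre", "stim", "post")))
  class(out) <- c("fly_track", "data.frame")
  out
}

#' Read a track from delimited text
#'
#' Expects a header with columns \code{time_s}, \code{x_mm}, \code{y_mm} and
#' optionally \code{stage}; extra columns are ignored.
#'
#' @param path File path.
#' @param schedule Stage schedule used when the file has no stage column.
#' @return A \code{fly_track}.
#' @export
read_track <- function(path, schedule = c(pre = 90, stim = 60, post = 90)) {
  d <- utils::read.table(path, header = TRUE, sep = "", as.is = TRUE)
  need <- c("time_s", "x_mm", "y_mm")
  if (!all(need %in% names(d)))
    stopf("track file must have columns %s", paste(need, collapse = ", "))
  fly_track(d$time_s, d$x_mm, d$y_mm,
            stage = if ("stage" %in% names(d)) d$stage else NULL,
            schedule = schedule)
}

#' Write a track as delimited text
#' @param track A \code{fly_track}.
#' @param path Output file path.
#' @export
write_track <- function(track, path) {
  utils::write.table(as.data.frame(track), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
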