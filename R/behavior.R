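#' Parameters of the two-state Markov locomotor model
#'
#' Free-walking flies alternate between forward movement and body rotation.
#' State changes occur only at 300 ms step boundaries with memoryless
#' switching probabilities estimated from exponential bout-duration fits.
#'
#' @param p_forward_to_rotation Per-step probability of switching from
#'   forward movement to rotation (default 0.40).
#' @param p_rotation_to_forward Per-step probability of switching from
#'   rotation to forward movement (default 0.60).
#' @param step_ms Step length in ms (default 300).
#' @param rotation_speed_deg_s Body rotation speed during rotation bouts
#'   (default 120 deg/s; see package vignette).
#' @param forward_speed_mm_s Walking speed during forward bouts (default 13
#'   mm/s, the wild-type range).
#' @return An object of class \code{markov_params}.
#' @export
markov_params <- function(p_forward_to_rotation = 0.40,
                          p_rotation_to_forward = 0.60,
                          step_ms = 300,
                          rotation_speed_deg_s = 120,
                          forward_speed_mm_s = 13) {
  stopifnot(p_forward_to_rotation >= 0, p_forward_to_rotation <= 1,
            p_rotation_to_forward >= 0, p_rotation_to_forward <= 1,
            step_ms > 0)
  structure(list(p_fr = p_forward_to_rotation,
                 p_rf = p_rotation_to_forward,
                 step_ms = step_ms,
                 rotation_speed_deg_s = rotation_speed_deg_s,
                 forward_speed_mm_s = forward_speed_mm_s),
            class = "markov_params")
}

#' Generate a Markov behavior sequence
#'
#' Simulates the forward/rotation state chain at the configured step length.
#' Each rotation bout draws an independent direction uniformly from
#' clockwise (-1) and counterclockwise (+1); the heading is constant within
#' forward bouts and rotates at the configured speed within rotation bouts.
#'
#' @param duration_s Total duration in seconds (at least one step).
#' @param params A \code{\link{markov_params}}.
#' @param seed Integer seed; identical seeds give identical sequences.
#' @param init_heading_deg Initial heading (default 0).
#' @param init_state Initial state, drawn from the stationary distribution
#'   when \code{NULL}.
#' @return An object of class \code{behavior_sequence}: a list with
#'   \code{step_s}, \code{time_s} (step start times), \code{state} (factor
#'   \code{forward}/\code{rotation}), \code{rotation_direction} (per-step
#'   -1/0/+1), and \code{heading_deg} (heading at each step start).
#' @export
generate_behavior <- function(duration_s, params = markov_params(),
                              seed = 1L, init_heading_deg = 0,
                              init_state = NULL) {
  step_s <- params$step_ms / 1000
  n <- floor(duration_s / step_s + 1e-9)
  if (n < 1L) stopf("duration must be at least one step (%g s)", step_s)
  with_seed(seed, {
    states <- integer(n)  # 1 = forward, 2 = rotation
    if (is.null(init_state)) {
      p_rot <- params$p_fr / (params$p_fr + params$p_rf)
      states[1L] <- if (stats::runif(1) < p_rot) 2L else 1L
    } else {
      init_state <- match.arg(init_state, c("forward", "rotation"))
      states[1L] <- if (init_state == "rotation") 2L else 1L
    }
    u <- stats::runif(n - 1L)
    for (k in seq_len(n - 1L)) {
      p_switch <- if (states[k] == 1L) params$p_fr else params$p_rf
      states[k + 1L] <- if (u[k] < p_switch) 3L - states[k] else states[k]
    }
    # one direction per rotation bout
    dir <- numeric(n)
    bout_id <- cumsum(c(TRUE, diff(states) != 0))
    for (b in unique(bout_id[states == 2L])) {
      sel <- bout_id == b
      dir[sel] <- if (stats::runif(1) < 0.5) -1 else 1
    }
    heading <- numeric(n)
    heading[1L] <- init_heading_deg
    if (n > 1L) {
      dheads <- ifelse(states == 2L,
                       dir * params$rotation_speed_deg_s * step_s, 0)
      heading <- wrap360(init_heading_deg + cumsum(c(0, dheads[-n])))
    }
    structure(list(step_s = step_s,
                   time_s = (seq_len(n) - 1L) * step_s,
                   state = factor(c("forward", "rotation")[states],
                                  levels = c("forward", "rotation")),
                   rotation_direction = dir,
                   heading_deg = heading,
                   params = params, seed = seed),
              class = "behavior_sequence")
  })
}

#' @export
print.behavior_sequence <- function(x, ...) {
  cat(sprintf("Behavior sequence: %d steps of %g s (%.1f s), %.1f%% forward\n",
              length(x$state), x$step_s, length(x$state) * x$step_s,
              100 * mean(x$state == "forward")))
  invisible(x)
}

#' Serialize a behavior sequence to delimited text
#' @param seq A \code{behavior_sequence}.
#' @param path Output path.
#' @export
write_behavior <- function(seq, path) {
  utils::write.table(
    data.frame(step_index = seq_along(seq$state) - 1L,
               time_s = seq$time_s, state = seq$state,
               heading_deg = seq$heading_deg),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bout durations of one behavioral state
#'
#' Runs of consecutive steps in the given state; durations are multiples of
#' the step length and sum to the total time spent in the state.
#'
#' @param seq A \code{behavior_sequence}.
#' @param state \code{"forward"} or \code{"rotation"}.
#' @return Numeric vector of durations in seconds.
#' @export
bout_durations <- function(seq, state = c("forward", "rotation")) {
  state <- match.arg(state)
  r <- rle(as.character(seq$state))
  r$lengths[r$values == state] * seq$step_s
}

#' Fit an exponential curve to a bout-duration distribution
#'
#' Fits normalized bout-duration frequencies to
#' \eqn{y(x) = \alpha \beta^{x / 0.3}} by least squares on the
#' log-transformed frequencies of positive-count bins.  For a memoryless
#' (geometric) bout process \eqn{\beta} estimates the per-step probability
#' of staying in the state.
#'
#' @param durations_s Bout durations in seconds (multiples of the step).
#' @param step_s Step length in seconds (default 0.3).
#' @return A list of class \code{bout_fit} with \code{alpha}, \code{beta},
#'   \code{r_squared}, and the binned \code{table} used for the fit.
#' @export
fit_bout_distribution <- function(durations_s, step_s = 0.3) {
  k <- round(durations_s / step_s)
  if (length(unique(k)) < 2L)
    stopf("bout fit needs at least two distinct duration values")
  tab <- tabulate(k, nbins = max(k))
  x <- seq_along(tab) * step_s
  freq <- tab / sum(tab)
  keep <- freq > 0
  # weight by bin counts: sparse tail bins otherwise bias the slope upward
  fit <- stats::lm(log(freq[keep]) ~ I(x[keep] / step_s),
                   weights = tab[keep])
  beta <- exp(unname(stats::coef(fit)[2L]))
  alpha <- exp(unname(stats::coef(fit)[1L]))
  r2 <- summary(fit)$r.squared
  structure(list(alpha = alpha, beta = beta, r_squared = r2,
                 table = data.frame(duration_s = x, freq = freq)),
            class = "bout_fit")
}

#' @export
print.bout_fit <- function(x, ...) {
  cat(sprintf("Bout fit: y = %.3f * %.3f^(x/0.3), R^2 = %.3f\n",
              x$alpha, x$beta, x$r_squared))
  invisible(x)
}
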