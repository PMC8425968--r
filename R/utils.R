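# Internal helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' @noRd
wrap360 <- function(x) x %% 360

# wrap to (-180, 180]
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# wrap an axial angle (period 180) to (-90, 90]
wrap90 <- function(x) {
  y <- (x + 90) %% 180 - 90
  y[y == -90] <- 90
  y
}

# circular unwrap of a trace in degrees: removes jumps > 180
unwrap_deg <- function(x) {
  if (length(x) < 2L) return(x)
  d <- wrap180(diff(x))
  x[1L] + c(0, cumsum(d))
}

# circular mean of angles (degrees) with weights >= 0
circ_mean_deg <- function(theta, w = NULL) {
  th <- deg2rad(theta)
  if (is.null(w)) w <- rep(1, length(th))
  s <- sum(w * sin(th)); c <- sum(w * cos(th))
  if (s == 0 && c == 0) return(NA_real_)
  wrap360(rad2deg(atan2(s, c)))
}

# Evaluate an expression with a temporary RNG state seeded by `seed`,
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Deterministic per-trial seed derived from a batch seed; kept < 2^31.
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
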