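# Independent oracles used across test files.

# Brute-force minimization of the direction-histogram second moment
# M(sigma) = sum_i p_i^2 sin^2(theta_i - sigma) over a fine grid of axes.
# Works on the paired 12-bin histogram like the closed form.
grid_fixation_oracle <- function(p12, step_deg = 0.01) {
  q6 <- (p12[1:6] + p12[7:12]) / 2
  q12 <- rep(q6, 2L)
  th <- (0:11) * 30 * pi / 180
  sigma <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  # M over the grid in one matrix product: sin^2(th - s)
  S <- outer(th, sigma, function(a, b) sin(a - b)^2)
  M <- as.numeric(q12^2 %*% S)
  i <- which.min(M)
  list(sigma_f_deg = sigma[i] * 180 / pi, M_min = M[i], M_max = max(M),
       FS = 1 - M[i] / max(M))
}

# axial (period-180) absolute difference in degrees
axial_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# random 12-bin probability histograms
random_histograms <- function(n, seed = 1) {
  set.seed(seed)
  t(replicate(n, {
    x <- rgamma(12, shape = runif(1, 0.3, 3))
    x / sum(x)
  }))
}

# a von Mises shaped rate vector over the 18 wedge centers
vm_profile <- function(center_deg, kappa = 3, peak = 40) {
  centers <- wedge_center_deg(0:17)
  peak * exp(kappa * (cos((centers - center_deg) * pi / 180) - 1))
}

# quick small-network builder for integrator tests: all weights zero so
# units are isolated
isolated_network <- function(seed = 1) {
  wt <- weight_table()
  wt$weight[] <- 0
  build_network(weights = wt, seed = seed)
}

# shared cached batches for the slow protocol/acceptance tests; built once
# per test run on first use
.batch_cache <- new.env(parent = emptyenv())
cached_batch <- function(condition, n_trials, seed = 7001) {
  key <- sprintf("%s_%d_%d", condition, n_trials, seed)
  if (!is.null(.batch_cache[[key]])) return(.batch_cache[[key]])
  proto <- protocol_spec(condition, n_trials = n_trials, seed = seed)
  .batch_cache[[key]] <- run_condition_batch(proto)
  .batch_cache[[key]]
}
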