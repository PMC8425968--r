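test_that("movement directions project onto the screen circle", {
  geo <- arena_geometry()
  # fly at center: direction equals the landmark azimuth regardless of radius
  tk <- fly_track(c(0, 0.05, 0.1), c(0, 1, 2), c(0, 0, 0))
  d <- movement_directions(tk, geo)
  expect_equal(d$theta_deg, c(0, 0))
  tk <- fly_track(c(0, 0.05), c(0, -1), c(0, 0))
  expect_equal(movement_directions(tk, geo)$theta_deg, 180)
  # off-center fly moving +y: azimuth of ray-circle intersection
  tk <- fly_track(c(0, 0.05), c(30, 30), c(0, 1))
  got <- movement_directions(tk, geo)$theta_deg
  expect_equal(got, atan2(sqrt(100^2 - 30^2), 30) * 180 / pi,
               tolerance = 1e-8)
  # stationary frames yield no sample
  tk <- fly_track(c(0, 0.05, 0.1), c(0, 0.01, 1), c(0, 0, 0))
  expect_equal(nrow(movement_directions(tk, geo)), 1L)
  # velocity convention reduces to the displacement azimuth
  tk <- fly_track(c(0, 0.05), c(30, 30), c(0, 1))
  expect_equal(movement_directions(tk, geo,
                                   convention = "velocity")$theta_deg, 90)
})

test_that("sliding-window histograms have the documented epoch structure", {
  set.seed(1)
  n <- 90 * 20
  d <- data.frame(time_s = seq(0, 90, length.out = n),
                  theta_deg = runif(n, 0, 360))
  h <- direction_histograms(d, t_start = 0, t_end = 90)
  expect_equal(length(h$epoch_time_s), floor((90 - 15) / 5) + 1)  # 16
  expect_equal(rowSums(h$p), rep(1, 16))
  # uniform directions: each quantile near 1/12 (3 sigma binomial)
  n_in <- mean(h$n)
  tol <- 3 * sqrt((1 / 12) * (11 / 12) / n_in)
  expect_true(all(abs(h$p - 1 / 12) < tol))
  # all directions at 0 deg concentrate in bin 1
  d0 <- data.frame(time_s = d$time_s, theta_deg = 0)
  h0 <- direction_histograms(d0, t_start = 0, t_end = 90)
  expect_true(all(h0$p[, 1] == 1))
  expect_true(all(h0$p[, -1] == 0))
})

test_that("fixation density uses a strict threshold and counts epochs", {
  mk <- function(pvals) list(epoch_time_s = seq_along(pvals),
                             p = t(vapply(pvals, function(x)
                               c(x / 2, rep((1 - x) / 10, 5), x / 2,
                                 rep((1 - x) / 10, 5)), numeric(12))),
                             n = rep(10, length(pvals)))
  expect_equal(fixation_density(mk(rep(1, 5))), 1)
  # exactly uniform epochs (P = 1/6) do not count
  u <- list(epoch_time_s = 1:4, p = matrix(1 / 12, 4, 12), n = rep(12, 4))
  expect_equal(fixation_density(u), 0)
  expect_equal(fixation_density(mk(c(0.5, 0.5, 0.5, 0.5, 0.1, 0.1, 0.1,
                                     0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1,
                                     0.1, 0.1))), 4 / 16)
  expect_error(fixation_density(list(p = matrix(NA_real_, 2, 12))),
               "undefined")
})

test_that("performance index and memory duration are simple arithmetic", {
  expect_equal(performance_index(0.5, 0.3), 0.2)
  expect_equal(performance_index(0.4, 0.4), 0)
  expect_equal(memory_duration(0.20, 120), 24)
})

test_that("radar pairing averages opposed quantiles", {
  p <- rep(1 / 12, 12)
  p[4] <- 0.4; p[10] <- 0.2
  p[-c(4, 10)] <- (1 - 0.6) / 10
  r <- radar_profile(p)
  expect_equal(unname(r["90"]), 0.3)
  expect_equal(sum(radar_profile(rep(1 / 12, 12))), 6 / 12)
  p2 <- rep(0, 12); p2[1] <- 0.5; p2[7] <- 0.5
  expect_equal(unname(radar_profile(p2)), c(0.5, 0, 0, 0, 0, 0))
})

test_that("closed-form fixation geometry matches the grid oracle", {
  # all mass on the 0/180 pair: exact axis and full strength
  p <- rep(0, 12); p[1] <- 0.5; p[7] <- 0.5
  fg <- fixation_geometry(p)
  expect_equal(fg$sigma_f_deg, 0)
  expect_equal(fg$FS, 1)
  expect_equal(fg$M_min, 0)
  # exactly uniform: isotropic, FS 0, sigma undefined
  fg <- fixation_geometry(rep(1 / 12, 12))
  expect_true(fg$isotropic)
  expect_equal(fg$FS, 0)
  expect_true(is.na(fg$sigma_f_deg))
  # random histograms against the brute-force grid minimization
  H <- random_histograms(200, seed = 42)
  for (i in seq_len(nrow(H))) {
    fg <- fixation_geometry(H[i, ])
    or <- grid_fixation_oracle(H[i, ], step_deg = 0.01)
    expect_lt(axial_diff(fg$sigma_f_deg, or$sigma_f_deg), 0.5)
    expect_lt(abs(fg$FS - or$FS), 1e-6)
  }
})

test_that("fixation geometry invariances hold", {
  H <- random_histograms(25, seed = 7)
  for (i in seq_len(nrow(H))) {
    fg <- fixation_geometry(H[i, ])
    # scale invariance
    fg2 <- fixation_geometry(3.7 * H[i, ])
    expect_equal(fg2$FS, fg$FS, tolerance = 1e-12)
    expect_equal(fg2$sigma_f_deg, fg$sigma_f_deg, tolerance = 1e-9)
    # rotating the histogram by 30 deg (one bin) shifts sigma_f by 30
    rot <- H[i, c(12, 1:11)]
    fg3 <- fixation_geometry(rot)
    expect_lt(axial_diff(fg3$sigma_f_deg, fg$sigma_f_deg + 30), 1e-6)
    expect_equal(fg3$FS, fg$FS, tolerance = 1e-9)
  }
})

test_that("the FS criterion and classification follow the control stats", {
  expect_equal(fs_criterion(0.0544, 0.0273), 0.109)
  expect_false(classify_fixation(0.0544))
  expect_false(classify_fixation(0.1090))  # strict inequality
  expect_true(classify_fixation(0.5))
})

test_that("locomotion metrics separate duty cycle from speed", {
  # stationary track
  tk <- fly_track(seq(0, 1, 0.05), rep(0, 21), rep(0, 21),
                  stage = rep("pre", 21))
  lm0 <- locomotion_metrics(tk)
  expect_equal(lm0$activity_pct, 0)
  expect_true(is.na(lm0$speed_mm_s))
  # constant 10 mm/s walk at 20 fps
  tt <- seq(0, 2, 0.05)
  tk <- fly_track(tt, 10 * tt, rep(0, length(tt)),
                  stage = rep("pre", length(tt)))
  lm1 <- locomotion_metrics(tk)
  expect_equal(lm1$activity_pct, 100)
  expect_equal(lm1$speed_mm_s, 10, tolerance = 1e-9)
  # half the frames moving at 8 mm/s
  x <- cumsum(rep(c(8 * 0.05, 0), 40))
  tk <- fly_track(seq(0, by = 0.05, length.out = 81), c(0, x),
                  rep(0, 81), stage = rep("pre", 81))
  lm2 <- locomotion_metrics(tk)
  expect_equal(lm2$activity_pct, 50)
  expect_equal(lm2$speed_mm_s, 8, tolerance = 1e-9)
})

test_that("escape rate is a guarded percentage", {
  expect_equal(escape_rate(3, 4), 75)
  expect_equal(escape_rate(0, 10), 0)
  expect_equal(escape_rate(5, 5), 100)
  expect_error(escape_rate(1, 0))
  expect_error(escape_rate(5, 4))
})

test_that("track rotation equivariance of the fixation pipeline", {
  p <- synthetic_fly_params(fixation_bias = 1, seed = 11,
                            schedule = c(pre = 60))
  tk <- synth_track(p)
  geo <- arena_geometry()
  rot <- 40
  tk2 <- tk
  th <- rot * pi / 180
  tk2$x_mm <- cos(th) * tk$x_mm - sin(th) * tk$y_mm
  tk2$y_mm <- sin(th) * tk$x_mm + cos(th) * tk$y_mm
  pool <- function(t) {
    d <- movement_directions(t, geo)
    tabulate(ringmem:::direction_bin(d$theta_deg), 12) / nrow(d)
  }
  f1 <- fixation_geometry(pool(tk))
  # rotating the track about the center rotates the fixation axis; FS is
  # only approximately preserved because directions are re-binned
  d2 <- movement_directions(tk2, geo)
  d2$theta_deg <- (d2$theta_deg - rot) %% 360
  f2 <- fixation_geometry(tabulate(ringmem:::direction_bin(d2$theta_deg),
                                   12) / nrow(d2))
  expect_lt(axial_diff(f1$sigma_f_deg, f2$sigma_f_deg), 1e-6)
  expect_equal(f1$FS, f2$FS, tolerance = 1e-9)
})
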