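test_that("rate profiles count and conserve spikes", {
  # 10 spikes of one unit in wedge 0 within one 100 ms bin
  sp <- data.frame(neuron_id = rep(0L, 10), time_ms = seq(1, 99, length.out = 10))
  wedge_of <- c(0L, rep(NA_integer_, 77))
  rp <- rate_profile(sp, wedge_of, duration_ms = 100, bin_ms = 100)
  expect_equal(rp$rates[1, 1], 100)
  # empty record is an all-zero profile, not an error
  rp0 <- rate_profile(sp[0, ], wedge_of, duration_ms = 500)
  expect_true(all(rp0$rates == 0))
  # conservation over random spikes
  set.seed(2)
  sp2 <- data.frame(neuron_id = sample(0:17, 500, TRUE),
                    time_ms = runif(500, 0, 2000))
  rp2 <- rate_profile(sp2, 0:17, duration_ms = 2000, bin_ms = 100)
  expect_equal(sum(rp2$rates) * 0.1, 500)
})

test_that("bump detection matches its definition on constructed profiles", {
  v <- vm_profile(190, kappa = 3, peak = 40)
  d <- detect_bump(v)
  expect_true(d$present)
  expect_lt(abs(d$position_deg - 190), 1)
  # uniform activity: no localized peak
  expect_false(detect_bump(rep(20, 18))$present)
  # two equal antipodal peaks fail contiguity
  v2 <- vm_profile(90, 4, 40) + vm_profile(270, 4, 40)
  expect_false(detect_bump(v2)$present)
  # subthreshold peak
  expect_false(detect_bump(vm_profile(90, 3, 4))$present)
  # all-zero
  expect_false(detect_bump(rep(0, 18))$present)
})

test_that("bump detection equals the exhaustive arc-search oracle", {
  set.seed(5)
  for (i in 1:150) {
    v <- switch(1 + i %% 4,
                vm_profile(runif(1, 0, 360), runif(1, 0.5, 6),
                           runif(1, 3, 60)),
                pmax(rnorm(18, 10, 8), 0),
                vm_profile(runif(1, 0, 360), 3, 30) + rnorm(18, 0, 3),
                rep(runif(1, 0, 30), 18) + rnorm(18, 0, 0.5))
    v <- pmax(v, 0)
    got <- detect_bump(v)
    ora <- ringmem:::detect_bump_oracle(v)
    expect_identical(got$present, ora$present)
    if (got$present)
      expect_lt(abs(((got$position_deg - ora$position_deg + 180) %% 360) -
                      180), 1e-9)
  }
})

test_that("FWHM recovers analytic widths and is invariant", {
  # wrapped-Gaussian-like profile: sigma 0.5 rad gives 2*sqrt(2 ln 2)*sigma
  centers <- wedge_center_deg(0:17) * pi / 180
  g <- 40 * exp(-0.5 * ((pmin(abs(centers - pi),
                              2 * pi - abs(centers - pi))) / 0.5)^2)
  prof <- structure(list(rates = matrix(rep(g, 10), 18, 10),
                         bin_ms = 100, time_s = (1:10) / 10 - 0.05,
                         wedge_center_deg = wedge_center_deg(0:17),
                         units_per_wedge = 1L),
                    class = "rate_profile")
  # linear interpolation between 20-degree wedge centers carries up to
  # about half a wedge of discretization error
  expect_equal(bump_fwhm(prof), 2 * sqrt(2 * log(2)) * 0.5,
               tolerance = 0.08)
  # rectangular profile spanning 6 wedges
  r <- rep(0, 18); r[6:11] <- 30
  prof$rates <- matrix(rep(r, 10), 18, 10)
  expect_equal(bump_fwhm(prof), 2 * pi / 3, tolerance = 1e-6)
  # rotation and uniform scaling leave FWHM unchanged
  v <- vm_profile(100, 2.2, 35)
  mk <- function(x) {
    prof$rates <- matrix(rep(x, 10), 18, 10); prof
  }
  f0 <- bump_fwhm(mk(v))
  expect_equal(bump_fwhm(mk(v[c(7:18, 1:6)])), f0, tolerance = 1e-9)
  expect_equal(bump_fwhm(mk(3 * v)), f0, tolerance = 1e-9)
  # absent bump: undefined metric
  expect_error(bump_fwhm(mk(rep(1, 18))), "undefined")
})

test_that("heading-bump deviation unwraps and flags losses", {
  n <- 100
  tm <- (1:n) / 10
  mkbump <- function(pos, present = rep(TRUE, n))
    data.frame(time_s = tm, present = present,
               position_deg = pos, amplitude_hz = 30)
  # perfectly tracking: zero deviation (no smoothing to keep it exact)
  heading <- (1:n) * 4
  d <- heading_bump_deviation(mkbump(heading %% 360), heading,
                              smooth_ms = 0)
  expect_equal(max(abs(d$deviation_deg)), 0, tolerance = 1e-9)
  expect_false(d$lost)
  # bump fixed while heading rotates a full turn: final deviation 360
  heading2 <- seq(0, 360, length.out = n)
  d2 <- heading_bump_deviation(mkbump(rep(90, n)), heading2, smooth_ms = 0)
  expect_equal(d2$deviation_deg[n], 360, tolerance = 1e-6)
  # counter-rotating convention: bump at -heading tracks with sign -1
  d3 <- heading_bump_deviation(mkbump((-heading) %% 360), heading,
                               bump_sign = -1, smooth_ms = 0)
  expect_equal(max(abs(d3$deviation_deg)), 0, tolerance = 1e-9)
  # mid-trace loss: deviation reported up to loss, flagged
  pres <- rep(TRUE, n); pres[41:n] <- FALSE
  d4 <- heading_bump_deviation(mkbump(heading %% 360, pres), heading,
                               smooth_ms = 0)
  expect_true(d4$lost)
  expect_true(all(is.na(d4$deviation_deg[41:n])))
  expect_error(heading_bump_deviation(mkbump(heading, c(FALSE, rep(TRUE, n - 1))),
                                      heading), "absent")
})

test_that("a common offset of both angle traces leaves deviation unchanged", {
  set.seed(3)
  n <- 80
  heading <- cumsum(rnorm(n, 0, 12))
  bump <- heading + rnorm(n, 0, 5)
  mk <- function(b, h) heading_bump_deviation(
    data.frame(time_s = (1:n) / 10, present = TRUE,
               position_deg = b %% 360, amplitude_hz = 20),
    h, smooth_ms = 0)
  d1 <- mk(bump, heading)
  d2 <- mk(bump + 77, heading + 77)
  expect_equal(d1$deviation_deg, d2$deviation_deg, tolerance = 1e-6)
})

test_that("bump loss fraction counts sustained absences", {
  n <- 100
  mk <- function(pres) data.frame(time_s = (1:n) / 10, present = pres,
                                  position_deg = 0, amplitude_hz = 10)
  keep <- mk(rep(TRUE, n))
  short_gap <- mk(c(rep(TRUE, 50), rep(FALSE, 10), rep(TRUE, 40)))  # 1 s gap
  long_gap <- mk(c(rep(TRUE, 50), rep(FALSE, 25), rep(TRUE, 25)))   # 2.5 s
  expect_equal(bump_loss_fraction(list(keep, keep)), 0)
  expect_equal(bump_loss_fraction(list(keep, short_gap)), 0)
  expect_equal(bump_loss_fraction(list(keep, keep, keep, long_gap)), 25)
  expect_error(bump_loss_fraction(list()))
})
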