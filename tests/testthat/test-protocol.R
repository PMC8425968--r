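test_that("protocol specs compute their manipulation windows", {
  expect_null(protocol_spec("wildtype")$manipulation_window_s)
  expect_equal(protocol_spec("eip_photo_stim")$manipulation_window_s,
               c(30, 60))
  expect_equal(protocol_spec("p_photo_post")$manipulation_window_s,
               c(80, 90))
  expect_equal(protocol_spec("p_photo_stim", stim_s = 90)$manipulation_window_s,
               c(60, 90))
  expect_error(protocol_spec("nonsense"))
})

test_that("trial schedules respect stage and gating bookkeeping", {
  cfg <- ringmem_config()
  net <- build_network(lif = cfg$lif, kinetics = cfg$kinetics,
                       gains = cfg$gains, seed = 9)
  proto <- protocol_spec("eip_photo_post", stim_s = 12, post_s = 36)
  beh <- generate_behavior(48, cfg$markov, seed = 4)
  sched <- build_trial_schedule(net, proto, beh, cfg)
  cur <- as.data.frame(sched$current)
  poi <- as.data.frame(sched$poisson)
  ring_c <- pop_ids(net, "RingC")
  ring_p <- pop_ids(net, "RingP")
  ring_e <- pop_ids(net, "RingEIP")
  # photoactivation stays inside its window (20-30 s of the post stage)
  photo <- cur[cur$neuron %in% ring_e & cur$i_na == cfg$currents$photoactivation_na, ]
  expect_true(all(photo$t_on >= 32000 & photo$t_off <= 42000))
  # full-gate drives alternate exclusively with the behavior state
  c_full <- cur[cur$neuron %in% ring_c & cur$i_na == cfg$ring_gate_current_na, ]
  p_full <- cur[cur$neuron %in% ring_p & cur$i_na == cfg$ring_gate_current_na, ]
  overlap <- function(a, b)
    any(outer(a$t_on, b$t_off, `<`) & outer(a$t_off, b$t_on, `>`))
  expect_false(overlap(c_full, p_full))
  # every step is covered by exactly one of the two full gates
  steps <- seq(0, 47.7, by = 0.3) * 1000
  covered <- vapply(steps + 1, function(t)
    any(c_full$t_on <= t & c_full$t_off > t) ||
      any(p_full$t_on <= t & p_full$t_off > t), logical(1))
  expect_true(all(covered))
  # the partial P-ring drive coincides with C-ring (rotation) windows only
  p_part <- cur[cur$neuron %in% ring_p & cur$i_na == cfg$ring_gate_partial_na, ]
  expect_true(all(vapply(seq_len(nrow(p_part)), function(i)
    any(c_full$t_on <= p_part$t_on[i] & c_full$t_off >= p_part$t_off[i]),
    logical(1))))
  # visual input confined to the stimulus stage
  eip_ids <- pop_ids(net, "EIP")
  vis <- poi[!(poi$neuron %in% eip_ids) & poi$rate_hz == cfg$visual$rate_hz, ]
  expect_true(all(vis$t_off <= 12000))
  # rotation input only during rotation steps, one side at a time
  rot <- poi[poi$rate_hz == cfg$rotation$rate_hz, ]
  pen_l <- pop_ids(net, "PEN", side = "left")
  pen_r <- pop_ids(net, "PEN", side = "right")
  for (i in seq_len(nrow(rot))) {
    step <- floor(rot$t_on[i] / 300) + 1
    expect_equal(as.character(beh$state[step]), "rotation")
    side_expected <- if (beh$rotation_direction[step] > 0) pen_l else pen_r
    expect_true(rot$neuron[i] %in% side_expected)
  }
})

test_that("short batches run deterministically and summarize", {
  proto <- protocol_spec("wildtype", stim_s = 6, post_s = 6, n_trials = 2,
                        seed = 77)
  b1 <- run_condition_batch(proto)
  b2 <- run_condition_batch(proto)
  expect_equal(b1$summary, b2$summary)
  expect_equal(nrow(b1$summary), 2L)
  expect_true(all(c("present_stim", "present_post", "fwhm_rad",
                    "bump_lost") %in% names(b1$summary)))
  # distinct trial seeds
  expect_equal(length(unique(b1$summary$seed)), 2L)
})

test_that("run_trial produces aligned traces and configuration echo", {
  tr <- run_trial(protocol_spec("wildtype", stim_s = 8, post_s = 8),
                  seed = 5)
  expect_s3_class(tr, "trial_record")
  expect_equal(nrow(tr$bump), ncol(tr$profile$rates))
  expect_equal(length(tr$heading_at_bins_deg), nrow(tr$bump))
  expect_equal(tr$condition, "wildtype")
  expect_equal(tr$bump_sign, -1)
  m <- trial_metrics(tr)
  expect_true(is.finite(m$present_stim) && is.finite(m$present_post))
})

test_that("config round-trips through structured text", {
  cfg <- ringmem_config()
  path <- tempfile(fileext = ".json")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$gains, cfg$gains)
  expect_equal(back$lif, cfg$lif)
  expect_equal(back$kinetics$tau_ms, cfg$kinetics$tau_ms)
  expect_equal(back$markov$p_fr, cfg$markov$p_fr)
  expect_equal(back$rotation, cfg$rotation)
})

test_that("tracks and spikes round-trip through delimited text", {
  p <- synthetic_fly_params(seed = 2, schedule = c(pre = 5, stim = 5,
                                                   post = 5))
  tk <- synth_track(p)
  path <- tempfile(fileext = ".tsv")
  write_track(tk, path)
  back <- read_track(path, schedule = c(pre = 5, stim = 5, post = 5))
  expect_equal(back$x_mm, tk$x_mm, tolerance = 1e-9)
  expect_equal(as.character(back$stage), as.character(tk$stage))
  # missing stage column: stages assigned from the schedule
  d <- utils::read.table(path, header = TRUE)
  write.table(d[, c("time_s", "x_mm", "y_mm")], path, row.names = FALSE)
  back2 <- read_track(path, schedule = c(pre = 5, stim = 5, post = 5))
  expect_equal(as.character(back2$stage), as.character(tk$stage))
})
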