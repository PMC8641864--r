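test_that("short-term plasticity updates obey their bounds and algebra", {
  up <- stp_spike_update(u = 0.2, x = 1, U = 0.2)
  expect_equal(up$u, 0.36)
  expect_equal(up$efficacy, 0.36)
  expect_equal(up$x, 0.64)
  # repeated spikes keep u in (0, 1] and x in [0, 1]
  u <- 0.2; x <- 1
  for (i in 1:50) {
    s <- stp_spike_update(u, x, 0.2)
    u <- s$u; x <- s$x
    expect_true(u > 0 && u <= 1)
    expect_true(x >= 0 && x <= 1)
  }
})

test_that("the simulator is quiescent without input and seed-deterministic", {
  sp <- ring_spec("bump", 64, 16, mu_bg_e = 0, mu_bg_i = 0, noise_sd = 0)
  pr <- stimulus_protocol(cue_strength = 0, drive_strength = 0, duration = 0.5,
                          cue_window = c(0.1, 0.2), drive_window = c(0.3, 0.4))
  r <- simulate_trial(sp, pr, seed = 1)
  expect_length(r$time, 0)
  sp2 <- ring_spec("silent", 64, 16)
  pr2 <- stimulus_protocol(duration = 1.0, cue_window = c(0.1, 0.3),
                           drive_window = c(0.5, 0.7), drive_strength = 2)
  a <- simulate_trial(sp2, pr2, seed = 42)
  b <- simulate_trial(sp2, pr2, seed = 42)
  expect_identical(a$time, b$time)
  expect_identical(a$neuron, b$neuron)
  batch1 <- run_condition(sp2, pr2, 3, seed = 5)
  batch2 <- run_condition(sp2, pr2, 3, seed = 5)
  expect_identical(lapply(batch1, `[[`, "time"),
                   lapply(batch2, `[[`, "time"))
  # recorded synaptic state stays within the update-rule bounds
  expect_true(all(a$stp$u_cue > 0 & a$stp$u_cue <= 1))
  expect_true(all(a$stp$x_cue >= 0 & a$stp$x_cue <= 1))
})

test_that("fano factor is 1 for poisson spikes and 0 for clock spikes", {
  pr <- poisson_records(200, rate = 10, n_exc = 32, duration = 2)
  ff <- fano_timecourse(pr, baseline = c(0.2, 1.2))
  expect_equal(mean(ff$ff), 1, tolerance = 0.1)
  expect_equal(mean(ff$dff[ff$time >= 0.2 & ff$time <= 1.2]), 0,
               tolerance = 0.02)
  # perfectly regular spiking, window an integer multiple of the period
  clock <- fake_records(function(i) {
    tt <- rep(seq(0.025, 2, by = 0.05), each = 32)
    list(neuron = rep(1:32, times = 40), time = tt)
  }, n_trials = 20)
  ffc <- fano_timecourse(clock, window = 0.1, baseline = c(0.2, 1.2))
  expect_equal(max(ffc$ff), 0, tolerance = 1e-12)
  expect_error(fano_timecourse(pr[1:5]), ">= 10 trials")
})

test_that("population-vector tuning behaves at its extremes", {
  one <- fake_records(function(i)
    list(neuron = rep(17L, 30), time = runif(30, 0, 2)), 5)
  ts1 <- tuning_strength(one, c(0, 2))
  expect_equal(ts1$strength, rep(1, 5), tolerance = 1e-12)
  expect_equal(ts1$decoded_angle, rep(360 * 16 / 32, 5), tolerance = 1e-9)
  unif <- fake_records(function(i)
    list(neuron = rep(1:32, each = 4), time = runif(128, 0, 2)), 5)
  expect_lt(max(tuning_strength(unif, c(0, 2))$strength), 1e-9)
  silent <- fake_records(function(i) list(neuron = integer(), time = numeric()), 3)
  ts0 <- tuning_strength(silent, c(0, 2))
  expect_equal(ts0$strength, rep(0, 3))
  expect_true(all(is.na(ts0$decoded_angle)))
})

test_that("a cued bump persists and its drift variance grows with the delay", {
  sp <- ring_spec("bump", 256, 64)
  pr <- stimulus_protocol(drive_strength = 0, duration = 3.0,
                          drive_window = c(2.6, 2.8))
  rec <- run_condition(sp, pr, 25, seed = 77)
  angs <- sapply(c(1.0, 2.0, 2.9), function(tc) {
    ts <- tuning_strength(rec, c(tc - 0.4, tc))
    ts$decoded_angle
  })
  err <- abs(((angs - 180 + 180) %% 360) - 180)
  # persistence: decoded angle within 30 degrees of the cue for >= 2 s
  expect_gte(mean(err[, 3] < 30, na.rm = TRUE), 0.9)
  # diffusion: across-trial dispersion of the decoded angle grows over time
  spread <- apply(err, 2, function(e) mean(e^2, na.rm = TRUE))
  expect_gt(spread[3], spread[1])
})

test_that("silent regime maintains a synaptic trace and reactivates all-or-none", {
  sp <- ring_spec("silent", 256, 64)
  pr <- stimulus_protocol(drive_strength = 1.5)
  rec <- run_condition(sp, pr, 20, seed = 88)
  # activity decays to near baseline in the delay...
  delay_rate <- mean(tuning_strength(rec, c(1.5, 2.5))$mean_rate)
  expect_lt(delay_rate, 1)
  # ...while u*x at cue-adjacent synapses stays above the ring average
  # throughout the delay (the silent trace)
  for (r in rec[1:5]) {
    s <- r$stp[r$stp$time >= 1.0 & r$stp$time <= 2.5, ]
    expect_true(all(s$ux_cue > s$ux_all))
  }
  det <- detect_reactivation(rec)
  expect_true(all(det$quiet))
  # reactivated trials point at the cue
  if (any(det$reactivated))
    expect_lt(mean(det$angle_error, na.rm = TRUE), 45)
  # no drive, no reactivations
  rec0 <- run_condition(sp, stimulus_protocol(drive_strength = 0), 10,
                        seed = 89)
  expect_equal(detect_reactivation(rec0)$fraction, 0)
})
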