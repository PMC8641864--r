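test_that("gamma waveform is peak-normalized at the analytic mode", {
  t <- seq(0, 2, by = 1e-4)
  for (ab in list(c(2, 0.130), c(3, 0.080), c(1.5, 0.2), c(5, 0.05))) {
    w <- gamma_waveform(t, ab[1], ab[2])
    expect_equal(max(w), 1, tolerance = 1e-9)
    expect_equal(t[which.max(w)], (ab[1] - 1) * ab[2], tolerance = 2e-4)
  }
  expect_identical(gamma_waveform(0, 2, 0.1), 0)
  # raw variant is the unnormalized kernel
  expect_equal(gamma_waveform(0.3, 2, 0.1, normalize = FALSE),
               0.3 * exp(-3))
  expect_error(gamma_waveform(t, 1, 0.1), "> 1")
  expect_error(gamma_waveform(t, 2, -1), "> 0")
  expect_error(gamma_waveform(-1, 2, 0.1), ">= 0")
})

test_that("lead field constructors honor their contracts", {
  lf <- make_leadfield("two-dipole-default", n_channels = 17)
  expect_equal(dim(lf$matrix), c(2, 17))
  expect_true(all(colSums(abs(lf$matrix)) > 0))
  ro1 <- make_leadfield("random-orthogonal", n_channels = 8, seed = 4)
  ro2 <- make_leadfield("random-orthogonal", n_channels = 8, seed = 4)
  expect_identical(ro1$matrix, ro2$matrix)
  expect_equal(rowSums(ro1$matrix^2), rep(1, 2), tolerance = 1e-12)
  expect_error(make_leadfield(n_channels = 1), ">= 2")
})

test_that("impulse-window noise reduction matches the configured fraction", {
  nm <- noise_model(sigma_base = 0.75, reduction_fraction = 0.3)
  expect_equal(nm$sigma_impulse, 0.525)
  # empirical variance ratio with waveform scale 0 approximates (1 - r)^2
  wp0 <- waveform_params(scale = 0)
  e <- simulate_condition_trials(1000, wp = wp0, noise = nm,
                                 lf = make_leadfield(n_channels = 2),
                                 duration = 2.0, srate = 100, seed = 21)
  tt <- time_axis(e)
  v_in <- var(as.vector(e$data[, , tt >= 1.3 & tt <= 1.5]))
  v_out <- var(as.vector(e$data[, , tt >= 0.3 & tt <= 1.2]))
  expect_equal(v_in / v_out, 0.49, tolerance = 0.05 * 0.49)
})

test_that("generators are seed-deterministic and label-sane", {
  lf <- make_leadfield(n_channels = 3)
  a <- simulate_condition_trials(6, lf = lf, srate = 50, seed = 9)
  b <- simulate_condition_trials(6, lf = lf, srate = 50, seed = 9)
  expect_identical(a$data, b$data)
  expect_identical(a$trial_meta, b$trial_meta)
  o <- simulate_oriented_trials(24, 6, lf = lf,
                                srate = 50, duration = 1.6,
                                noise = noise_model(impulse_window = c(1.2, 1.4)),
                                seed = 2)
  expect_true(all(o$trial_meta$orientation >= 0 &
                    o$trial_meta$orientation < 180))
  expect_equal(length(unique(o$trial_meta$orientation)), 6)
  expect_error(simulate_condition_trials(0, lf = lf), ">= 1")
  expect_error(simulate_oriented_trials(10, 3, lf = lf), ">= 4")
})

test_that("noiseless projection is linear in the source amplitudes", {
  lf <- make_leadfield(n_channels = 5)
  nm <- noise_model(sigma_base = 1e-12)  # effectively noiseless
  wp <- waveform_params(sigma_a = 0, sigma_b = 0, scale = 0.5)
  wp2 <- waveform_params(sigma_a = 0, sigma_b = 0, scale = 1.5)
  e1 <- simulate_condition_trials(2, wp = wp, noise = nm, lf = lf,
                                  duration = 2.0, srate = 100, seed = 1)
  e3 <- simulate_condition_trials(2, wp = wp2, noise = nm, lf = lf,
                                  duration = 2.0, srate = 100, seed = 1)
  expect_lt(max(abs(e3$data - 3 * e1$data)), 1e-9)
  # deterministic limit: zero noise, zero parameter spread -> identical trials
  expect_lt(max(abs(e1$data[1, , ] - e1$data[2, , ])), 1e-9)
})

test_that("epoch sets round-trip through the plain-text serialization", {
  e <- tiny_epochs(3, 2, 10)
  dir <- withr::local_tempdir()
  write_epoch_set(e, dir)
  e2 <- read_epoch_set(dir)
  expect_equal(e2$data, e$data, tolerance = 1e-12)
  expect_equal(e2$srate, e$srate)
  expect_equal(e2$trial_meta$orientation, e$trial_meta$orientation)
})
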