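test_that("across-trial variance is flat for stationary noise and zero for clones", {
  set.seed(1)
  e <- tiny_epochs(200, 2, 40, fill = NULL, seed = 1)
  e$data[] <- rnorm(length(e$data), 0, 2)
  v <- across_trial_variance(e)
  expect_equal(mean(v$var), 4, tolerance = 0.15)
  expect_lt(sd(v$var) / mean(v$var), 0.2)
  dup <- tiny_epochs(4, 2, 30, fill = rep(1:60, each = 4))
  expect_equal(max(abs(across_trial_variance(dup, detrend = FALSE)$var)), 0)
  expect_error(across_trial_variance(tiny_epochs(1, 2, 10)), "single trial")
})

test_that("delta_var is the percent change from baseline and scale-free", {
  tmv <- seq(0, 1.99, by = 0.01)
  base <- rep(2, length(tmv))
  vv <- structure(list(var = rbind(base, base), time = tmv,
                       sessions = c("a", "b")),
                  class = "variance_timecourse")
  vv$var[, tmv >= 1.5] <- 4                 # variance doubles late
  dv <- delta_var(vv, c(0.2, 1.0))
  expect_equal(mean(dv$dvar[, tmv >= 1.6]), 100, tolerance = 1e-9)
  expect_equal(mean(dv$dvar[, tmv < 1.4]), 0, tolerance = 1e-9)
  # invariance under global voltage scaling (variance x 9)
  vv9 <- vv; vv9$var <- 9 * vv9$var
  dv9 <- delta_var(vv9, c(0.2, 1.0))
  expect_equal(dv9$dvar, dv$dvar, tolerance = 1e-9)
  bad <- vv; bad$var[1, ] <- -1
  expect_error(delta_var(bad, c(0.2, 1.0)), "non-positive")
})

test_that("per-session variance averaging differs from pooled variance", {
  # sessions with different means: pooling would inflate variance
  set.seed(2)
  mk <- function(mu, ses) {
    d <- array(rnorm(50 * 1 * 20, mu, 1), c(50, 1, 20))
    epoch_set(d, 100, trial_meta = data.frame(orientation = rep(0, 50),
                                              session = rep(ses, 50)))
  }
  e <- bind_epochs(list(mk(0, "a"), mk(10, "b")))
  v <- across_trial_variance(e, detrend = FALSE)
  expect_equal(mean(v$var), 1, tolerance = 0.15)   # per-session, then average
  pooled <- mean(apply(e$data, c(2, 3), var))      # ignores session structure
  expect_gt(pooled, 20)
})

test_that("decoding-based trial split recovers a planted variance coupling", {
  set.seed(3)
  n <- 120; ns <- 4
  sets <- lapply(1:ns, function(s) {
    sdv <- sample(rep(c(0.5, 1.5), each = n / 2))   # per-trial noise level
    d <- array(rnorm(n * 2 * 30) * rep(sdv, 2 * 30), c(n, 2, 30))
    list(e = epoch_set(d, 100,
                       trial_meta = data.frame(orientation = rep(0, n),
                                               session = rep(paste0("s", s),
                                                             n))),
         strength = -sdv + rnorm(n, 0, 0.1))  # low-noise trials decode better
  })
  e <- bind_epochs(lapply(sets, `[[`, "e"))
  strengths <- lapply(sets, function(x) matrix(x$strength, ncol = 1))
  vs <- variance_by_decoding_split(e, strengths, t_ref = 1)
  expect_gt(mean(vs$diff), 0)              # var(low decoding) > var(high)
  expect_true(any(vs$p < 0.005))
  # random strengths: difference straddles zero
  rnd <- lapply(sets, function(x) matrix(rnorm(n), ncol = 1))
  vs0 <- variance_by_decoding_split(e, rnd, t_ref = 1)
  expect_gt(mean(abs(vs0$tstat) < 3), 0.9)
  const <- lapply(sets, function(x) matrix(1, n, 1))
  expect_error(variance_by_decoding_split(e, const, t_ref = 1), "degenerate")
})

test_that("outlier-session screening excludes exactly the planted sessions", {
  set.seed(4)
  v <- structure(list(var = matrix(rnorm(20 * 5, 10, 0.5), 20),
                      time = 1:5, sessions = paste0("s", 1:20)),
                 class = "variance_timecourse")
  out <- exclude_outlier_sessions(v, impulse_time = 3, criterion = 5)
  expect_length(out$excluded, 0)
  v$var[c(2, 7), 3] <- 10 + 5 * 10 * mad(v$var[, 3])  # far beyond threshold
  out2 <- exclude_outlier_sessions(v, impulse_time = 3, criterion = 5)
  expect_setequal(out2$excluded, c("s2", "s7"))
  expect_equal(sum(out2$keep), 18)
})
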