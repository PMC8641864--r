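# a decoding_timecourse-shaped object built directly from numbers, so the
# inference machinery can be tested against known distributions
fake_dt <- function(strength, time, trial_strength = NULL) {
  structure(list(strength = strength, time = time,
                 sessions = paste0("s", seq_len(nrow(strength))),
                 trial_strength = trial_strength,
                 n_folds = 8, params = list()),
            class = "decoding_timecourse")
}

test_that("window test handles degenerate, strong and null inputs", {
  tmv <- seq(0.1, 1, by = 0.1)
  z <- fake_dt(matrix(0, 6, 10), tmv)
  wt <- window_test(z, c(0.2, 0.5))
  expect_identical(wt$t, 0)
  expect_identical(wt$p, 0.5)
  set.seed(1)
  s <- fake_dt(matrix(rnorm(30 * 10, 0.5, 0.1), 30), tmv)
  expect_lt(window_test(s, c(0.1, 1))$p, 1e-6)
  # calibration: null rejection close to nominal alpha
  set.seed(2)
  rej <- mean(replicate(1000, {
    window_test(fake_dt(matrix(rnorm(8 * 4), 8), tmv[1:4]),
                c(0.1, 0.4))$p < 0.05
  }))
  expect_gt(rej, 0.03); expect_lt(rej, 0.07)
  expect_error(window_test(z, c(5, 6)), "no decoded time points")
})

test_that("subsample grid corner reproduces the pooled test and trends hold", {
  set.seed(3)
  tab <- data.frame(session = rep(paste0("s", 1:6), each = 40),
                    value = rnorm(240, 0.3, 1))
  g <- subsample_grid(tab, c(3, 6), c(60, 240), n_resamples = 50, seed = 4)
  pooled <- pingwm:::one_sided_t(tab$value)
  expect_equal(g$stat[2, 2], pooled$mean, tolerance = 1e-12)
  expect_equal(g$pvals[2, 2], pooled$p, tolerance = 1e-12)
  expect_true(is.na(g$pvals[1, 2]))      # infeasible cell
  # in expectation, p decreases with more trials (positive effect)
  expect_lt(g$pvals[2, 2], g$pvals[2, 1])
  expect_error(subsample_grid(tab, c(3, 9), c(10, 20), 10, 1), "sessions")
  expect_error(subsample_grid(tab, 3, 500, 10, 1), "available")
})

test_that("bootstrap CI is degenerate for constants and covers the mean", {
  b <- bootstrap_ci(rep(2.5, 12), n_boot = 200, seed = 1)
  expect_equal(b$ci_low, 2.5)
  expect_equal(b$ci_high, 2.5)
  expect_equal(b$sem, 0)
  set.seed(5)
  b2 <- bootstrap_ci(rnorm(30, 1, 0.1), n_boot = 2000, seed = 2)
  expect_gt(b2$ci_low, 0)                 # clearly excludes zero
  expect_equal(b2$sem, 0.1 / sqrt(30), tolerance = 0.3)
  # coverage calibration
  set.seed(6)
  cover <- mean(replicate(400, {
    ci <- bootstrap_ci(rnorm(25, 1, 1), n_boot = 200)
    ci$ci_low <= 1 && 1 <= ci$ci_high
  }))
  expect_gt(cover, 0.90); expect_lt(cover, 0.99)
  expect_warning(bootstrap_ci(rnorm(5), n_boot = 50), "unstable")
})

test_that("randomization test follows the add-one permutation rule", {
  tmv <- seq(0.1, 0.5, by = 0.1)
  obs <- fake_dt(matrix(1, 2, 5), tmv)
  null <- structure(list(strengths = matrix(rep(seq(-1, 0.8, length.out = 999),
                                                5), 999),
                         time = tmv, n_shuffles = 999),
                    class = "shuffle_null")
  rt <- randomization_test(obs, null, c(0.1, 0.5))
  expect_equal(rt$p, 1 / 1000)
  # observed at the null median gives p near 0.5
  obs2 <- fake_dt(matrix(median(null$strengths[, 1]), 2, 5), tmv)
  expect_equal(randomization_test(obs2, null, c(0.1, 0.5))$p, 0.5,
               tolerance = 0.01)
  # invariance under common monotone rescaling
  f <- function(x) tanh(x / 2)
  obs3 <- obs; obs3$strength <- f(obs3$strength)
  null3 <- null; null3$strengths <- f(null3$strengths)
  expect_equal(randomization_test(obs3, null3, c(0.1, 0.5))$p, rt$p)
  bad <- null; bad$time <- tmv + 1
  expect_error(randomization_test(obs, bad, c(0.1, 0.5)), "time axes")
})

test_that("median split is unbiased on exchangeable data and finds planted effects", {
  tmv <- seq(0.1, 1, by = 0.1)
  mk <- function(shift) lapply(1:8, function(s)
    matrix(rnorm(32 * 10, ifelse(s <= 4, shift, 0)), 32))
  set.seed(8)
  shufs <- lapply(1:20, function(i) mk(0))
  null <- median_split_cv(mk(0), tmv, split_window = c(0.2, 0.45),
                          n_splitfolds = 400, shuffle_strengths = shufs,
                          n_shuffle_folds = 50, seed = 9)
  expect_gt(mean(null$frac_above), 0.40)
  expect_lt(mean(null$frac_above), 0.60)
  expect_false(any(null$significant))
  planted <- median_split_cv(mk(0.6), tmv, split_window = c(0.2, 0.45),
                             n_splitfolds = 400, shuffle_strengths = shufs,
                             n_shuffle_folds = 50, seed = 10)
  expect_gt(mean(planted$high_sessions[, 1:4]), 0.9)
  expect_true(all(planted$significant))
  # reproducible under seed even for a single split-fold
  acc <- mk(0)
  a <- median_split_cv(acc, tmv, n_splitfolds = 1, seed = 3)
  b <- median_split_cv(acc, tmv, n_splitfolds = 1, seed = 3)
  expect_identical(a$high, b$high)
  expect_error(median_split_cv(mk(0)[1:3], tmv), ">= 4 sessions")
})
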