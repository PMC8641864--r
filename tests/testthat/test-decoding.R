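test_that("vector strength follows the -cos convention", {
  for (K in c(3, 4, 6, 8)) {
    bins <- 360 * (0:(K - 1)) / K
    expect_equal(vector_strength(-cos(bins * pi / 180), bins), 0.5,
                 tolerance = 1e-12)
    expect_equal(vector_strength(cos(bins * pi / 180), bins), -0.5,
                 tolerance = 1e-12)
    expect_equal(vector_strength(rep(3, K), bins), 0, tolerance = 1e-12)
  }
  expect_error(vector_strength(1, 0), ">= 2 bins")
})

test_that("RDF separates well-separated classes and is flat under permutation", {
  set.seed(11)
  lab <- rep(180 * (0:3) / 4, each = 24)
  mu <- 4 * cbind(cos(2 * lab * pi / 180), sin(2 * lab * pi / 180))
  X <- cbind(mu, matrix(0, 96, 2)) + matrix(rnorm(96 * 4), 96)
  r <- mahalanobis_rdf(X, lab, n_folds = 4)
  own <- r$dist[cbind(1:96, r$cls_idx)]
  expect_gt(mean(own == apply(r$dist, 1, min)), 0.95)
  expect_gt(mean(vector_strength(r$profile, r$bins)), 0.5)
  # permuted labels: mean profile within monte-carlo range of zero
  set.seed(12)
  perm <- sample(lab)
  rp <- mahalanobis_rdf(X, perm, n_folds = 4)
  st <- vector_strength(rp$profile, rp$bins)
  expect_lt(abs(mean(st)), 3 * sd(st) / sqrt(length(st)) + 0.05)
  expect_error(mahalanobis_rdf(X[c(1:5, 25:29), ], lab[c(1:5, 25:29)],
                               n_folds = 8), "n_folds")
  expect_error(mahalanobis_rdf(X, rep(0, 96), n_folds = 4), "distinct")
})

test_that("RDF profiles are invariant under invertible channel mixing", {
  set.seed(13)
  K <- 8; lab <- rep(180 * (0:(K - 1)) / K, each = 12)
  mu <- cbind(cos(2 * lab * pi / 180), sin(2 * lab * pi / 180)) %*%
    matrix(rnorm(12), 2)
  X <- mu + matrix(rnorm(length(lab) * 6), length(lab))
  A <- matrix(rnorm(36), 6) + 2 * diag(6)
  set.seed(7); r1 <- mahalanobis_rdf(X, lab, n_folds = 4, shrinkage = 0)
  set.seed(7); r2 <- mahalanobis_rdf(X %*% A, lab, n_folds = 4, shrinkage = 0)
  expect_lt(max(abs(r1$profile - r2$profile)), 1e-6)
})

test_that("decoding strength tracks tuning gain and the null is centered", {
  lf <- make_leadfield(n_channels = 6)
  nm <- noise_model(impulse_window = c(0.6, 0.7))
  mk <- function(gain, seed) simulate_oriented_trials(
    96, 8, tuning_gain = gain, noise = nm, lf = lf, duration = 0.8,
    srate = 100, seed = seed)
  times <- c(0.2, 0.25, 0.3)
  means <- sapply(c(0, 1, 3), function(g)
    mean(decode_timecourse(mk(g, 31), times = times, seed = 1,
                           keep_trials = FALSE)$strength))
  expect_true(all(diff(means) > 0))      # nondecreasing in gain
  expect_lt(abs(means[1]), 0.06)         # null near zero
  expect_gt(means[3], 0.3)               # strong signal decodable
  # deterministic under seed
  d1 <- decode_timecourse(mk(1, 5), times = times, seed = 3)
  d2 <- decode_timecourse(mk(1, 5), times = times, seed = 3)
  expect_identical(d1$strength, d2$strength)
  expect_error(decode_timecourse(mk(1, 5), channels = "nope", times = times),
               "available")
})

test_that("alpha-power front end decodes an amplitude-modulated tuned signal", {
  # 10 Hz carrier whose amplitude carries the circular code
  srate <- 125; tt <- seq(0, 1.2, by = 1 / srate)
  K <- 4; ntr <- 64
  ori <- rep(180 * (0:(K - 1)) / K, length.out = ntr)
  set.seed(17)
  dat <- array(0, c(ntr, 4, length(tt)))
  code <- cbind(1.5 + cos(2 * ori * pi / 180), 1.5 + sin(2 * ori * pi / 180))
  mix <- matrix(c(1, 0.4, 0.2, 0.8, 0.3, 1, 0.7, 0.1), 2)
  for (i in seq_len(ntr)) {
    src <- rbind(code[i, 1] * sin(2 * pi * 10 * tt),
                 code[i, 2] * sin(2 * pi * 10 * tt + 1))
    dat[i, , ] <- t(mix) %*% src + matrix(rnorm(4 * length(tt), 0, 0.4),
                                          4)
  }
  e <- epoch_set(dat, srate, trial_meta = data.frame(orientation = ori))
  dt <- decode_timecourse(e, signal = "alpha", times = c(0.5, 0.6, 0.7),
                          n_folds = 4, seed = 2, keep_trials = FALSE)
  expect_gt(mean(dt$strength), 0.1)
})

test_that("shuffle null is centered, gain-invariant and reproducible", {
  lf <- make_leadfield(n_channels = 6)
  nm <- noise_model(impulse_window = c(0.6, 0.7))
  e <- simulate_oriented_trials(96, 8, tuning_gain = 2, noise = nm, lf = lf,
                                duration = 0.8, srate = 100, seed = 41)
  times <- c(0.2, 0.25, 0.3)
  sn <- shuffle_null(e, 30, seed = 6, times = times, keep_trials = FALSE)
  expect_lt(abs(mean(sn$strengths)),
            2 * sd(rowMeans(sn$strengths)) / sqrt(30) + 0.02)
  sn2 <- shuffle_null(e, 30, seed = 6, times = times, keep_trials = FALSE)
  expect_identical(sn$strengths, sn2$strengths)
  # permutation destroys the label coupling: null distribution comparable
  # for strong-gain and zero-gain data
  e0 <- simulate_oriented_trials(96, 8, tuning_gain = 0, noise = nm, lf = lf,
                                 duration = 0.8, srate = 100, seed = 41)
  sn0 <- shuffle_null(e0, 30, seed = 6, times = times, keep_trials = FALSE)
  ks <- suppressWarnings(ks.test(as.vector(sn$strengths),
                                 as.vector(sn0$strengths)))
  expect_gt(ks$p.value, 0.01)
})
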