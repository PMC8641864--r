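#' Baseline-correct an epoch set
#'
#' Subtracts, per trial and channel, the mean voltage over `window` from the
#' whole epoch. Baselining is idempotent (the window mean of an already
#' baselined epoch is zero). Note that baselining during a delay period can
#' manufacture spurious decodability increases when across-trial variance
#' later drops; see the methods vignette.
#'
#' @param e an [epoch_set()].
#' @param window numeric length-2 `(start, end)` in seconds, inside the epoch.
#' @return a baselined `epoch_set`.
#' @export
apply_baseline <- function(e, window) {
  idx <- window_indices(e, window)
  if (length(idx) == 0) stop("baseline window contains no samples")
  bl <- apply(e$data[, , idx, drop = FALSE], c(1, 2), mean)
  e$data <- e$data - array(bl, dim(e$data))
  e
}

# sample indices covered by a time window (inclusive)
window_indices <- function(e, window) {
  if (length(window) != 2L || window[1] >= window[2])
    stop("`window` must be (start, end) with start < end")
  tt <- time_axis(e)
  if (window[1] < tt[1] - 1e-9 || window[2] > tt[length(tt)] + 1e-9)
    stop(sprintf("window [%g, %g] s outside epoch [%g, %g] s",
                 window[1], window[2], tt[1], tt[length(tt)]))
  which(tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9)
}

#' Stitch consecutive epochs, reverting per-epoch baselining
#'
#' Given two epochs of the same trials where `epoch_b` temporally follows
#' `epoch_a` but was independently baselined, computes the trial-by-trial,
#' channel-by-channel voltage offset between the end of `epoch_a` and the
#' start of `epoch_b`, adds it back to `epoch_b`, and returns the
#' concatenated continuous epoch. If the first sample of `epoch_b` coincides
#' in time with the last sample of `epoch_a` (one-sample overlap) the offset
#' is exact and the duplicate sample is dropped; if the epochs merely abut,
#' the offset uses the junction difference, which assumes continuity of the
#' underlying trace across one sample step.
#'
#' @param epoch_a,epoch_b [epoch_set()] objects with identical trials,
#'   channels and sampling rate.
#' @return the stitched `epoch_set` starting at `epoch_a$t0`.
#' @export
debaseline_stitch <- function(epoch_a, epoch_b) {
  if (n_trials(epoch_a) != n_trials(epoch_b) ||
      n_channels(epoch_a) != n_channels(epoch_b))
    stop("epochs differ in trials or channels")
  if (epoch_a$srate != epoch_b$srate) stop("sampling rates differ")
  if (n_samples(epoch_b) < 1) stop("`epoch_b` has no samples")
  ta_end <- time_axis(epoch_a)[n_samples(epoch_a)]
  dtol <- 0.5 / epoch_a$srate
  overlap <- abs(epoch_b$t0 - ta_end) < dtol
  abut <- abs(epoch_b$t0 - (ta_end + 1 / epoch_a$srate)) < dtol
  if (!overlap && !abut)
    stop("`epoch_b` must start at or one sample after the end of `epoch_a`")
  last_a <- epoch_a$data[, , n_samples(epoch_a)]
  first_b <- epoch_b$data[, , 1]
  offset <- last_a - first_b
  b <- epoch_b$data + array(offset, dim(epoch_b$data))
  keep <- if (overlap) seq.int(2L, n_samples(epoch_b)) else
    seq_len(n_samples(epoch_b))
  if (length(keep) == 0) stop("`epoch_b` must extend beyond the overlap sample")
  dat <- array(0, c(n_trials(epoch_a), n_channels(epoch_a),
                    n_samples(epoch_a) + length(keep)))
  dat[, , seq_len(n_samples(epoch_a))] <- epoch_a$data
  dat[, , n_samples(epoch_a) + seq_along(keep)] <- b[, , keep, drop = FALSE]
  epoch_set(dat, epoch_a$srate, epoch_a$t0, epoch_a$channel_labels,
            epoch_a$trial_meta)
}

#' Remove a least-squares linear trend
#'
#' Fits and subtracts a straight line from each time series (drift from e.g.
#' moving electrodes). With `preserve_mean = TRUE` only the slope is removed
#' and the series mean is kept, which is the variant used inside the
#' across-trial variance pipeline where the absolute variance level is the
#' quantity of interest.
#'
#' @param x numeric vector, or matrix with time in columns (each row a
#'   series).
#' @param preserve_mean keep the series mean (remove slope only)?
#' @return same shape as `x`.
#' @export
detrend_linear <- function(x, preserve_mean = FALSE) {
  if (is.vector(x)) return(drop(detrend_linear(matrix(x, 1), preserve_mean)))
  n <- ncol(x)
  if (n < 2) stop("need >= 2 samples to detrend")
  tc <- seq_len(n) - (n + 1) / 2                 # centered time
  denom <- sum(tc^2)
  slope <- (x %*% tc) / denom                    # per-row LS slope
  fit <- slope %*% rbind(tc)
  if (!preserve_mean) fit <- fit + rowMeans(x)
  x - fit
}

#' Gaussian temporal smoothing
#'
#' Convolves each trial/channel time series with a unit-area Gaussian kernel
#' of standard deviation `sigma` seconds (truncated at 6 sigma), using
#' reflection padding at the edges. `sigma = 0` is the identity. Two standard
#' uses: smoothing voltage traces before decoding (sigma = 32 ms) to improve
#' signal-to-noise, and smoothing decoding-strength time courses afterwards
#' (sigma = 10 ms).
#'
#' @param x an [epoch_set()], or a numeric vector/matrix (time in columns)
#'   with `srate` supplied.
#' @param sigma kernel s.d. in seconds (>= 0).
#' @param srate sampling rate in Hz (taken from `x` when it is an epoch set).
#' @return same type as `x`.
#' @export
smooth_gaussian <- function(x, sigma, srate = NULL) {
  if (sigma < 0) stop("`sigma` must be >= 0")
  if (inherits(x, "epoch_set")) {
    if (sigma == 0) return(x)
    d <- dim(x$data)
    m <- matrix(aperm(x$data, c(3, 1, 2)), nrow = d[3])  # samples x (trial*ch)
    sm <- gauss_smooth_mat(t(m), sigma * x$srate)
    x$data <- aperm(array(t(sm), c(d[3], d[1], d[2])), c(2, 3, 1))
    return(x)
  }
  if (is.null(srate)) stop("`srate` required for plain numeric input")
  if (sigma == 0) return(x)
  if (is.vector(x)) return(drop(gauss_smooth_mat(matrix(x, 1), sigma * srate)))
  gauss_smooth_mat(x, sigma * srate)
}

# rows = series, columns = time; sigma in samples; reflection padding
gauss_smooth_mat <- function(x, sigma_samp) {
  n <- ncol(x)
  r <- max(1L, ceiling(6 * sigma_samp))
  k <- stats::dnorm(seq(-r, r), sd = sigma_samp)
  k <- k / sum(k)
  pre <- x[, pmin(pmax(seq.int(r + 1, 2), 1), n), drop = FALSE]
  post <- x[, pmax(pmin(seq.int(n - 1, n - r), n), 1), drop = FALSE]
  xp <- cbind(pre, x, post)
  out <- matrix(0, nrow(x), n)
  for (i in seq_len(nrow(x)))
    out[i, ] <- stats::filter(xp[i, ], k, sides = 2)[r + seq_len(n)]
  out
}

#' Alpha-band total power via the Hilbert analytic signal
#'
#' Band-pass filters each trial/channel trace to `band` (zero-phase FIR,
#' forward-backward), forms the analytic signal with the Hilbert transform and
#' returns its squared complex magnitude, i.e. the total power of the band.
#' The default band is the 8-12 Hz alpha band. The filter's half-width in
#' samples is attached as attribute `"edge_samples"`; power estimates within
#' that margin of either epoch edge are distorted by filter transients and
#' should be excluded from inference.
#'
#' @param e an [epoch_set()].
#' @param band numeric length-2 `(low, high)` Hz, with
#'   `0 < low < high < srate/2`.
#' @param order FIR filter order (even; default scales with `srate/low`).
#' @return an `epoch_set` in power units (squared voltage), with attribute
#'   `edge_samples`.
#' @export
alpha_power <- function(e, band = c(8, 12), order = NULL) {
  ny <- e$srate / 2
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2] ||
      band[2] >= ny)
    stop("`band` must satisfy 0 < low < high < srate/2 (Nyquist ", ny, " Hz)")
  if (is.null(order)) order <- 2L * ceiling(1.5 * e$srate / band[1])
  if (order %% 2L) order <- order + 1L
  if (order + 2L > n_samples(e))
    stop("epoch too short for the band-pass filter (order ", order, ")")
  b <- signal::fir1(order, band / ny, type = "pass")
  d <- dim(e$data)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    xf <- signal::filtfilt(b, e$data[i, j, ])
    out[i, j, ] <- Mod(analytic_signal(xf))^2
  }
  e$data <- out
  attr(e, "edge_samples") <- order %/% 2L
  e
}

# FFT-based analytic signal (one-sided spectrum doubling)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}
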