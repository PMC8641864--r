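#' Ring-network specification
#'
#' Parameters of the leaky integrate-and-fire ring network. Excitatory and
#' inhibitory neurons are spatially distributed on a ring so that nearby
#' excitatory neurons (similar preferred angles) have stronger-than-average
#' connections: the E-to-E kernel is a Gaussian over angular distance with
#' s.d. `ee_sigma` radians, normalized so its ring mean is 1 (total recurrent
#' strength `g_ee` is then independent of the kernel width). All other
#' connection classes (E-to-I, I-to-E, I-to-I) are all-to-all and untuned.
#' Optional short-term plasticity on excitatory synapses follows the standard
#' two-variable facilitation/depression scheme: on every presynaptic spike
#' `u <- u + U * (1 - u)`, the released efficacy is `u * x`, and
#' `x <- x - u * x`; between spikes `u` relaxes to `U` with `stp_tau_f` and
#' `x` to 1 with `stp_tau_d`.
#'
#' Two presets define the package's study regimes:
#' `"bump"` (no plasticity, strong recurrence: a cued activity bump persists
#' through the delay and a nonspecific drive boosts its tuning) and
#' `"silent"` (plasticity enabled, recurrence insufficient for persistent
#' activity: the cue leaves a silent synaptic trace from which a nonspecific
#' drive can reignite the bump in an all-or-none fashion). The default sizes
#' (2048 excitatory, 512 inhibitory) can be scaled down (the test suite uses
#' 512/128) without changing the qualitative contrasts.
#'
#' @param preset `"bump"` or `"silent"`.
#' @param n_exc,n_inh population sizes.
#' @param ... named overrides of any spec field (see Details / defaults in
#'   the returned list).
#' @return a `ring_spec` list.
#' @export
ring_spec <- function(preset = c("bump", "silent"), n_exc = 2048, n_inh = 512,
                      ...) {
  preset <- match.arg(preset)
  base <- list(
    n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
    dt = 1e-4,
    tau_m_e = 0.020, tau_m_i = 0.010,          # membrane time constants (s)
    v_th = 20, v_reset = 0, t_ref = 0.002,     # threshold/reset (mV), refractory
    tau_si = 0.005,                            # inhibitory current decay (s)
    noise_sd = 30,                             # white-noise current (mV s^-1/2)
    max_rate = 500,                            # divergence guard (Hz/neuron)
    preset = preset)
  if (preset == "bump") {
    # slow (NMDA-like) recurrent excitation stabilizes a persistent bump at
    # moderate rates, close enough to the bifurcation that a nonspecific
    # drive visibly deepens (boosts) the attractor
    reg <- list(stp_enabled = FALSE, stp_U = 0.2, stp_tau_f = 3, stp_tau_d = 0.25,
                tau_se = 0.08, ee_sigma = 0.5,
                g_ee = 9, g_ie = 40, g_ei = 70, g_ii = 15,
                mu_bg_e = 15, mu_bg_i = 4)
  } else {
    # strong but depressing recurrence: the cued bump collapses after the
    # cue (x depletion), leaving a facilitated u*x trace; recurrence is too
    # weak to reignite spontaneously but a weak nonspecific drive can,
    # stochastically and all-or-none
    reg <- list(stp_enabled = TRUE, stp_U = 0.2, stp_tau_f = 3, stp_tau_d = 0.25,
                tau_se = 0.03, ee_sigma = 0.35,
                g_ee = 90, g_ie = 200, g_ei = 100, g_ii = 15,
                mu_bg_e = 9, mu_bg_i = 4)
  }
  spec <- utils::modifyList(c(base, reg), list(...))
  stopifnot(spec$n_exc >= 1, spec$n_inh >= 1, spec$dt > 0,
            spec$stp_U > 0, spec$stp_U <= 1)
  structure(spec, class = "ring_spec")
}

#' Stimulus protocol for a ring-network trial
#'
#' A trial consists of a tuned cue (Gaussian current profile centered on
#' `cue_angle`) followed, after a delay, by a nonspecific drive delivered
#' uniformly to all excitatory neurons (the "ping").
#'
#' @param cue_angle cue direction in degrees on `[0, 360)`.
#' @param cue_strength peak cue current (mV).
#' @param cue_window `(start, end)` seconds.
#' @param cue_width Gaussian s.d. of the cue profile (degrees).
#' @param drive_strength nonspecific drive current to all excitatory
#'   neurons (mV); 0 disables the ping.
#' @param drive_window `(start, end)` seconds.
#' @param duration trial length (s).
#' @return a `stimulus_protocol` list.
#' @export
stimulus_protocol <- function(cue_angle = 180, cue_strength = 18,
                              cue_window = c(0.25, 0.5), cue_width = 25,
                              drive_strength = 0,
                              drive_window = c(2.5, 3.0), duration = 3.5) {
  stopifnot(cue_angle >= 0, cue_angle < 360,
            cue_window[1] < cue_window[2], drive_window[1] < drive_window[2],
            cue_window[2] <= duration, drive_window[2] <= duration)
  structure(list(cue_angle = cue_angle, cue_strength = cue_strength,
                 cue_window = as.numeric(cue_window), cue_width = cue_width,
                 drive_strength = drive_strength,
                 drive_window = as.numeric(drive_window),
                 duration = duration),
            class = "stimulus_protocol")
}

#' Short-term plasticity spike update
#'
#' The presynaptic update applied on each excitatory spike: facilitation
#' first (`u <- u + U * (1 - u)`), then release of efficacy `u * x`, then
#' depression (`x <- x - u * x`). From rest (`u = U`, `x = 1`) with
#' `U = 0.2`, a single spike leaves `u = 0.36`.
#'
#' @param u,x presynaptic variables before the spike.
#' @param U baseline release increment in `(0, 1]`.
#' @return list with updated `u`, `x` and the released `efficacy`.
#' @export
stp_spike_update <- function(u, x, U) {
  stopifnot(U > 0, U <= 1)
  u2 <- u + U * (1 - u)
  eff <- u2 * x
  list(u = u2, x = x - eff, efficacy = eff)
}

#' Simulate one trial of the ring network
#'
#' Euler integration (fixed step `spec$dt`, default 0.1 ms) of the LIF ring
#' with seed-controlled Gaussian background noise. Returns all spikes plus a
#' 10-ms-resolution recording of the synaptic-trace state (mean `u * x` over
#' cue-adjacent neurons and over the whole ring), which is how silent
#' maintenance is observed when no neuron is firing.
#'
#' @param spec a [ring_spec()].
#' @param proto a [stimulus_protocol()].
#' @param seed integer seed (fully determines the trial).
#' @return a `spike_record`: list with `neuron`, `time` (excitatory spikes),
#'   `neuron_inh`, `time_inh`, `stp` (data.frame of recorded synaptic state),
#'   `spec`, `proto`, `seed`.
#' @export
simulate_trial <- function(spec, proto, seed = 1) {
  out <- .lif_ring_cpp(unclass(spec), unclass(proto), as.integer(seed))
  structure(list(neuron = out$neuron, time = out$time,
                 neuron_inh = out$neuron_inh, time_inh = out$time_inh,
                 stp = data.frame(time = out$stp_time,
                                  ux_cue = out$stp_ux_cue,
                                  ux_all = out$stp_ux_all,
                                  u_cue = out$stp_u_cue,
                                  x_cue = out$stp_x_cue),
                 spec = spec, proto = proto, seed = seed),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("<spike_record> %d E spikes, %d I spikes over %.2f s (%s)\n",
              length(x$time), length(x$time_inh), x$proto$duration,
              x$spec$preset))
  invisible(x)
}

#' Run a batch of trials
#'
#' Per-trial seeds are derived deterministically from the master seed, so the
#' same master seed reproduces the identical batch.
#'
#' @param spec a [ring_spec()]; @param proto a [stimulus_protocol()].
#' @param n_trials number of trials.
#' @param seed master seed.
#' @return list of `spike_record`.
#' @export
run_condition <- function(spec, proto, n_trials, seed = 1) {
  lapply(seq_len(n_trials), function(k)
    simulate_trial(spec, proto, derive_seed(seed, k)))
}

# excitatory spike counts per neuron in [w1, w2), per trial -> neurons x trials
count_window <- function(records, window, n_exc) {
  vapply(records, function(r) {
    keep <- r$time >= window[1] & r$time < window[2]
    tabulate(r$neuron[keep], nbins = n_exc)
  }, numeric(n_exc))
}

# half-window binned counts: list over trials of neurons x bins matrices;
# a sliding window of width `window` stepped by window/2 is then the sum of
# two adjacent bins
fano_bins <- function(records, window, duration, n_exc) {
  half <- window / 2
  n_bins <- floor(duration / half)
  lapply(records, function(r) {
    b <- pmin(floor(r$time / half) + 1L, n_bins)
    m <- matrix(0L, n_exc, n_bins)
    idx <- (b - 1L) * n_exc + r$neuron
    tab <- tabulate(idx, nbins = n_exc * n_bins)
    m[] <- tab
    m
  })
}

# Fano factor per window from binned counts, for a trial subset `idx`;
# returns the neuron-averaged FF per window (NA where no neuron fires)
fano_from_bins <- function(bins, idx) {
  n_bins <- ncol(bins[[1]])
  n_win <- n_bins - 1L
  n_exc <- nrow(bins[[1]])
  n <- length(idx)
  s1 <- matrix(0, n_exc, n_win)
  s2 <- matrix(0, n_exc, n_win)
  for (i in idx) {
    w <- bins[[i]][, 1:n_win, drop = FALSE] +
      bins[[i]][, 2:n_bins, drop = FALSE]
    s1 <- s1 + w
    s2 <- s2 + w^2
  }
  m <- s1 / n
  v <- (s2 - n * m^2) / (n - 1)
  ffn <- ifelse(m > 0, v / m, NA)
  list(ff = colMeans(ffn, na.rm = TRUE),
       n_neurons = colSums(!is.na(ffn)))
}

#' Fano-factor time course
#'
#' For each sliding window (width `window`, default 100 ms, stepped by half a
#' window), computes per excitatory neuron the variance of spike counts
#' across trials divided by their mean, then averages over neurons with
#' nonzero mean count. `dff` is the difference relative to the mean Fano
#' factor in `baseline` (conventionally the delay period preceding the
#' nonspecific drive).
#'
#' @param records list of [simulate_trial()] spike records (>= 10 trials).
#' @param window window width in seconds (default 0.1).
#' @param baseline `(start, end)` seconds of the baseline period.
#' @return data.frame with `time` (window centers), `ff`, `dff`,
#'   `n_neurons` (neurons entering the average).
#' @export
fano_timecourse <- function(records, window = 0.1,
                            baseline = NULL) {
  if (length(records) < 10) stop("need >= 10 trials for a stable Fano factor")
  spec <- records[[1]]$spec
  dur <- records[[1]]$proto$duration
  bins <- fano_bins(records, window, dur, spec$n_exc)
  fb <- fano_from_bins(bins, seq_along(records))
  centers <- window / 2 + (seq_along(fb$ff) - 1) * window / 2
  ff <- fb$ff
  nn <- fb$n_neurons
  if (all(nn == 0)) stop("zero mean spike count in every window")
  if (is.null(baseline))
    baseline <- c(records[[1]]$proto$cue_window[2] + 0.2,
                  records[[1]]$proto$drive_window[1])
  bidx <- centers >= baseline[1] & centers <= baseline[2]
  if (!any(bidx)) stop("baseline period contains no windows")
  b <- mean(ff[bidx], na.rm = TRUE)
  data.frame(time = centers, ff = ff, dff = ff - b, n_neurons = nn)
}

#' Population-vector tuning strength
#'
#' Projects the excitatory firing-rate vector in `window` onto the ring: the
#' population vector is the rate-weighted mean of the unit vectors at each
#' neuron's preferred angle; its magnitude normalized by the summed rate is
#' the tuning strength (0 for uniform activity, 1 for activity concentrated
#' at one angle), and its argument the decoded angle.
#'
#' @param records a single `spike_record` or a list of them.
#' @param window `(start, end)` seconds.
#' @return data.frame with one row per trial: `strength`, `decoded_angle`
#'   (degrees in `[0, 360)`, `NA` when there is no activity), `mean_rate`
#'   (Hz per neuron).
#' @export
tuning_strength <- function(records, window) {
  if (inherits(records, "spike_record")) records <- list(records)
  spec <- records[[1]]$spec
  nE <- spec$n_exc
  theta <- 2 * pi * (seq_len(nE) - 1) / nE
  cnt <- count_window(records, window, nE)      # neurons x trials
  tot <- colSums(cnt)
  zx <- colSums(cnt * cos(theta))
  zy <- colSums(cnt * sin(theta))
  strength <- ifelse(tot > 0, sqrt(zx^2 + zy^2) / tot, 0)
  ang <- ifelse(tot > 0, (atan2(zy, zx) * 180 / pi) %% 360, NA_real_)
  data.frame(strength = strength, decoded_angle = ang,
             mean_rate = tot / nE / diff(window))
}

#' Detect all-or-none reactivations
#'
#' In the activity-silent regime, a nonspecific drive reignites the cued bump
#' in some trials and not others. A trial is flagged reactivated when its
#' tuned firing (tuning strength times mean excitatory rate) in the
#' post-drive `window` exceeds `threshold`. Trials whose pre-drive activity
#' already exceeds `quiet_criterion` (Hz per neuron, checked over the 0.5 s
#' preceding the drive) are reported separately since for them "reactivation"
#' is ill-defined.
#'
#' @param records list of spike records from one condition.
#' @param window post-drive evaluation window (default: drive onset to 0.5 s
#'   after it).
#' @param threshold tuned-rate threshold (Hz per neuron).
#' @param quiet_criterion maximal pre-drive mean rate (Hz per neuron).
#' @return list with `reactivated` (logical per trial), `fraction`,
#'   `tuned_rate` (per trial), `angle_error` (degrees, per reactivated
#'   trial), `quiet` (logical per trial).
#' @export
detect_reactivation <- function(records, window = NULL, threshold = 1,
                                quiet_criterion = 2) {
  proto <- records[[1]]$proto
  if (is.null(window))
    window <- c(proto$drive_window[1], proto$drive_window[1] + 0.5)
  pre <- c(max(0, proto$drive_window[1] - 0.5), proto$drive_window[1])
  ts_post <- tuning_strength(records, window)
  ts_pre <- tuning_strength(records, pre)
  tuned <- ts_post$strength * ts_post$mean_rate
  reac <- tuned > threshold
  err <- abs(((ts_post$decoded_angle - proto$cue_angle + 180) %% 360) - 180)
  list(reactivated = reac, fraction = mean(reac), tuned_rate = tuned,
       angle_error = ifelse(reac, err, NA_real_),
       quiet = ts_pre$mean_rate <= quiet_criterion)
}
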