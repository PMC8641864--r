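#' Gamma-shaped single-trial evoked waveform
#'
#' Evoked responses are modelled as a Gamma-density-shaped transient
#' \deqn{f(t \mid a, b) = e^{a-1} \, [b(a-1)]^{-(a-1)} \, t^{a-1} e^{-t/b},}
#' which is the raw kernel \eqn{t^{a-1} e^{-t/b}} normalized so that its peak
#' value is exactly 1, attained at the mode \eqn{t = (a-1)\,b}. The shape
#' parameter `a` (> 1, dimensionless) controls rise sharpness, and the time
#' constant `b` (seconds) the decay.
#'
#' @param t numeric vector of times in seconds, all `>= 0`.
#' @param a shape parameter, must be `> 1`.
#' @param b time constant in seconds, must be `> 0`.
#' @param normalize if `TRUE` (default) return the peak-normalized waveform
#'   (maximum 1 at `t = (a - 1) * b`); if `FALSE` return the raw, unnormalized
#'   kernel `t^(a-1) * exp(-t/b)`.
#' @return numeric vector of amplitudes, same length as `t`; `f(0) = 0`.
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' max(gamma_waveform(t, a = 2, b = 0.130))  # 1 at t = 0.130 s
#' @export
gamma_waveform <- function(t, a, b, normalize = TRUE) {
  if (!is.numeric(a) || length(a) != 1L || a <= 1)
    stop("`a` must be a scalar > 1")
  if (!is.numeric(b) || length(b) != 1L || b <= 0)
    stop("`b` must be a scalar > 0 (seconds)")
  if (any(t < 0)) stop("`t` must be >= 0")
  # work on the log scale: t^(a-1) overflows for large t/a otherwise
  out <- numeric(length(t))
  pos <- t > 0
  lg <- (a - 1) * log(t[pos]) - t[pos] / b
  if (normalize) lg <- lg + (a - 1) - (a - 1) * log(b * (a - 1))
  out[pos] <- exp(lg)
  out
}

#' Waveform parameter set for the condition generator
#'
#' Per-trial waveforms draw their shape `a ~ N(mu_a, sigma_a)` and time
#' constant `b ~ N(mu_b, sigma_b)` (draws with `a <= 1` or `b <= 0` are
#' rejected and redrawn), are scaled by `scale` and start at `onset` seconds.
#' The two default parameter sets, [waveform_params_conditions()], are the
#' phenomenological two-condition simulation settings: condition 1 has
#' `mu_a = 2`, `mu_b = 0.130` s, scale 0.5; condition 2 has `mu_a = 3`,
#' `mu_b = 0.080` s, scale 0.25; both with `sigma_a = 0.2`,
#' `sigma_b = 0.0005` s and onset 0.1 s.
#'
#' @param mu_a mean shape (dimensionless, > 1).
#' @param mu_b mean time constant (s, > 0).
#' @param sigma_a s.d. of the shape draw (>= 0).
#' @param sigma_b s.d. of the time-constant draw (s, >= 0).
#' @param scale amplitude multiplier applied to the unit-peak waveform.
#' @param onset waveform start time (s, >= 0) on the epoch time axis.
#' @return a `waveform_params` list.
#' @export
waveform_params <- function(mu_a = 2, mu_b = 0.130, sigma_a = 0.2,
                            sigma_b = 0.0005, scale = 0.5, onset = 0.1) {
  stopifnot(mu_a > 1, mu_b > 0, sigma_a >= 0, sigma_b >= 0,
            is.finite(scale), onset >= 0)
  structure(list(mu_a = mu_a, mu_b = mu_b, sigma_a = sigma_a,
                 sigma_b = sigma_b, scale = scale, onset = onset),
            class = "waveform_params")
}

#' @rdname waveform_params
#' @export
waveform_params_conditions <- function() {
  list(waveform_params(mu_a = 2, mu_b = 0.130, scale = 0.5),
       waveform_params(mu_a = 3, mu_b = 0.080, scale = 0.25))
}

#' Additive-noise model with an impulse-window variability reduction
#'
#' Channel noise is i.i.d. Gaussian with s.d. `sigma_base` everywhere except
#' inside `impulse_window`, where the s.d. is reduced by
#' `reduction_fraction`: effective s.d. `sigma_base * (1 - reduction_fraction)`.
#' The defaults encode a baseline s.d. of 0.75 and a 30% reduction during the
#' 1.3-1.5 s impulse window, i.e. an impulse s.d. of 0.525.
#'
#' @param sigma_base baseline noise s.d. (> 0).
#' @param impulse_window numeric length-2, `(start, end)` in seconds.
#' @param reduction_fraction fractional s.d. reduction inside the window, in
#'   `[0, 1)`.
#' @return a `noise_model` list with the derived field `sigma_impulse`.
#' @export
noise_model <- function(sigma_base = 0.75, impulse_window = c(1.3, 1.5),
                        reduction_fraction = 0.3) {
  stopifnot(sigma_base > 0, length(impulse_window) == 2L,
            impulse_window[1] < impulse_window[2],
            reduction_fraction >= 0, reduction_fraction < 1)
  structure(list(sigma_base = sigma_base,
                 impulse_window = as.numeric(impulse_window),
                 reduction_fraction = reduction_fraction,
                 sigma_impulse = sigma_base * (1 - reduction_fraction)),
            class = "noise_model")
}

#' Synthetic lead field (source-to-channel gain matrix)
#'
#' Builds the sources x channels gain matrix through which simulated dipole
#' time courses are projected to scalp channels. Two constructions:
#' `"two-dipole-default"` mimics two occipital sources whose gains fall off
#' smoothly (Gaussian) across a posterior channel row, with a small gain floor
#' so no channel is completely blind; `"random-orthogonal"` draws Gaussian
#' rows and orthonormalizes them (unit-norm rows), giving an arbitrary but
#' well-conditioned mixing.
#'
#' @param kind `"two-dipole-default"` or `"random-orthogonal"`.
#' @param n_channels number of channels (>= 2).
#' @param n_sources number of sources (rows); `"two-dipole-default"` is fixed
#'   at 2.
#' @param seed integer seed (only used by `"random-orthogonal"`).
#' @return a `lead_field` list with fields `matrix` (sources x channels),
#'   `channel_labels`, `source_descriptions`.
#' @export
make_leadfield <- function(kind = c("two-dipole-default", "random-orthogonal"),
                           n_channels = 17, n_sources = 2, seed = NULL) {
  kind <- match.arg(kind)
  if (n_channels < 2) stop("`n_channels` must be >= 2")
  labels <- paste0("P", seq_len(n_channels))
  if (kind == "two-dipole-default") {
    pos <- seq(-1, 1, length.out = n_channels)
    g1 <- exp(-(pos + 0.4)^2 / (2 * 0.35^2))
    g2 <- exp(-(pos - 0.4)^2 / (2 * 0.35^2))
    m <- rbind(g1, g2) + 0.02           # gain floor: no all-zero column
    rownames(m) <- NULL
    desc <- c("left occipital dipole (smooth posterior topography)",
              "right occipital dipole (smooth posterior topography)")
  } else {
    m <- with_seed_if(seed, {
      q <- qr.Q(qr(matrix(stats::rnorm(n_channels * n_sources), n_channels)))
      t(q[, seq_len(n_sources), drop = FALSE])
    })
    desc <- sprintf("random orthonormal source %d", seq_len(n_sources))
  }
  if (any(colSums(abs(m)) == 0)) stop("lead field has an all-zero channel column")
  structure(list(matrix = m, channel_labels = labels,
                 source_descriptions = desc),
            class = "lead_field")
}

# draw (a, b) pairs with rejection of a <= 1 or b <= 0, preserving the
# Gaussian shape of the accepted distribution
draw_ab <- function(n, wp) {
  a <- stats::rnorm(n, wp$mu_a, wp$sigma_a)
  b <- stats::rnorm(n, wp$mu_b, wp$sigma_b)
  bad <- which(a <= 1 | b <= 0)
  while (length(bad)) {
    a[bad] <- stats::rnorm(length(bad), wp$mu_a, wp$sigma_a)
    b[bad] <- stats::rnorm(length(bad), wp$mu_b, wp$sigma_b)
    bad <- bad[a[bad] <= 1 | b[bad] <= 0]
  }
  cbind(a = a, b = b)
}

# noise s.d. per sample given the impulse-window reduction
noise_sd_profile <- function(tt, noise) {
  sd <- rep(noise$sigma_base, length(tt))
  inw <- tt >= noise$impulse_window[1] & tt <= noise$impulse_window[2]
  sd[inw] <- noise$sigma_impulse
  sd
}

# core generator: per-trial source amplitude matrix (trials x sources),
# shared waveform machinery, projection, noise
simulate_epochs <- function(amp, wp_list, cond_of_trial, noise, lf, duration,
                            srate, meta) {
  n <- nrow(amp)
  ns <- ncol(amp)
  if (nrow(lf$matrix) != ns)
    stop("lead field has ", nrow(lf$matrix), " source rows; need ", ns)
  nch <- ncol(lf$matrix)
  tt <- seq(0, duration, by = 1 / srate)
  S <- length(tt)
  dat <- array(0, c(n, nch, S))
  for (i in seq_len(n)) {
    wp <- wp_list[[cond_of_trial[i]]]
    ab <- draw_ab(1, wp)
    trel <- tt - wp$onset
    w <- numeric(S)
    sup <- trel > 0
    w[sup] <- gamma_waveform(trel[sup], ab[1, "a"], ab[1, "b"]) * wp$scale
    # sources x samples signal, then project to channels
    src <- outer(amp[i, ], w)                      # ns x S
    sig <- crossprod(lf$matrix, src)               # nch x S
    sdv <- noise_sd_profile(tt, noise)
    nse <- matrix(stats::rnorm(nch * S), nch, S) *
      matrix(sdv, nch, S, byrow = TRUE)
    dat[i, , ] <- sig + nse
  }
  epoch_set(dat, srate, 0, lf$channel_labels, meta)
}

#' Simulate the two-condition synthetic EEG dataset
#'
#' Generates `n_trials` epochs per condition. Each trial draws its waveform
#' shape and time constant from the condition's Gaussian parameter
#' distributions, places the scaled unit-peak Gamma waveform at the onset,
#' assigns the same condition waveform to every dipole source, projects to
#' channels through the lead field, and adds i.i.d. Gaussian channel noise
#' whose s.d. drops by `noise$reduction_fraction` inside the impulse window.
#' The two default conditions stand for gratings at 0 and 45 degrees.
#'
#' @param n_trials trials per condition (>= 1).
#' @param wp a single [waveform_params()] (used for every condition) or a list
#'   with one per condition; default [waveform_params_conditions()].
#' @param noise a [noise_model()].
#' @param lf a [make_leadfield()] lead field.
#' @param duration epoch length in seconds (must contain onset + waveform
#'   support and the impulse window).
#' @param srate sampling rate in Hz.
#' @param seed integer seed; identical seeds give identical epoch sets.
#' @param session session label stored in `trial_meta$session`.
#' @return an [epoch_set()] with `trial_meta` columns `condition` (1-based),
#'   `orientation` (0 / 45 degrees) and `session`.
#' @export
simulate_condition_trials <- function(n_trials,
                                      wp = waveform_params_conditions(),
                                      noise = noise_model(),
                                      lf = make_leadfield(),
                                      duration = 2.8, srate = 500,
                                      seed = NULL, session = "s1") {
  if (n_trials < 1) stop("`n_trials` must be >= 1")
  if (inherits(wp, "waveform_params")) wp <- list(wp, wp)
  ncond <- length(wp)
  oris <- ((seq_len(ncond) - 1) * 45) %% 180
  if (duration < max(vapply(wp, `[[`, 0, "onset")) ||
      duration < noise$impulse_window[2])
    stop("`duration` too short for the waveform onset and impulse window")
  cond <- rep(seq_len(ncond), each = n_trials)
  meta <- data.frame(condition = cond, orientation = oris[cond],
                     session = session)
  with_seed_if(seed, {
    amp <- matrix(1, length(cond), nrow(lf$matrix))  # same waveform, all sources
    simulate_epochs(amp, wp, cond, noise, lf, duration, srate, meta)
  })
}

#' Simulate K-orientation trials with a circular tuning code
#'
#' Generalizes the two-condition generator so the full circular decoder can be
#' exercised: orientations are evenly spaced on `[0, 180)` and, because
#' orientation is a circular variable with period 180 degrees, tuning uses the
#' doubled angle. Trial source amplitudes are
#' `tuning_gain * c(cos(2 theta), sin(2 theta))` (a two-channel circular
#' code) riding on the same Gamma waveform and noise machinery; with
#' `tuning_gain = 0` the data are pure noise.
#'
#' @param n_trials total number of trials (balanced over orientations as far
#'   as divisibility allows).
#' @param n_orientations number of evenly spaced orientations (>= 4; the
#'   vector-strength summary needs at least 4 bins to be meaningful).
#' @param tuning_gain source amplitude per unit circular code.
#' @param noise,lf,duration,srate,seed,session as in
#'   [simulate_condition_trials()].
#' @param wp waveform parameters for the carrier transient (single set).
#' @return an [epoch_set()] with `trial_meta$orientation` in `[0, 180)`.
#' @export
simulate_oriented_trials <- function(n_trials, n_orientations = 8,
                                     tuning_gain = 1,
                                     noise = noise_model(),
                                     lf = make_leadfield(),
                                     duration = 2.8, srate = 500,
                                     seed = NULL, session = "s1",
                                     wp = waveform_params()) {
  if (n_orientations < 4)
    stop("`n_orientations` must be >= 4 (vector strength undefined on fewer bins)")
  if (n_trials < 1) stop("`n_trials` must be >= 1")
  if (nrow(lf$matrix) != 2)
    stop("the circular code needs a 2-source lead field")
  oris <- 180 * (seq_len(n_orientations) - 1) / n_orientations
  ori <- rep_len(oris, n_trials)
  meta <- data.frame(orientation = ori, session = session)
  th2 <- 2 * ori * pi / 180
  amp <- tuning_gain * cbind(cos(th2), sin(th2))
  with_seed_if(seed, {
    simulate_epochs(amp, list(wp), rep(1L, n_trials), noise, lf,
                    duration, srate, meta)
  })
}

#' Simulate a multi-session oriented dataset
#'
#' Convenience wrapper generating one [simulate_oriented_trials()] epoch set
#' per session with per-session tuning gains and deterministically derived
#' seeds, then concatenating trials. Used by the power / median-split demos,
#' where sessions differ in signal-to-noise.
#'
#' @param n_sessions number of sessions.
#' @param n_trials trials per session.
#' @param tuning_gains scalar or vector (one gain per session).
#' @param seed master seed.
#' @param ... passed to [simulate_oriented_trials()].
#' @return an [epoch_set()] with `trial_meta$session` in `s1..sN`.
#' @export
simulate_session_set <- function(n_sessions, n_trials, tuning_gains = 1,
                                 seed = NULL, ...) {
  gains <- rep_len(tuning_gains, n_sessions)
  sets <- lapply(seq_len(n_sessions), function(s) {
    simulate_oriented_trials(n_trials, tuning_gain = gains[s],
                             seed = derive_seed(seed, s),
                             session = paste0("s", s), ...)
  })
  bind_epochs(sets)
}

#' Concatenate epoch sets along the trial axis
#'
#' @param sets list of `epoch_set` with identical channels, srate and t0.
#' @return a single `epoch_set`.
#' @export
bind_epochs <- function(sets) {
  stopifnot(length(sets) >= 1)
  e1 <- sets[[1]]
  for (e in sets[-1])
    if (!identical(e$channel_labels, e1$channel_labels) ||
        e$srate != e1$srate || n_samples(e) != n_samples(e1))
      stop("epoch sets are not alignable (channels / srate / samples differ)")
  dat <- array(0, c(sum(vapply(sets, n_trials, 0L)), n_channels(e1),
                    n_samples(e1)))
  off <- 0L
  for (e in sets) {
    dat[off + seq_len(n_trials(e)), , ] <- e$data
    off <- off + n_trials(e)
  }
  meta <- do.call(rbind, lapply(sets, `[[`, "trial_meta"))
  rownames(meta) <- NULL
  epoch_set(dat, e1$srate, e1$t0, e1$channel_labels, meta)
}
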