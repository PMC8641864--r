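#' Across-trial variance time course
#'
#' Computes, per session, the variance across trials of the voltage traces at
#' every sensor and time point, removes a linear drift from each sensor's
#' variance time series (slope only, preserving the mean level, so that the
#' percent-change normalization of [delta_var()] remains meaningful), and
#' averages over sensors. Variances are computed for each session separately
#' and only then combined, so session-specific factors (montage, stimulus
#' set, TMS target) do not leak into the variance estimate.
#'
#' @param e an [epoch_set()]; every session needs at least 2 trials.
#' @param detrend remove the per-sensor linear drift (default `TRUE`)?
#' @return a `variance_timecourse`: list with `var` (sessions x times),
#'   `time`, `sessions`.
#' @export
across_trial_variance <- function(e, detrend = TRUE) {
  sessions <- split_sessions(e)
  tt <- time_axis(e)
  out <- matrix(0, length(sessions), n_samples(e))
  for (s in seq_along(sessions)) {
    es <- sessions[[s]]
    n <- n_trials(es)
    if (n < 2) stop("session ", names(sessions)[s], " has a single trial")
    d <- es$data
    mu <- colMeans(d)                                  # channels x samples
    v <- (colSums(d^2) - n * mu^2) / (n - 1)           # across-trial variance
    if (detrend) v <- detrend_linear(v, preserve_mean = TRUE)
    out[s, ] <- colMeans(v)                            # average over sensors
  }
  structure(list(var = out, time = tt, sessions = names(sessions)),
            class = "variance_timecourse")
}

#' Percent change of across-trial variance from baseline
#'
#' For each session, `dvar = (var - b) / b * 100` where `b` is the mean
#' variance in `baseline_window`. Referencing to a pre-impulse baseline makes
#' the measure scale-free and attributes changes to the impulse rather than
#' to factors common to the whole epoch.
#'
#' @param v a [across_trial_variance()] result.
#' @param baseline_window `(start, end)` seconds. Two conventional choices:
#'   the 0.2 s immediately before the impulse, or the full 2 s preceding it.
#' @return `v` with added fields `dvar` (sessions x times, percent) and
#'   `baseline_window`.
#' @export
delta_var <- function(v, baseline_window) {
  idx <- which(v$time >= baseline_window[1] - 1e-9 &
                 v$time <= baseline_window[2] + 1e-9)
  if (length(idx) == 0) stop("baseline window contains no samples")
  b <- rowMeans(v$var[, idx, drop = FALSE])
  if (any(b <= 0))
    stop("non-positive baseline variance after detrending (sessions: ",
         paste(v$sessions[b <= 0], collapse = ", "),
         "); inspect the variance time course or disable detrending")
  v$dvar <- sweep(sweep(v$var, 1, b), 1, b, `/`) * 100
  v$baseline_window <- baseline_window
  v
}

#' Variance difference between low- and high-decoding trials
#'
#' Splits the trials of each session at the `q` quantile of their decoding
#' strength at the time of maximal decodability `t_ref`, computes the
#' sensor-averaged across-trial variance time course of each group, and
#' returns the low-minus-high difference with a two-sided t test across
#' sessions at each time point (flagged at p < 0.005).
#'
#' @param e an [epoch_set()].
#' @param trial_strengths list per session of trials x times matrices of
#'   single-trial decoding strength (aligned to `e`'s sessions), or a
#'   `decoding_timecourse` with per-trial strengths.
#' @param t_ref time (s) of maximal decodability at which trials are ranked.
#' @param q split quantile (default 0.5, a median split).
#' @param p_threshold two-sided significance threshold (default 0.005).
#' @return list with `diff` (sessions x times, var_low - var_high), `time`,
#'   `tstat`, `p`, `significant`, `t_ref`.
#' @export
variance_by_decoding_split <- function(e, trial_strengths, t_ref, q = 0.5,
                                       p_threshold = 0.005) {
  if (inherits(trial_strengths, "decoding_timecourse")) {
    dt <- trial_strengths
    jt <- which.min(abs(dt$time - t_ref))
    strengths <- lapply(dt$trial_strength, function(m) m[, jt])
  } else {
    strengths <- lapply(trial_strengths, function(m) {
      jt <- which.min(abs(seq_len(ncol(m)) - t_ref))  # already a column index
      m[, jt]
    })
  }
  sessions <- split_sessions(e)
  if (length(strengths) != length(sessions))
    stop("trial strengths and epoch sessions differ in number")
  tt <- time_axis(e)
  dmat <- matrix(0, length(sessions), n_samples(e))
  for (s in seq_along(sessions)) {
    es <- sessions[[s]]
    st <- strengths[[s]]
    if (length(st) != n_trials(es))
      stop("session ", s, ": strengths not aligned to trials")
    if (stats::sd(st) == 0)
      stop("degenerate split: all trial strengths equal in session ", s)
    thr <- stats::quantile(st, q)
    lo <- which(st <= thr)
    hi <- which(st > thr)
    if (length(lo) < 2 || length(hi) < 2)
      stop("decoding split leaves < 2 trials in a group (session ", s, ")")
    v_lo <- across_trial_variance(es[lo, , ])$var
    v_hi <- across_trial_variance(es[hi, , ])$var
    dmat[s, ] <- v_lo - v_hi
  }
  n <- nrow(dmat)
  m <- colMeans(dmat)
  se <- apply(dmat, 2, stats::sd) / sqrt(n)
  tstat <- ifelse(se > 0, m / se, 0)
  p <- 2 * stats::pt(abs(tstat), n - 1, lower.tail = FALSE)
  list(diff = dmat, time = tt, tstat = tstat, p = p,
       significant = p < p_threshold, t_ref = t_ref)
}

#' Screen out sessions with outlier impulse-time variance
#'
#' Flags sessions whose across-trial variance at the impulse exceeds
#' `median + criterion * MAD` of the across-session distribution (a robust
#' screen for, e.g., TMS artifact variance) and returns the kept set plus a
#' report.
#'
#' @param v a [across_trial_variance()] result (all sessions).
#' @param impulse_time time (s) at which variance is screened.
#' @param criterion robust z threshold in MAD units (default 5).
#' @return list with `kept` (session names), `excluded`, `values`
#'   (per-session variance at the impulse), `threshold`, and `keep`
#'   (logical index usable on `v$var`).
#' @export
exclude_outlier_sessions <- function(v, impulse_time, criterion = 5) {
  if (nrow(v$var) < 3) stop("need >= 3 sessions to screen for outliers")
  jt <- which.min(abs(v$time - impulse_time))
  vals <- v$var[, jt]
  med <- stats::median(vals)
  madv <- stats::mad(vals)
  thr <- med + criterion * madv
  keep <- vals <= thr
  list(kept = v$sessions[keep], excluded = v$sessions[!keep],
       values = stats::setNames(vals, v$sessions), threshold = thr,
       keep = keep)
}
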