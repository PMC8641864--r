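#' One-sided window test on decoding strength
#'
#' Averages decoding strength over a time window per unit (session, or pooled
#' single trials) and tests the mean against zero with a one-sample,
#' one-sided t test. One-sided testing is the conservative choice when the
#' claim at stake is a *lack* of decoding: negative strengths are not
#' expected.
#'
#' @param dt a [decode_timecourse()] result.
#' @param window numeric `(start, end)` seconds within the time axis.
#' @param pool `"sessions"` (test across session means) or `"pooled-trials"`
#'   (test across all trials' window means, pooled over sessions).
#' @return list with `t`, `p` (one-sided, greater), `df`, `n`, `mean`,
#'   `values` (the per-unit window means).
#' @export
window_test <- function(dt, window, pool = c("sessions", "pooled-trials")) {
  pool <- match.arg(pool)
  vals <- window_values(dt, window, pool)
  one_sided_t(vals)
}

# per-unit window means from a decoding timecourse
window_values <- function(dt, window, pool) {
  idx <- which(dt$time >= window[1] - 1e-9 & dt$time <= window[2] + 1e-9)
  if (length(idx) == 0) stop("window contains no decoded time points")
  if (pool == "sessions") {
    rowMeans(dt$strength[, idx, drop = FALSE])
  } else {
    if (is.null(dt$trial_strength))
      stop("per-trial strengths not kept; rerun with keep_trials = TRUE")
    unlist(lapply(dt$trial_strength, function(m)
      rowMeans(m[, idx, drop = FALSE])), use.names = FALSE)
  }
}

one_sided_t <- function(vals) {
  n <- length(vals)
  m <- mean(vals)
  s <- stats::sd(vals)
  if (n < 2 || s == 0) {
    # degenerate data: all-zero gives the null-neutral (t = 0, p = 0.5)
    tstat <- if (isTRUE(all.equal(m, 0))) 0 else sign(m) * Inf
    return(list(t = tstat, p = stats::pt(tstat, max(n - 1, 1), lower.tail = FALSE),
                df = max(n - 1, 1), n = n, mean = m, values = vals))
  }
  tstat <- m / (s / sqrt(n))
  list(t = tstat, p = stats::pt(tstat, n - 1, lower.tail = FALSE),
       df = n - 1, n = n, mean = m, values = vals)
}

#' Decoding as a function of trial and session numbers
#'
#' Maps statistical power over a grid of session and trial counts: for every
#' cell, repeatedly (`n_resamples` times) draws that many sessions, then that
#' many trials without repetition from the pooled trials of the drawn
#' sessions, and records the mean single-trial decoding strength and the
#' one-sided t-test p value. The cell p value reported is the median over
#' resamples; at the full-data corner every resample is the complete pool, so
#' the cell reproduces the pooled [window_test()] exactly.
#'
#' @param trial_table data.frame with columns `session` and `value` (one
#'   window-mean decoding strength per trial). Build with
#'   [trial_table_from_timecourse()].
#' @param n_sessions_axis,n_trials_axis increasing integer vectors of counts.
#' @param n_resamples resamples per cell (default 5000).
#' @param seed integer seed.
#' @return a `subsample_grid`: list with `stat` and `pvals` matrices
#'   (sessions axis x trials axis), the axes, `n_resamples`, `seed`.
#' @export
subsample_grid <- function(trial_table, n_sessions_axis, n_trials_axis,
                           n_resamples = 5000, seed = NULL) {
  stopifnot(all(c("session", "value") %in% names(trial_table)))
  sess <- unique(trial_table$session)
  if (max(n_sessions_axis) > length(sess))
    stop("requested more sessions than available (", length(sess), ")")
  by_sess <- split(trial_table$value, trial_table$session)
  stat <- pv <- matrix(NA_real_,
                       length(n_sessions_axis), length(n_trials_axis),
                       dimnames = list(n_sessions_axis, n_trials_axis))
  with_seed_if(seed, {
    for (i in seq_along(n_sessions_axis)) {
      ns <- n_sessions_axis[i]
      n_avail <- min(vapply(by_sess, length, 0L)) * ns
      for (j in seq_along(n_trials_axis)) {
        nt <- n_trials_axis[j]
        if (nt > nrow(trial_table))
          stop("requested ", nt, " trials but only ", nrow(trial_table),
               " available")
        if (nt > n_avail) next       # infeasible cell at this session count
        full <- ns == length(sess) && nt == nrow(trial_table)
        reps <- if (full) 1L else n_resamples
        ms <- ps <- numeric(reps)
        for (r in seq_len(reps)) {
          pick <- sample(sess, ns)
          pool <- unlist(by_sess[as.character(pick)], use.names = FALSE)
          v <- if (nt >= length(pool)) pool else sample(pool, nt)
          tt <- one_sided_t(v)
          ms[r] <- tt$mean
          ps[r] <- tt$p
        }
        stat[i, j] <- mean(ms)
        pv[i, j] <- stats::median(ps)
      }
    }
  })
  structure(list(stat = stat, pvals = pv,
                 n_sessions_axis = n_sessions_axis,
                 n_trials_axis = n_trials_axis,
                 n_resamples = n_resamples, seed = seed),
            class = "subsample_grid")
}

#' @rdname subsample_grid
#' @param dt a [decode_timecourse()] result with per-trial strengths.
#' @param window window (s) averaged into each trial's value.
#' @export
trial_table_from_timecourse <- function(dt, window) {
  idx <- which(dt$time >= window[1] - 1e-9 & dt$time <= window[2] + 1e-9)
  if (length(idx) == 0) stop("window contains no decoded time points")
  do.call(rbind, lapply(seq_along(dt$trial_strength), function(s)
    data.frame(session = dt$sessions[s],
               value = rowMeans(dt$trial_strength[[s]][, idx, drop = FALSE]))))
}

#' Bootstrap SEM and percentile confidence interval
#'
#' Resamples units (sessions) with replacement. The SEM is the standard
#' deviation of the bootstrap means and the CI the percentile interval.
#' Accepts a vector (one value per unit) or a matrix (units x time points,
#' bootstrapped column-wise with common resampling of rows).
#'
#' @param x numeric vector or matrix (units in rows).
#' @param n_boot number of bootstrap resamples (a warning is issued below
#'   100).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return list with `mean`, `sem`, `ci_low`, `ci_high` (scalars or vectors
#'   over columns).
#' @export
bootstrap_ci <- function(x, n_boot = 5000, level = 0.95, seed = NULL) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (n < 2) stop("need >= 2 units")
  if (n_boot < 100) warning("n_boot < 100: intervals will be unstable")
  bm <- with_seed_if(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
    t(apply(idx, 1, function(ii) colMeans(x[ii, , drop = FALSE])))
  })
  if (ncol(x) == 1) bm <- matrix(bm, ncol = 1)
  a <- (1 - level) / 2
  list(mean = drop(colMeans(x)), sem = drop(apply(bm, 2, stats::sd)),
       ci_low = drop(apply(bm, 2, stats::quantile, probs = a)),
       ci_high = drop(apply(bm, 2, stats::quantile, probs = 1 - a)))
}

#' Randomization test of decoding strength against a shuffle null
#'
#' One-sided permutation p value for the window-mean decoding strength
#' against the shuffle-null distribution obtained with the identical
#' pipeline: `p = (1 + #(null >= observed)) / (1 + n_shuffles)` (the add-one
#' convention avoids p = 0 and makes the test exact under exchangeability).
#'
#' @param dt observed [decode_timecourse()] result.
#' @param null a [shuffle_null()] computed with the same parameters.
#' @param window `(start, end)` seconds.
#' @return list with `p`, `observed`, `null_values`.
#' @export
randomization_test <- function(dt, null, window) {
  if (!isTRUE(all.equal(dt$time, null$time)))
    stop("observed and null time axes differ; recompute the null with ",
         "identical pipeline parameters")
  idx <- which(dt$time >= window[1] - 1e-9 & dt$time <= window[2] + 1e-9)
  if (length(idx) == 0) stop("window contains no decoded time points")
  obs <- mean(rowMeans(dt$strength[, idx, drop = FALSE]))
  nv <- rowMeans(null$strengths[, idx, drop = FALSE])
  list(p = (1 + sum(nv >= obs)) / (1 + length(nv)),
       observed = obs, null_values = nv)
}

#' Cross-validated median split of sessions by decodability
#'
#' Selects high-decodability sessions without circularity. In each of
#' `n_splitfolds` split-folds the single-trial decoding strengths of every
#' session are randomly split in two halves (stratified by orientation when
#' labels are supplied); the first half ranks sessions by mean strength in
#' the early-delay `split_window` and a median split labels them high / low
#' (with an odd session count the high group receives the extra session);
#' the second half then supplies the held-out strength time courses of the
#' two groups. Chance level (the shuffle predictor) is the high-group
#' held-out mean obtained by the same procedure on label-shuffled decodings,
#' averaged over shuffles and `n_shuffle_folds` split-folds. The high-group
#' strength at a time point is called significant when at least
#' `criterion` (default 95%) of split-folds exceed the shuffle predictor.
#'
#' @param trial_strengths list (one element per session) of trials x times
#'   matrices of single-trial decoding strength, e.g.
#'   `dt$trial_strength` from [decode_timecourse()].
#' @param time numeric vector of the time axis (seconds).
#' @param split_window early-delay ranking window, default `c(0.25, 0.45)` s.
#' @param n_splitfolds number of random half-splits (default 2000).
#' @param labels optional list of per-session orientation labels for
#'   stratified half-splitting.
#' @param shuffle_strengths optional list over shuffles, each structured like
#'   `trial_strengths`, e.g. from [shuffle_null()] with
#'   `keep_trials = TRUE`; required for the significance criterion.
#' @param n_shuffle_folds split-folds per shuffle for the predictor
#'   (default 200).
#' @param criterion fraction of split-folds that must exceed the predictor
#'   (default 0.95).
#' @param seed integer seed.
#' @return a `median_split_result`: list with `time`, `high`, `low`
#'   (split-folds x times held-out means), `high_sessions` (split-folds x
#'   sessions logical), `shuffle_predictor` (times), `frac_above`
#'   (times), `significant` (times, logical), `split_window`, `seed`.
#' @export
median_split_cv <- function(trial_strengths, time,
                            split_window = c(0.25, 0.45),
                            n_splitfolds = 2000, labels = NULL,
                            shuffle_strengths = NULL, n_shuffle_folds = 200,
                            criterion = 0.95, seed = NULL) {
  S <- length(trial_strengths)
  if (S < 4) stop("need >= 4 sessions for a median split")
  nt <- vapply(trial_strengths, nrow, 0L)
  if (any(nt < 2)) stop("every session needs >= 2 trials")
  widx <- which(time >= split_window[1] - 1e-9 &
                  time <= split_window[2] + 1e-9)
  if (length(widx) == 0) stop("split_window contains no time points")
  res <- with_seed_if(seed, {
    main <- split_fold_means(trial_strengths, widx, n_splitfolds, labels)
    pred <- NULL
    if (!is.null(shuffle_strengths)) {
      acc <- 0
      for (sh in shuffle_strengths) {
        m <- split_fold_means(sh, widx, n_shuffle_folds, labels)
        acc <- acc + colMeans(m$high)
      }
      pred <- acc / length(shuffle_strengths)
    }
    list(main = main, pred = pred)
  })
  frac <- signif_flag <- NULL
  if (!is.null(res$pred)) {
    frac <- colMeans(sweep(res$main$high, 2, res$pred, `>`))
    signif_flag <- frac >= criterion
  }
  structure(list(time = time, high = res$main$high, low = res$main$low,
                 high_sessions = res$main$high_sessions,
                 shuffle_predictor = res$pred, frac_above = frac,
                 significant = signif_flag, split_window = split_window,
                 criterion = criterion, seed = seed),
            class = "median_split_result")
}

# one batch of split-folds: returns held-out high/low means (folds x times)
# and the high-group membership per fold
split_fold_means <- function(trial_strengths, widx, n_folds, labels) {
  S <- length(trial_strengths)
  Tn <- ncol(trial_strengths[[1]])
  high <- low <- matrix(0, n_folds, Tn)
  high_sessions <- matrix(FALSE, n_folds, S)
  n_high <- ceiling(S / 2)                 # odd count: extra session is high
  for (f in seq_len(n_folds)) {
    rank_val <- numeric(S)
    held <- matrix(0, S, Tn)
    for (s in seq_len(S)) {
      m <- trial_strengths[[s]]
      h1 <- half_split(nrow(m), if (is.null(labels)) NULL else labels[[s]])
      rank_val[s] <- mean(m[h1, widx, drop = FALSE])
      held[s, ] <- colMeans(m[-h1, , drop = FALSE])
    }
    hi <- order(rank_val, decreasing = TRUE)[seq_len(n_high)]
    high_sessions[f, hi] <- TRUE
    high[f, ] <- colMeans(held[hi, , drop = FALSE])
    low[f, ] <- colMeans(held[-hi, , drop = FALSE])
  }
  list(high = high, low = low, high_sessions = high_sessions)
}

# indices of the first half of a random half-split, optionally stratified
half_split <- function(n, labels = NULL) {
  if (is.null(labels)) return(sample.int(n, floor(n / 2)))
  idx <- unlist(lapply(split(seq_len(n), labels), function(ii)
    ii[sample.int(length(ii), floor(length(ii) / 2))]), use.names = FALSE)
  if (length(idx) == 0) idx <- sample.int(n, max(1, floor(n / 2)))
  idx
}
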