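#' Cross-validated Mahalanobis representational dissimilarity function
#'
#' For each held-out trial, computes the Mahalanobis distance between the
#' trial's feature pattern and the mean pattern of every orientation class,
#' using class means and a shrinkage-regularized pooled within-class
#' covariance estimated from the training folds only. Distances are then
#' re-indexed by the circular difference between the trial's label and each
#' class label (angles doubled onto `[0, 360)`, since orientation has period
#' 180 degrees) and mean-centered across bins, yielding a per-trial
#' representational dissimilarity function (RDF) over angular-difference bins.
#'
#' @param x numeric matrix, trials x features (e.g. selected channels at one
#'   time point).
#' @param labels orientation labels in degrees, mod 180; at least 2 distinct
#'   values, each with at least `n_folds` trials.
#' @param n_folds number of stratified cross-validation folds (default 8).
#' @param shrinkage covariance shrinkage in `[0, 1]` toward the scaled
#'   identity, or `"auto"` for the analytic Ledoit-Wolf value computed from
#'   the training residuals.
#' @param fold_id optional integer vector of pre-assigned folds (overrides the
#'   stratified assignment; mainly for reproducibility tests).
#' @return list with `profile` (trials x bins, mean-centered),
#'   `bins` (angular difference of the doubled angle, degrees in `[0, 360)`),
#'   `labels`, and `fold_id`. Fold assignment consumes the R RNG.
#' @export
mahalanobis_rdf <- function(x, labels, n_folds = 8, shrinkage = "auto",
                            fold_id = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(labels) != n) stop("length(labels) must match nrow(x)")
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need >= 2 distinct labels")
  cnt <- table(factor(labels, levels = classes))
  if (any(cnt < n_folds))
    stop("every class needs >= n_folds trials (smallest has ", min(cnt), ")")
  if (is.null(fold_id)) fold_id <- stratified_folds(labels, n_folds)
  rdf_core(x, labels, classes, fold_id, shrinkage)
}

# stratified fold assignment: shuffle within class, deal round-robin
stratified_folds <- function(labels, n_folds) {
  fold_id <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold_id[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold_id
}

# internal fast path: no argument validation
rdf_core <- function(x, labels, classes, fold_id, shrinkage) {
  n <- nrow(x)
  p <- ncol(x)
  K <- length(classes)
  cls_idx <- match(labels, classes)
  dist_mat <- matrix(0, n, K)                 # trial x class distances
  for (f in unique(fold_id)) {
    te <- which(fold_id == f)
    tr <- which(fold_id != f)
    xt <- x[tr, , drop = FALSE]
    ct <- cls_idx[tr]
    mus <- rowsum(xt, ct, reorder = TRUE) / as.vector(table(ct))
    res <- xt - mus[ct, , drop = FALSE]
    S <- crossprod(res) / (nrow(res) - K)
    lam <- if (identical(shrinkage, "auto")) lw_shrinkage(res) else shrinkage
    if (lam > 0) S <- (1 - lam) * S + lam * mean(diag(S)) * diag(p)
    R <- tryCatch(chol(S), error = function(e)
      stop("singular covariance; use shrinkage > 0 (or \"auto\")"))
    # one batched triangular solve: all held-out trials x all class means
    nte <- length(te)
    diffs <- matrix(t(x[te, , drop = FALSE])[, rep(seq_len(nte), K)],
                    p, nte * K) -
      matrix(t(mus)[, rep(seq_len(K), each = nte)], p, nte * K)
    z <- backsolve(R, diffs, transpose = TRUE)
    dist_mat[te, ] <- matrix(sqrt(colSums(z^2)), nte, K)
  }
  # re-index by doubled circular label difference and mean-center per trial
  dth <- outer(labels, classes, function(a, b) (2 * (b - a)) %% 360)
  bins <- sort(unique(round(c(dth), 6)))
  prof <- matrix(0, n, length(bins))
  bin_of <- matrix(match(round(dth, 6), round(bins, 6)), n, K)
  prof[cbind(rep(seq_len(n), K), c(bin_of))] <- c(dist_mat)
  prof <- prof - rowMeans(prof)
  list(profile = prof, bins = bins, labels = labels, fold_id = fold_id,
       dist = dist_mat, classes = classes, cls_idx = cls_idx)
}

# Ledoit-Wolf analytic shrinkage intensity toward mean(diag) * I,
# computed from (within-class) residuals
lw_shrinkage <- function(res) {
  n <- nrow(res)
  p <- ncol(res)
  S <- crossprod(res) / n
  mu <- mean(diag(S))
  d2 <- sum((S - mu * diag(p))^2)
  nrm2 <- rowSums(res^2)
  qS <- rowSums((res %*% S) * res)
  b2 <- (sum(nrm2^2) - 2 * sum(qS) + n * sum(S^2)) / n^2
  b2 <- min(max(b2, 0), d2)
  if (d2 <= 0) return(0)
  max(0, min(1, b2 / d2))
}

#' Vector strength of a representational dissimilarity function
#'
#' Summarizes an RDF over evenly spaced angular-difference bins (doubled
#' angles) as `-mean(cos(bins) * profile)`. The sign convention makes the
#' strength positive when dissimilarity grows with angular difference, i.e.
#' when the stimulus is decodable: a planted `-cos` profile gives exactly
#' +0.5.
#'
#' @param profile numeric vector (one RDF) or matrix (trials x bins).
#' @param bins angular-difference bin centers in degrees on the doubled
#'   circle, evenly spaced on `[0, 360)`.
#' @return scalar (or vector over trials) decoding strength.
#' @export
vector_strength <- function(profile, bins) {
  if (length(bins) < 2) stop("need >= 2 bins")
  w <- cos(bins * pi / 180)
  if (is.matrix(profile)) {
    if (ncol(profile) != length(bins)) stop("profile/bins mismatch")
    return(drop(-profile %*% w) / length(bins))
  }
  if (length(profile) != length(bins)) stop("profile/bins mismatch")
  -mean(w * profile)
}

# per-trial decoding strengths from an RDF fit. With only two classes the
# circular summary degenerates, and the strength is the two-class reduction
# of vector strength: cross-condition minus within-condition distance.
strength_from_rdf <- function(r) {
  if (ncol(r$dist) == 2) {
    own <- r$dist[cbind(seq_len(nrow(r$dist)), r$cls_idx)]
    return(rowSums(r$dist) - 2 * own)
  }
  vector_strength(r$profile, r$bins)
}

#' Time-resolved decoding of an epoch set
#'
#' For every session and time point, decodes the stimulus orientation from
#' the selected channels with the cross-validated Mahalanobis RDF and
#' summarizes it as vector strength, averaged over trials. Voltage can be
#' smoothed before decoding (`smooth_sigma_data`, e.g. 32 ms, the
#' statistical-power variant) and/or the resulting strength time courses
#' smoothed afterwards (`smooth_sigma_strength`, e.g. 10 ms). With exactly
#' two distinct labels the strength is the cross-minus-within condition
#' distance (see the methods vignette).
#'
#' @param e an [epoch_set()] with `trial_meta$orientation` (and optionally
#'   `$session`).
#' @param channels channel labels (or indices) to decode from; default all.
#' @param signal `"voltage"` (raw traces) or `"alpha"` (8-12 Hz total power
#'   computed with [alpha_power()] first).
#' @param smooth_sigma_data Gaussian s.d. (s) applied to the data before
#'   decoding; 0 disables.
#' @param smooth_sigma_strength Gaussian s.d. (s) applied to the decoding
#'   strength time courses; 0 disables.
#' @param n_folds,shrinkage passed to [mahalanobis_rdf()].
#' @param times optional numeric vector restricting decoding to the sample
#'   times nearest these values (seconds); default every sample.
#' @param window_samples odd number of consecutive samples averaged into the
#'   feature vector at each decoded time point (1 = instantaneous).
#' @param seed integer seed controlling fold assignment.
#' @param keep_trials keep per-trial strength matrices (needed by the median
#'   split and variance split)?
#' @param band alpha band passed to [alpha_power()] when `signal = "alpha"`.
#' @return a `decoding_timecourse`: list with `strength` (sessions x times),
#'   `time`, `sessions`, `trial_strength` (list of trials x times matrices,
#'   if kept), `trial_meta` (per session), `n_folds`, `params`.
#' @export
decode_timecourse <- function(e, channels = NULL, signal = c("voltage", "alpha"),
                              smooth_sigma_data = 0, smooth_sigma_strength = 0,
                              n_folds = 8, shrinkage = "auto", times = NULL,
                              window_samples = 1, seed = NULL,
                              keep_trials = TRUE, band = c(8, 12)) {
  signal <- match.arg(signal)
  if (is.null(e$trial_meta$orientation))
    stop("`e` needs trial_meta$orientation")
  ch <- if (is.null(channels)) seq_len(n_channels(e)) else
    if (is.character(channels)) match_channels(e, channels) else channels
  if (signal == "alpha") e <- alpha_power(e, band = band)
  if (smooth_sigma_data > 0) e <- smooth_gaussian(e, smooth_sigma_data)
  tt <- time_axis(e)
  tidx <- if (is.null(times)) seq_along(tt) else
    unique(vapply(times, function(x) which.min(abs(tt - x)), 0L))
  sessions <- split_sessions(e)
  S <- length(sessions)
  strength <- matrix(0, S, length(tidx))
  trial_strength <- vector("list", S)
  with_seed_if(seed, {
    for (s in seq_len(S)) {
      es <- sessions[[s]]
      lab <- es$trial_meta$orientation
      fold_id <- stratified_folds(lab, n_folds)
      classes <- sort(unique(lab))
      ts_mat <- matrix(0, n_trials(es), length(tidx))
      hw <- (window_samples - 1) %/% 2
      for (j in seq_along(tidx)) {
        cols <- intersect(tidx[j] + (-hw:hw), seq_along(tt))
        feat <- if (length(cols) == 1) es$data[, ch, cols] else
          apply(es$data[, ch, cols, drop = FALSE], c(1, 2), mean)
        r <- rdf_core(as.matrix(feat), lab, classes, fold_id, shrinkage)
        ts_mat[, j] <- strength_from_rdf(r)
      }
      if (smooth_sigma_strength > 0 && length(tidx) > 1)
        ts_mat <- smooth_gaussian(ts_mat, smooth_sigma_strength, e$srate)
      strength[s, ] <- colMeans(ts_mat)
      trial_strength[[s]] <- ts_mat
    }
  })
  structure(list(strength = strength, time = tt[tidx],
                 sessions = names(sessions),
                 trial_strength = if (keep_trials) trial_strength else NULL,
                 trial_meta = lapply(sessions, `[[`, "trial_meta"),
                 n_folds = n_folds,
                 params = list(channels = ch, signal = signal,
                               smooth_sigma_data = smooth_sigma_data,
                               smooth_sigma_strength = smooth_sigma_strength,
                               shrinkage = shrinkage,
                               window_samples = window_samples)),
            class = "decoding_timecourse")
}

#' @export
print.decoding_timecourse <- function(x, ...) {
  cat(sprintf("<decoding_timecourse> %d session(s) x %d time point(s)\n",
              nrow(x$strength), ncol(x$strength)))
  cat(sprintf("  signal: %s, folds: %d, mean strength: %.4g\n",
              x$params$signal, x$n_folds, mean(x$strength)))
  invisible(x)
}

#' Shuffle-null distribution of decoding strength
#'
#' Reruns the full decoding pipeline `n_shuffles` times with orientation
#' labels permuted within session, giving the empirical chance distribution
#' of the decoding strength (the shuffle predictor).
#'
#' @param e an [epoch_set()].
#' @param n_shuffles number of label permutations (>= 1; >= 100 recommended
#'   for inference).
#' @param seed integer seed.
#' @param keep_trials keep per-trial strengths for every shuffle (needed when
#'   feeding the median split's shuffle predictor)?
#' @param ... decoding parameters passed to [decode_timecourse()].
#' @return a `shuffle_null`: list with `strengths` (n_shuffles x times,
#'   session-mean), `per_session` (n_shuffles x sessions x times),
#'   `trial_strength` (list over shuffles, if kept), `time`, `n_shuffles`,
#'   `seed`.
#' @export
shuffle_null <- function(e, n_shuffles, seed = NULL, keep_trials = FALSE, ...) {
  if (n_shuffles < 1) stop("`n_shuffles` must be >= 1")
  ses <- e$trial_meta$session
  if (is.null(ses)) ses <- rep("s1", n_trials(e))
  dt0 <- NULL
  out <- NULL
  trial_keep <- if (keep_trials) vector("list", n_shuffles) else NULL
  for (b in seq_len(n_shuffles)) {
    sh_seed <- derive_seed(seed, b)
    eb <- e
    eb$trial_meta$orientation <- with_seed_if(sh_seed, {
      ave(e$trial_meta$orientation, ses,
          FUN = function(v) v[sample.int(length(v))])
    })
    dt <- decode_timecourse(eb, seed = derive_seed(seed, n_shuffles + b),
                            keep_trials = keep_trials, ...)
    if (is.null(out)) {
      dt0 <- dt
      out <- array(0, c(n_shuffles, nrow(dt$strength), ncol(dt$strength)))
    }
    out[b, , ] <- dt$strength
    if (keep_trials) trial_keep[[b]] <- dt$trial_strength
  }
  structure(list(strengths = apply(out, c(1, 3), mean),
                 per_session = out, trial_strength = trial_keep,
                 time = dt0$time, n_shuffles = n_shuffles, seed = seed),
            class = "shuffle_null")
}
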