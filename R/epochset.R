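#' Epoched multichannel EEG container
#'
#' An `epoch_set` holds a trials x channels x samples voltage array together
#' with its time axis and per-trial metadata. It is the common currency of the
#' package: the synthetic generators produce one, and all preprocessing,
#' decoding and variance analyses consume one.
#'
#' @param data numeric array, trials x channels x samples. Must be finite.
#' @param srate sampling rate in Hz.
#' @param t0 time of the first sample in seconds.
#' @param channel_labels character vector, one label per channel.
#' @param trial_meta data.frame with one row per trial. Conventional columns:
#'   `orientation` (degrees, in `[0, 180)`), `condition`, `session`, `subject`.
#' @return An object of class `epoch_set`.
#' @examples
#' e <- epoch_set(array(rnorm(2 * 3 * 10), c(2, 3, 10)), srate = 100, t0 = 0,
#'                channel_labels = c("O1", "Oz", "O2"),
#'                trial_meta = data.frame(orientation = c(0, 90)))
#' n_trials(e)
#' @export
epoch_set <- function(data, srate, t0 = 0, channel_labels = NULL,
                      trial_meta = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (trials x channels x samples)")
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("`data` must be finite")
  if (!is.numeric(srate) || length(srate) != 1L || srate <= 0)
    stop("`srate` must be a positive scalar (Hz)")
  d <- dim(data)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(d[2]))
  if (length(channel_labels) != d[2])
    stop("length(channel_labels) must equal the channel dimension (",
         d[2], "), got ", length(channel_labels))
  if (is.null(trial_meta)) trial_meta <- data.frame(trial = seq_len(d[1]))
  if (nrow(trial_meta) != d[1])
    stop("nrow(trial_meta) must equal the trial dimension (", d[1], ")")
  if (!is.null(trial_meta$orientation)) {
    ori <- trial_meta$orientation
    if (any(!is.finite(ori)) || any(ori < 0 | ori >= 180))
      stop("trial_meta$orientation must lie in [0, 180) degrees")
  }
  structure(
    list(data = data, srate = as.numeric(srate), t0 = as.numeric(t0),
         channel_labels = as.character(channel_labels),
         trial_meta = trial_meta),
    class = "epoch_set")
}

#' @rdname epoch_set
#' @param e an `epoch_set`.
#' @export
n_trials <- function(e) dim(e$data)[1]

#' @rdname epoch_set
#' @export
n_channels <- function(e) dim(e$data)[2]

#' @rdname epoch_set
#' @export
n_samples <- function(e) dim(e$data)[3]

#' Time axis of an epoch set
#'
#' @param e an `epoch_set`.
#' @return numeric vector of sample times in seconds.
#' @export
time_axis <- function(e) e$t0 + (seq_len(n_samples(e)) - 1L) / e$srate

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  tt <- time_axis(x)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$srate))
  cat(sprintf("  time: %.3f .. %.3f s\n", tt[1], tt[length(tt)]))
  cat("  channels:", paste(utils::head(x$channel_labels, 8), collapse = ", "),
      if (d[2] > 8) "..." else "", "\n")
  cat("  trial_meta:", paste(names(x$trial_meta), collapse = ", "), "\n")
  invisible(x)
}

#' Subset an epoch set
#'
#' `e[i, j, k]` subsets trials (`i`), channels (`j`, indices or labels) and
#' samples (`k`), keeping metadata in register.
#'
#' @param x an `epoch_set`.
#' @param i trial indices.
#' @param j channel indices or labels.
#' @param k sample indices.
#' @param ... unused.
#' @export
`[.epoch_set` <- function(x, i, j, k, ...) {
  if (missing(i)) i <- seq_len(n_trials(x))
  if (missing(j)) j <- seq_len(n_channels(x))
  if (missing(k)) k <- seq_len(n_samples(x))
  if (is.character(j)) j <- match_channels(x, j)
  t0 <- x$t0
  if (is.numeric(k)) t0 <- time_axis(x)[k][1]
  dat <- x$data[i, j, k, drop = FALSE]
  epoch_set(dat, x$srate, t0, x$channel_labels[j],
            x$trial_meta[i, , drop = FALSE])
}

# resolve channel labels to indices, with an informative error
match_channels <- function(e, channels) {
  idx <- match(channels, e$channel_labels)
  if (anyNA(idx))
    stop("unknown channel label(s): ",
         paste(channels[is.na(idx)], collapse = ", "),
         "; available: ", paste(e$channel_labels, collapse = ", "))
  idx
}

#' Split an epoch set by session
#'
#' @param e an `epoch_set` whose `trial_meta` has a `session` column (a single
#'   implicit session is assumed if absent).
#' @return named list of `epoch_set`, one per session, in order of appearance.
#' @export
split_sessions <- function(e) {
  ses <- e$trial_meta$session
  if (is.null(ses)) return(stats::setNames(list(e), "s1"))
  ids <- unique(ses)
  stats::setNames(lapply(ids, function(s) {
    e[which(ses == s), , ]
  }), as.character(ids))
}

#' Read and write epoch sets as plain text
#'
#' Serializes an `epoch_set` to a directory of plain-text files:
#' `header.json` (sampling rate, t0, dimensions, channel labels),
#' `trials.csv` (the metadata table) and `data.csv` (one row per
#' trial x channel, samples across columns). `read_epoch_set()` reverses it.
#'
#' @param e an `epoch_set`.
#' @param path directory to write to / read from (created if needed).
#' @return `write_epoch_set()` returns `path` invisibly; `read_epoch_set()`
#'   returns the reconstructed `epoch_set`.
#' @export
write_epoch_set <- function(e, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(e$data)
  hdr <- list(srate = e$srate, t0 = e$t0, n_trials = d[1], n_channels = d[2],
              n_samples = d[3], channel_labels = e$channel_labels)
  jsonlite::write_json(hdr, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(e$trial_meta, file.path(path, "trials.csv"),
                   row.names = FALSE)
  flat <- matrix(aperm(e$data, c(3, 2, 1)), nrow = d[1] * d[2], byrow = TRUE)
  idx <- expand.grid(channel = seq_len(d[2]), trial = seq_len(d[1]))
  out <- cbind(trial = idx$trial[order(idx$trial)],
               channel = rep(seq_len(d[2]), d[1]), as.data.frame(flat))
  utils::write.csv(out, file.path(path, "data.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(path) {
  hdr <- jsonlite::read_json(file.path(path, "header.json"),
                             simplifyVector = TRUE)
  meta <- utils::read.csv(file.path(path, "trials.csv"),
                          stringsAsFactors = FALSE)
  raw <- utils::read.csv(file.path(path, "data.csv"))
  vals <- as.matrix(raw[, -(1:2), drop = FALSE])
  dat <- array(0, c(hdr$n_trials, hdr$n_channels, hdr$n_samples))
  for (r in seq_len(nrow(raw)))
    dat[raw$trial[r], raw$channel[r], ] <- vals[r, ]
  epoch_set(dat, hdr$srate, hdr$t0, hdr$channel_labels, meta)
}

# run code under a temporary RNG state seeded with `seed`; NULL seed uses the
# ambient RNG stream untouched by any save/restore
with_seed_if <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}

# derive a bounded child seed for sub-streams (sessions, trials, shuffles)
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483629)
}
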