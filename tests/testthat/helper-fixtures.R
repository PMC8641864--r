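# small in-code fixtures shared across test files

tiny_epochs <- function(n_trials = 4, n_channels = 2, n_samples = 20,
                        srate = 100, fill = NULL, seed = 1) {
  dat <- withr::with_seed(seed, {
    if (is.null(fill)) array(rnorm(n_trials * n_channels * n_samples),
                             c(n_trials, n_channels, n_samples))
    else array(fill, c(n_trials, n_channels, n_samples))
  })
  epoch_set(dat, srate = srate,
            trial_meta = data.frame(orientation =
                                      rep_len(c(0, 90), n_trials)))
}

# synthetic spike records (no network simulation) for Fano/tuning readouts
fake_records <- function(counts_fun, n_trials, n_exc = 32, duration = 2,
                         seed = 1) {
  spec <- list(n_exc = n_exc, preset = "fake")
  proto <- list(duration = duration, cue_angle = 180,
                cue_window = c(0.2, 0.4), drive_window = c(1.2, 1.4))
  withr::with_seed(seed, lapply(seq_len(n_trials), function(i) {
    st <- counts_fun(i)
    structure(list(neuron = st$neuron, time = st$time, spec = spec,
                   proto = proto),
              class = "spike_record")
  }))
}

# homogeneous Poisson spikes at `rate` Hz per neuron
poisson_records <- function(n_trials, rate = 10, n_exc = 32, duration = 2,
                            seed = 1) {
  fake_records(function(i) {
    n <- rpois(1, rate * n_exc * duration)
    list(neuron = sample.int(n_exc, n, replace = TRUE),
         time = sort(runif(n, 0, duration)))
  }, n_trials, n_exc, duration, seed)
}
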