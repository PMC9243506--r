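# Shared fixture builders.  Everything is generated in code at test time;
# small sampling rates keep the suite fast while preserving the pipeline's
# integer decimation to 100 Hz.

# A profile over a small montage (first `nch` channels of the standard one).
tiny_profile <- function(id = "s1", nch = 4, ...) {
  ch <- standard_montage()[seq_len(nch)]
  w <- default_spatial_weights()[seq_len(nch)]
  subject_profile(id, spatial_weights = w, ...)
}

# A noise recording over the full 30-channel montage with evenly spaced
# markers (non-overlapping epochs by default).
noise_recording <- function(n_markers = 10, fs = 500, spacing_ms = 1200,
                            noise_sd = 2, id = "s1", seed = 1,
                            channel_names = standard_montage()) {
  withr::with_seed(seed, {
    n <- round((n_markers * spacing_ms + 2000) * fs / 1000)
    dat <- matrix(rnorm(length(channel_names) * n, 0, noise_sd),
                  length(channel_names), n)
    onsets <- round((500 + spacing_ms * (seq_len(n_markers) - 1)) * fs / 1000)
    mk <- flash_markers(onsets, (seq_len(n_markers) - 1) %% 13,
                        seq_len(n_markers) %% 2 == 0)
    continuous_recording(dat, fs, channel_names, mk, id)
  })
}

# A small processed dataset (epochs already at 30 x 90) with controllable
# class structure, for harness-contract tests that do not need real signal.
stub_dataset <- function(n_subjects = 3, n_ep = 40, seed = 1) {
  withr::with_seed(seed, {
    structure(lapply(seq_len(n_subjects), function(s) {
      id <- paste0("s", s)
      eps <- array(rnorm(n_ep * 30 * 90), c(n_ep, 30, 90))
      eps[, 1, 1] <- seq_len(n_ep)        # epoch identity tag for partition checks
      labels <- rep(c(0, 0, 0, 0, 1), length.out = n_ep)
      list(profile = subject_profile(id, sex = c("M", "F")[1 + s %% 2]),
           epochs = epoch_set(eps, labels, rep(id, n_ep), 100))
    }), class = "p300_dataset")
  })
}

# A classifier stub satisfying the fit/predict_proba contract that records
# what it is shown; predictions are p = 0.9 for epochs whose tag is even
# (arbitrary but deterministic).
recording_classifier <- function(log_env) {
  structure(list(
    name = "stub",
    fit = function(epochs, labels, profiles) {
      log_env$train_ids <- c(log_env$train_ids, list(unique(epochs$subject_ids)))
      log_env$train_profiles <- c(log_env$train_profiles, list(names(profiles)))
      list()
    },
    predict_proba = function(fitted, epochs, profiles) {
      log_env$test_tags <- c(log_env$test_tags, list(epochs$epochs[, 1, 1]))
      log_env$test_ids <- c(log_env$test_ids, list(unique(epochs$subject_ids)))
      rep(0.5, n_epochs(epochs))
    }
  ), class = "p300_classifier")
}
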