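#' Bandpass filter specification
#'
#' Butterworth bandpass applied to continuous EEG before epoching. The
#' default matches ERP practice: 0.1-30 Hz, order 3. `zero_phase` mode
#' filters forward and backward (no phase distortion; effective magnitude
#' order doubles) and is the offline default; `causal` mode is the online
#' path.
#'
#' @param low_hz,high_hz Band edges in Hz.
#' @param order Butterworth order (per pass).
#' @param mode `"zero_phase"` or `"causal"`.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(low_hz = 0.1, high_hz = 30, order = 3,
                        mode = c("zero_phase", "causal")) {
  if (low_hz <= 0 || low_hz >= high_hz) stopf("need 0 < low_hz < high_hz")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order,
                 mode = match.arg(mode)),
            class = "filter_spec")
}

#' Select and order montage channels
#'
#' Reduces a recording to the analysis montage, reordering rows to match.
#'
#' @param rec A [continuous_recording()].
#' @param montage Ordered channel labels (default the 30-channel
#'   [standard_montage()]).
#' @return The recording restricted to `montage`, rows in montage order.
#' @export
select_channels <- function(rec, montage = standard_montage()) {
  miss <- setdiff(montage, rec$channel_names)
  if (length(miss) > 0) {
    stopf("recording is missing montage channel(s): %s",
          paste(miss, collapse = ", "))
  }
  idx <- match(montage, rec$channel_names)
  continuous_recording(rec$data[idx, , drop = FALSE], rec$fs, montage,
                       rec$markers, rec$subject_id)
}

#' Bandpass-filter a recording
#'
#' Applies the order-`order` Butterworth bandpass of `spec` to every channel.
#'
#' @param rec A [continuous_recording()].
#' @param spec A [filter_spec()].
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, spec = filter_spec()) {
  fs <- rec$fs
  if (fs <= 2 * spec$high_hz) {
    stopf("sampling rate %g Hz is too low for a %g Hz upper edge", fs,
          spec$high_hz)
  }
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (fs / 2),
                       type = "pass")
  out <- rec$data
  for (c in seq_len(nrow(out))) {
    out[c, ] <- if (spec$mode == "zero_phase") {
      signal::filtfilt(bf, rec$data[c, ])
    } else {
      as.numeric(signal::filter(bf, rec$data[c, ]))
    }
  }
  continuous_recording(out, fs, rec$channel_names, rec$markers,
                       rec$subject_id)
}

#' Cut stimulus-locked epochs
#'
#' Extracts one epoch per flash marker over `[-100, +800)` ms (half-open at
#' sample resolution; sample 0 is the stimulus-onset sample), labelled by
#' `is_target`. Epochs whose window would leave the recording are dropped
#' with a message.
#'
#' @param rec A [continuous_recording()] with markers.
#' @param t_start_ms,t_end_ms Epoch window relative to onset, ms.
#' @return An [epoch_set()] at the recording's sampling rate.
#' @export
segment_epochs <- function(rec, t_start_ms = -100, t_end_ms = 800) {
  fs <- rec$fs
  mk <- rec$markers
  n_samp <- round((t_end_ms - t_start_ms) * fs / 1000)
  pre <- round(-t_start_ms * fs / 1000)
  if (nrow(mk) == 0) {
    warning("recording has no markers; returning an empty epoch set")
    return(epoch_set(array(0, c(0, nrow(rec$data), n_samp)), numeric(0),
                     character(0), fs, t_start_ms, t_end_ms,
                     channel_names = rec$channel_names))
  }
  start0 <- mk$onset_sample - pre                      # 0-based window start
  ok <- start0 >= 0 & (start0 + n_samp) <= ncol(rec$data)
  if (any(!ok)) {
    message(sprintf("dropped %d epoch(s) at the recording edge", sum(!ok)))
  }
  keep <- which(ok)
  arr <- array(0, c(length(keep), nrow(rec$data), n_samp))
  for (j in seq_along(keep)) {
    i <- keep[j]
    arr[j, , ] <- rec$data[, (start0[i] + 1):(start0[i] + n_samp)]
  }
  epoch_set(arr, as.numeric(mk$is_target[keep]),
            rep(rec$subject_id, length(keep)), fs, t_start_ms, t_end_ms,
            channel_names = rec$channel_names)
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the pre-stimulus interval
#' (`[t_start_ms, 0)`), referencing each epoch to its own pre-stimulus
#' activity. Idempotent.
#'
#' @param epochs An [epoch_set()] whose window covers `[t_start_ms, 0)`.
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs) {
  if (epochs$t_start_ms >= 0) stopf("epoch window does not cover a baseline interval")
  d <- dim(epochs$epochs)
  if (d[1] == 0) return(epochs)
  bl_n <- round(-epochs$t_start_ms * epochs$fs / 1000)
  x <- epochs$epochs
  dim(x) <- c(d[1] * d[2], d[3])                      # (epoch, channel) rows
  mm <- rowMeans(x[, seq_len(bl_n), drop = FALSE])
  x <- x - mm
  dim(x) <- d
  out <- epochs
  out$epochs <- x
  out
}

#' Amplitude-threshold artifact rejection
#'
#' Removes every epoch containing any sample outside
#' `[-threshold, +threshold]` microvolts (applied after baseline correction
#' in the standard pipeline, so constant offsets do not trigger rejection).
#'
#' @param epochs An [epoch_set()].
#' @param threshold Rejection threshold in microvolts (default 100).
#' @return `list(epochs = kept epoch_set, rejected = logical mask)` over the
#'   input epochs.
#' @export
reject_artifacts <- function(epochs, threshold = 100) {
  d <- dim(epochs$epochs)
  if (d[1] == 0) return(list(epochs = epochs, rejected = logical(0)))
  x <- epochs$epochs
  dim(x) <- c(d[1], d[2] * d[3])
  rejected <- apply(abs(x) > threshold, 1, any)
  list(epochs = epochs[!rejected], rejected = rejected)
}

# Linear-phase FIR anti-alias lowpass: cutoff at 0.45 * target_fs, 151 taps
# (Hamming), whose transition band stays above the 30 Hz analysis band while
# attenuating at the new Nyquist.
anti_alias_fir <- function(fs, target_fs) {
  signal::fir1(150, 0.9 * target_fs / fs)
}

#' Decimate epochs to the model sampling rate
#'
#' Anti-alias lowpass (linear-phase 151-tap FIR, cutoff 0.45 x `target_fs`,
#' applied centered with edge reflection) followed by keeping every
#' `fs / target_fs`-th sample. A 900 ms epoch at 100 Hz yields exactly 90
#' samples -- the detector's input width.
#'
#' @param epochs An [epoch_set()].
#' @param target_fs Target sampling rate (must divide `fs`).
#' @return The decimated `epoch_set` (identity when `fs == target_fs`).
#' @export
decimate_epochs <- function(epochs, target_fs = 100) {
  fs <- epochs$fs
  if (fs == target_fs) return(epochs)
  fac <- fs / target_fs
  if (abs(fac - round(fac)) > 1e-9) {
    stopf("sampling rate %g is not an integer multiple of target %g", fs,
          target_fs)
  }
  fac <- as.integer(round(fac))
  d <- dim(epochs$epochs)
  n_out <- round(0.9 * target_fs)
  if (d[1] == 0) {
    out <- epochs
    out$epochs <- array(0, c(0, d[2], n_out))
    out$fs <- target_fs
    return(out)
  }
  b <- anti_alias_fir(fs, target_fs)
  pad <- (length(b) - 1L) %/% 2L
  x <- aperm(epochs$epochs, c(3, 2, 1))                # samples first
  dim(x) <- c(d[3], d[2] * d[1])
  xp <- rbind(x[(pad + 1):2, , drop = FALSE], x,
              x[(d[3] - 1):(d[3] - pad), , drop = FALSE])
  xf <- stats::filter(xp, b, sides = 2)
  xf <- xf[pad + seq_len(d[3]), , drop = FALSE]
  keep <- seq(1, d[3], by = fac)[seq_len(n_out)]
  xd <- xf[keep, , drop = FALSE]
  dim(xd) <- c(n_out, d[2], d[1])
  out <- epochs
  out$epochs <- aperm(xd, c(3, 2, 1))
  out$fs <- target_fs
  out
}

#' Full preprocessing pipeline for one recording
#'
#' Montage selection, bandpass, epoching, baseline correction, artifact
#' rejection, decimation -- yielding the detector's `n x 30 x 90` input.
#'
#' @param rec A [continuous_recording()].
#' @param montage Channel montage (default [standard_montage()]).
#' @param spec A [filter_spec()].
#' @param threshold Artifact-rejection threshold, microvolts.
#' @param target_fs Output sampling rate, Hz.
#' @return An [epoch_set()]; the number of rejected epochs is attached as
#'   attribute `"n_rejected"`.
#' @export
preprocess_recording <- function(rec, montage = standard_montage(),
                                 spec = filter_spec(), threshold = 100,
                                 target_fs = 100) {
  rec <- select_channels(rec, montage)
  rec <- bandpass_filter(rec, spec)
  ep <- segment_epochs(rec)
  ep <- baseline_correct(ep)
  rej <- reject_artifacts(ep, threshold)
  out <- decimate_epochs(rej$epochs, target_fs)
  attr(out, "n_rejected") <- sum(rej$rejected)
  out
}

# Stack several epoch sets (same geometry) into one.
combine_epoch_sets <- function(sets) {
  sets <- Filter(function(s) n_epochs(s) > 0, sets)
  if (length(sets) == 1) return(sets[[1]])
  d <- dim(sets[[1]]$epochs)
  ns <- vapply(sets, n_epochs, 0L)
  arr <- array(0, c(sum(ns), d[2], d[3]))
  at <- 0L
  for (s in sets) {
    arr[at + seq_len(n_epochs(s)), , ] <- s$epochs
    at <- at + n_epochs(s)
  }
  epoch_set(arr, unlist(lapply(sets, `[[`, "labels")),
            unlist(lapply(sets, `[[`, "subject_ids")),
            sets[[1]]$fs, sets[[1]]$t_start_ms, sets[[1]]$t_end_ms,
            channel_names = sets[[1]]$channel_names)
}

#' Preprocess a whole synthetic cohort
#'
#' Runs [preprocess_recording()] on every session of every subject and stacks
#' the results per subject.
#'
#' @param cohort A `p300_cohort` from [generate_cohort()].
#' @param ... Passed to [preprocess_recording()].
#' @return A `p300_dataset`: list with one element per subject holding
#'   `profile` and `epochs` (processed [epoch_set()]).
#' @export
preprocess_cohort <- function(cohort, ...) {
  out <- lapply(cohort, function(subj) {
    eps <- lapply(subj$recordings, preprocess_recording, ...)
    list(profile = subj$profile, epochs = combine_epoch_sets(eps))
  })
  structure(out, class = "p300_dataset")
}
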