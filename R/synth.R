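#' Speller paradigm configuration
#'
#' Describes the oddball matrix-speller paradigm: a 6 x 7 character grid whose
#' 6 rows and 7 columns flash one at a time. One *sequence* flashes each of
#' the 13 lines exactly once (so the attended character's line flashes twice
#' per sequence: once as a row, once as a column); one *run* is 8 sequences
#' (104 flashes) and outputs one character; one *session* is 5 runs.
#'
#' Flash duration and inter-flash interval are presentation choices that the
#' generator exposes rather than fixes; defaults give a 175 ms stimulus onset
#' asynchrony.
#'
#' @param n_rows,n_cols Grid size (must be 6 x 7).
#' @param sequences_per_run Sequences per run (default 8).
#' @param runs_per_session Runs per session (default 5).
#' @param sessions Sessions per subject (default 1).
#' @param flash_duration_ms,inter_flash_interval_ms Stimulus timing, ms.
#' @param fs_acquisition Acquisition sampling rate in Hz (default 1000; the
#'   preprocessing chain later decimates to 100 Hz).
#' @return A `paradigm_config` list.
#' @export
paradigm_config <- function(n_rows = 6L, n_cols = 7L, sequences_per_run = 8L,
                            runs_per_session = 5L, sessions = 1L,
                            flash_duration_ms = 100, inter_flash_interval_ms = 75,
                            fs_acquisition = 1000) {
  if (n_rows * n_cols != 42L) stopf("the speller grid must be 6 x 7 (42 characters)")
  cfg <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              sequences_per_run = as.integer(sequences_per_run),
              runs_per_session = as.integer(runs_per_session),
              sessions = as.integer(sessions),
              flash_duration_ms = flash_duration_ms,
              inter_flash_interval_ms = inter_flash_interval_ms,
              fs_acquisition = fs_acquisition)
  cfg$n_lines <- cfg$n_rows + cfg$n_cols          # 13
  cfg$soa_ms <- flash_duration_ms + inter_flash_interval_ms
  structure(cfg, class = "paradigm_config")
}

#' The 30-channel analysis montage
#'
#' Ordered labels of the 30 standard 10-20 electrodes retained for analysis.
#' @return Character vector of length 30.
#' @export
standard_montage <- function() {
  c("FP1", "FPz", "FP2", "F7", "F3", "Fz", "F4", "F8",
    "FC3", "FCz", "FC4", "T7", "C3", "Cz", "C4", "T8",
    "CP3", "CPz", "CP4", "P7", "P3", "Pz", "P4", "P8",
    "PO5", "POz", "PO6", "O1", "Oz", "O2")
}

#' Default P300 scalp topography
#'
#' Per-channel gains for the simulated P300, maximal over centro-parietal
#' sites (Pz/CPz/POz) and tapering toward frontal and temporal electrodes --
#' the classic P3b distribution.
#'
#' @param channel_names Montage labels the gains are aligned to.
#' @return Named numeric vector of gains in `[0, 1]`.
#' @export
default_spatial_weights <- function(channel_names = standard_montage()) {
  w <- c(FP1 = 0.15, FPz = 0.15, FP2 = 0.15, F7 = 0.2, F3 = 0.3, Fz = 0.4,
         F4 = 0.3, F8 = 0.2, FC3 = 0.45, FCz = 0.6, FC4 = 0.45, T7 = 0.3,
         C3 = 0.6, Cz = 0.85, C4 = 0.6, T8 = 0.3, CP3 = 0.8, CPz = 0.95,
         CP4 = 0.8, P7 = 0.5, P3 = 0.8, Pz = 1.0, P4 = 0.8, P8 = 0.5,
         PO5 = 0.7, POz = 0.9, PO6 = 0.7, O1 = 0.6, Oz = 0.65, O2 = 0.6)
  out <- w[channel_names]
  out[is.na(out)] <- 0.1
  names(out) <- channel_names
  out
}

#' Simulated participant profile
#'
#' Subject-level parameters of the generator: demographics plus the P300
#' response parameters they modulate (amplitude, latency) and the subject's
#' background-noise level. Amplitude and latency heterogeneity across sex and
#' age is the individual variation the wide (memorization) branch of the
#' detector is designed to exploit.
#'
#' @param subject_id Identifier.
#' @param sex `"M"` or `"F"`.
#' @param age_group Categorical age bin (default vocabulary
#'   `young`/`mid`/`old`).
#' @param p300_amplitude Peak target-response amplitude at the best channel,
#'   microvolts (>= 0).
#' @param p300_latency Peak latency after stimulus onset, ms (in (0, 800)).
#' @param latency_jitter_sd Trial-to-trial latency jitter SD, ms.
#' @param noise_scale Background EEG scale (SD of the 1/f process), microvolts.
#' @param spatial_weights Per-channel response gain; names define the montage.
#' @param p300_width_ms Gaussian SD of the response bump, ms.
#' @return A `subject_profile` list.
#' @export
subject_profile <- function(subject_id, sex = "M", age_group = "mid",
                            p300_amplitude = 8, p300_latency = 350,
                            latency_jitter_sd = 15, noise_scale = 4,
                            spatial_weights = default_spatial_weights(),
                            p300_width_ms = 45) {
  if (p300_amplitude < 0) stopf("p300_amplitude must be >= 0")
  if (p300_latency <= 0 || p300_latency >= 800) {
    stopf("p300_latency must lie in (0, 800) ms")
  }
  structure(
    list(subject_id = as.character(subject_id), sex = sex,
         age_group = age_group, p300_amplitude = p300_amplitude,
         p300_latency = p300_latency, latency_jitter_sd = latency_jitter_sd,
         noise_scale = noise_scale, spatial_weights = spatial_weights,
         p300_width_ms = p300_width_ms),
    class = "subject_profile"
  )
}

#' Generate one run's flash schedule
#'
#' Produces the 104 flash events of a single run: 8 sequences, each a uniform
#' random permutation of the 13 line indices (0-5 rows, 6-12 columns), with
#' onsets spaced by flash duration + inter-flash interval. A flash is a target
#' iff its line contains the attended character, so every sequence holds
#' exactly 2 targets.
#'
#' @param cfg A [paradigm_config()].
#' @param target_position `c(row, col)` of the attended character (1-based).
#' @param seed Integer seed; the schedule is a pure function of (cfg,
#'   target_position, seed).
#' @param t0_ms Onset of the first flash, ms.
#' @return A `data.frame` with columns `sequence_index`, `line_index`,
#'   `onset_ms`, `is_target`.
#' @export
generate_flash_schedule <- function(cfg, target_position, seed, t0_ms = 0) {
  row <- target_position[1]; col <- target_position[2]
  if (row < 1 || row > cfg$n_rows || col < 1 || col > cfg$n_cols) {
    stopf("target_position (%d, %d) lies outside the %d x %d grid",
          row, col, cfg$n_rows, cfg$n_cols)
  }
  target_lines <- c(row - 1L, cfg$n_rows + col - 1L)
  with_seed(seed, {
    lines <- unlist(lapply(seq_len(cfg$sequences_per_run),
                           function(s) sample.int(cfg$n_lines) - 1L))
    n <- length(lines)
    data.frame(
      sequence_index = rep(seq_len(cfg$sequences_per_run), each = cfg$n_lines),
      line_index = lines,
      onset_ms = t0_ms + (seq_len(n) - 1L) * cfg$soa_ms,
      is_target = lines %in% target_lines
    )
  })
}

#' Generate a whole-session flash schedule
#'
#' Concatenates `runs_per_session` run schedules (one attended character per
#' run) with an inter-run gap, returning absolute onsets.
#'
#' @param cfg A [paradigm_config()].
#' @param targets Optional `runs_per_session x 2` matrix of `(row, col)`
#'   targets; drawn uniformly when `NULL`.
#' @param seed Integer seed.
#' @param start_offset_ms Silence before the first flash (leave >= 100 ms for
#'   the epoch baseline).
#' @param inter_run_gap_ms Gap between runs, ms.
#' @return A `data.frame` as in [generate_flash_schedule()] plus `run_index`,
#'   with the target grid positions attached as attribute `"targets"`.
#' @export
generate_session_schedule <- function(cfg, targets = NULL, seed = 1,
                                      start_offset_ms = 1000,
                                      inter_run_gap_ms = 2000) {
  with_seed(seed, {
    if (is.null(targets)) {
      targets <- cbind(sample.int(cfg$n_rows, cfg$runs_per_session, replace = TRUE),
                       sample.int(cfg$n_cols, cfg$runs_per_session, replace = TRUE))
    }
    run_seeds <- sample.int(.Machine$integer.max, cfg$runs_per_session)
    t0 <- start_offset_ms
    out <- vector("list", cfg$runs_per_session)
    for (r in seq_len(cfg$runs_per_session)) {
      sched <- generate_flash_schedule(cfg, targets[r, ], run_seeds[r], t0_ms = t0)
      sched$run_index <- r
      out[[r]] <- sched
      t0 <- max(sched$onset_ms) + cfg$soa_ms + inter_run_gap_ms
    }
    res <- do.call(rbind, out)
    attr(res, "targets") <- targets
    res
  })
}

#' Subject-specific event-related response template
#'
#' A Gaussian-windowed positive deflection peaking `p300_latency` ms after
#' stimulus onset with peak amplitude `p300_amplitude`, scaled per channel by
#' the profile's spatial weights. Time zero of the template is stimulus onset.
#'
#' @param profile A [subject_profile()].
#' @param fs Sampling rate in Hz.
#' @param length_ms Template length in ms (must cover the latency).
#' @param latency_ms Peak latency override (used internally for per-trial
#'   jitter); defaults to the profile's latency.
#' @return Matrix `channels x round(length_ms * fs / 1000)`.
#' @export
synthesize_erp_template <- function(profile, fs, length_ms = 800,
                                    latency_ms = profile$p300_latency) {
  if (latency_ms <= 0 || latency_ms >= length_ms) {
    stopf("latency %g ms falls outside the %g ms template window",
          latency_ms, length_ms)
  }
  n <- round(length_ms * fs / 1000)
  t_ms <- (seq_len(n) - 1) * 1000 / fs          # 0-based sample times
  bump <- profile$p300_amplitude *
    exp(-0.5 * ((t_ms - latency_ms) / profile$p300_width_ms)^2)
  outer(unname(profile$spatial_weights), bump)
}

# 1/f ("pink") background noise via spectral shaping: white Gaussian noise
# whose spectrum is scaled by 1/sqrt(f) above a 0.5 Hz floor (power ~ 1/f),
# normalized to unit SD.
one_over_f_noise <- function(n, fs) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  scale <- 1 / sqrt(pmax(f, 0.5))
  scale[1] <- 0                                  # no DC component
  x <- Re(stats::fft(spec * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Synthesize a continuous speller EEG recording
#'
#' Renders a flash schedule into continuous multichannel EEG for one subject:
#' background activity (1/f noise plus a 10 Hz alpha sinusoid, scaled by the
#' subject's `noise_scale`) with the subject's response template added at
#' every target flash onset, its latency jittered per trial by
#' `Normal(0, latency_jitter_sd)`. Markers match the schedule exactly.
#'
#' @param schedule Flash schedule (`onset_ms`, `line_index`, `is_target`).
#' @param profile A [subject_profile()]; its `spatial_weights` names define
#'   the generated channels.
#' @param cfg A [paradigm_config()] (supplies the sampling rate).
#' @param seed Integer seed.
#' @param nontarget_amplitude_uv Optional small evoked deflection on
#'   non-target flashes (default 0: non-targets carry no response).
#' @param alpha_fraction Alpha-sinusoid amplitude as a fraction of
#'   `noise_scale`.
#' @param pad_end_ms Silence appended after the last flash.
#' @return A [continuous_recording()].
#' @export
synthesize_recording <- function(schedule, profile, cfg, seed,
                                 nontarget_amplitude_uv = 0,
                                 alpha_fraction = 0.5, pad_end_ms = 1500) {
  if (nrow(schedule) == 0) stopf("schedule must contain at least one flash")
  fs <- cfg$fs_acquisition
  ch_names <- names(profile$spatial_weights)
  nch <- length(ch_names)
  n <- ceiling((max(schedule$onset_ms) + pad_end_ms) * fs / 1000)
  with_seed(seed, {
    dat <- matrix(0, nch, n)
    t_s <- (seq_len(n) - 1) / fs
    for (c in seq_len(nch)) {
      phase <- stats::runif(1, 0, 2 * pi)
      dat[c, ] <- profile$noise_scale *
        (one_over_f_noise(n, fs) +
           alpha_fraction * sin(2 * pi * 10 * t_s + phase))
    }
    onset_samp <- round(schedule$onset_ms * fs / 1000)
    tmpl_len <- round(800 * fs / 1000)
    for (i in seq_len(nrow(schedule))) {
      amp <- if (schedule$is_target[i]) profile$p300_amplitude else nontarget_amplitude_uv
      if (amp == 0) next
      lat <- profile$p300_latency +
        stats::rnorm(1, 0, profile$latency_jitter_sd)
      lat <- min(max(lat, 50), 750)
      p <- profile
      p$p300_amplitude <- amp
      tmpl <- synthesize_erp_template(p, fs, 800, latency_ms = lat)
      idx <- (onset_samp[i] + 1):(onset_samp[i] + tmpl_len)
      keep <- idx <= n
      dat[, idx[keep]] <- dat[, idx[keep]] + tmpl[, keep, drop = FALSE]
    }
    markers <- flash_markers(onset_samp, schedule$line_index,
                             schedule$is_target)
    continuous_recording(dat, fs, ch_names, markers, profile$subject_id)
  })
}

#' Inject high-amplitude artifacts into epoch windows
#'
#' Adds a low-frequency half-cosine pulse exceeding `amplitude` microvolts
#' inside the post-stimulus window of `k` distinct flash epochs, as a fixture
#' for the +/-100 microvolt rejection rule. The pulse is 150 ms wide so it
#' survives the 0.1-30 Hz bandpass essentially intact. When epoch windows do
#' not overlap (marker spacing >= 1000 ms), exactly the `k` chosen epochs are
#' later rejected; under the speller's 175 ms flash spacing neighbouring
#' epochs overlap the pulse and may be rejected too.
#'
#' @param rec A [continuous_recording()] with markers.
#' @param k Number of epochs to corrupt (`k <=` number of markers).
#' @param amplitude Pulse peak in microvolts; must exceed 100 or the pulse
#'   could never trigger rejection.
#' @param seed Integer seed.
#' @return The corrupted recording, with the (sorted) indices of the affected
#'   markers in attribute `"injected_markers"`.
#' @export
inject_artifacts <- function(rec, k, amplitude = 500, seed = 1) {
  if (amplitude <= 100) {
    stopf("artifact amplitude must exceed 100 microvolts (got %g)", amplitude)
  }
  nm <- nrow(rec$markers)
  if (k > nm) stopf("k = %d exceeds the %d available epochs", k, nm)
  out <- rec
  if (k == 0) {
    attr(out, "injected_markers") <- integer(0)
    return(out)
  }
  fs <- rec$fs
  pulse_len <- round(0.150 * fs)
  pulse <- amplitude * 1.05 * sin(pi * seq(0, 1, length.out = pulse_len))
  with_seed(seed, {
    idx <- sort(sample.int(nm, k))
    for (i in idx) {
      onset <- rec$markers$onset_sample[i]
      start <- onset + round(0.300 * fs)          # well inside [0, 800) ms
      cols <- (start + 1):(start + pulse_len)
      cols <- cols[cols <= ncol(out$data)]
      ch <- sample.int(nrow(out$data), 1)
      out$data[ch, cols] <- out$data[ch, cols] + pulse[seq_along(cols)]
    }
    attr(out, "injected_markers") <- idx
    out
  })
}

#' Default cohort heterogeneity distributions
#'
#' The distributions the cohort generator draws subject profiles from.
#' Amplitude depends on sex (females slightly larger P300), latency on age
#' group (latency lengthens with age); background noise is log-normal around
#' 4 microvolts. Values are in microvolts / ms.
#'
#' @return A named list of distribution parameters.
#' @export
default_heterogeneity <- function() {
  list(
    sexes = c(M = 0.5, F = 0.5),
    age_groups = c(young = 1 / 3, mid = 1 / 3, old = 1 / 3),
    amplitude_mean = c(M = 7, F = 9), amplitude_sd = 1,
    latency_mean = c(young = 310, mid = 350, old = 400), latency_sd = 15,
    latency_jitter_sd = 15,
    noise_scale_mean = 4, noise_scale_sdlog = 0.15
  )
}

#' Draw subject profiles from the heterogeneity distributions
#'
#' @param n_subjects Number of profiles.
#' @param heterogeneity Distribution list, see [default_heterogeneity()].
#' @param seed Integer seed.
#' @param channel_names Montage for the spatial weights.
#' @return List of [subject_profile()] objects (ids `s1`, `s2`, ...).
#' @export
draw_subject_profiles <- function(n_subjects, heterogeneity = default_heterogeneity(),
                                  seed = 1, channel_names = standard_montage()) {
  h <- heterogeneity
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      sex <- sample(names(h$sexes), 1, prob = h$sexes)
      age <- sample(names(h$age_groups), 1, prob = h$age_groups)
      amp <- max(0.5, stats::rnorm(1, h$amplitude_mean[[sex]], h$amplitude_sd))
      lat <- min(max(stats::rnorm(1, h$latency_mean[[age]], h$latency_sd), 150), 600)
      noise <- h$noise_scale_mean * exp(stats::rnorm(1, 0, h$noise_scale_sdlog))
      subject_profile(
        subject_id = paste0("s", i), sex = sex, age_group = age,
        p300_amplitude = amp, p300_latency = lat,
        latency_jitter_sd = h$latency_jitter_sd, noise_scale = noise,
        spatial_weights = default_spatial_weights(channel_names)
      )
    })
  })
}

#' Generate a synthetic speller cohort
#'
#' Draws `n_subjects` profiles and simulates, for each subject and session,
#' one continuous speller recording (`runs_per_session` runs of 104 flashes
#' with random attended characters). The cohort is a pure function of
#' (arguments, seed).
#'
#' @inheritParams draw_subject_profiles
#' @param cfg A [paradigm_config()].
#' @return A `p300_cohort`: list with one element per subject, each holding
#'   `profile` and `recordings` (one [continuous_recording()] per session).
#' @export
generate_cohort <- function(n_subjects, heterogeneity = default_heterogeneity(),
                            cfg = paradigm_config(), seed = 1,
                            channel_names = standard_montage()) {
  if (n_subjects < 1) stopf("n_subjects must be >= 1")
  with_seed(seed, {
    profiles <- draw_subject_profiles(
      n_subjects, heterogeneity,
      seed = sample.int(.Machine$integer.max, 1), channel_names = channel_names)
    cohort <- lapply(profiles, function(p) {
      recs <- lapply(seq_len(cfg$sessions), function(s) {
        sched <- generate_session_schedule(
          cfg, seed = sample.int(.Machine$integer.max, 1))
        synthesize_recording(sched, p, cfg,
                             seed = sample.int(.Machine$integer.max, 1))
      })
      list(profile = p, recordings = recs)
    })
    structure(cohort, class = "p300_cohort")
  })
}
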