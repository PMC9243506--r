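test_that("channel selection returns the 30 montage channels in order", {
  extra <- paste0("X", 1:34)
  ch64 <- c(standard_montage(), extra)
  rec <- noise_recording(n_markers = 2, fs = 500, seed = 1,
                         channel_names = sample(ch64))
  sel <- select_channels(rec)
  expect_equal(nrow(sel$data), 30)
  expect_identical(sel$channel_names, standard_montage())
  expect_identical(sel$data[5, ],
                   rec$data[match("F3", rec$channel_names), ])
  # identity when already the montage
  rec30 <- noise_recording(n_markers = 2, fs = 500, seed = 2)
  expect_identical(select_channels(rec30)$data, rec30$data)
  # missing channel named in the error
  drop <- rec30
  keep <- rec30$channel_names != "FCz"
  drop$data <- drop$data[keep, ]
  drop$channel_names <- drop$channel_names[keep]
  expect_error(select_channels(drop), "FCz")
})

test_that("the bandpass has the analytic Butterworth response at key tones", {
  fs <- 1000
  t <- seq_len(10 * fs) / fs
  mid <- (3 * fs):(7 * fs)
  mk <- flash_markers()
  make_rec <- function(x) continuous_recording(matrix(x, 1), fs, "Pz", mk)
  # 10 Hz tone: well inside the 0.1-30 Hz band, amplitude preserved to 5%
  f10 <- bandpass_filter(make_rec(sin(2 * pi * 10 * t)), filter_spec())
  expect_lt(abs(max(abs(f10$data[1, mid])) - 1), 0.05)
  # 60 Hz tone through the causal path: analytic order-3 magnitude ~ 0.124
  f60 <- bandpass_filter(make_rec(sin(2 * pi * 60 * t)),
                         filter_spec(mode = "causal"))
  expect_lt(max(abs(f60$data[1, mid])), 0.15)
  # DC is removed by the 0.1 Hz edge once its ~1.6 s transient has settled
  tdc <- seq_len(30 * fs) / fs
  fdc <- bandpass_filter(make_rec(rep(5, length(tdc))), filter_spec())
  expect_lt(max(abs(fdc$data[1, (12 * fs):(18 * fs)])), 0.05)
  expect_error(bandpass_filter(make_rec(sin(t)), filter_spec(high_hz = 600)),
               "too low")
})

test_that("epoching spans 900 ms, labels targets, and drops edge windows", {
  rec <- noise_recording(n_markers = 10, fs = 500, seed = 3)
  ep <- segment_epochs(rec)
  expect_equal(dim(ep$epochs), c(10, 30, 450))       # 900 ms at 500 Hz
  expect_equal(ep$t_end_ms - ep$t_start_ms, 900)
  expect_equal(ep$labels, as.numeric(rec$markers$is_target))
  # stimulus-onset sample is sample 0 of the window's post-baseline part
  on <- rec$markers$onset_sample[4]
  expect_identical(ep$epochs[4, , 51], rec$data[, on + 1])
  # a marker 50 ms from the start cannot host a -100 ms baseline
  rec2 <- rec
  rec2$markers$onset_sample[1] <- round(0.05 * rec$fs)
  expect_message(ep2 <- segment_epochs(rec2), "dropped 1")
  expect_equal(n_epochs(ep2), 9)
  # no markers: empty set with a warning
  rec3 <- rec
  rec3$markers <- flash_markers()
  expect_warning(ep3 <- segment_epochs(rec3), "no markers")
  expect_equal(n_epochs(ep3), 0)
})

test_that("baseline correction zeroes the pre-stimulus mean and is idempotent", {
  rec <- noise_recording(n_markers = 8, fs = 500, seed = 4)
  ep <- baseline_correct(segment_epochs(rec))
  bl <- round(0.1 * ep$fs)
  blmeans <- apply(ep$epochs[, , seq_len(bl)], c(1, 2), mean)
  expect_lt(max(abs(blmeans)), 1e-10)
  expect_equal(baseline_correct(ep)$epochs, ep$epochs)
  # a constant offset vanishes entirely
  epc <- epoch_set(array(7, c(2, 3, 450)), c(0, 1), c("a", "a"), 500)
  expect_true(all(baseline_correct(epc)$epochs == 0))
})

test_that("artifact rejection equals a brute-force extrema scan", {
  rec <- noise_recording(n_markers = 30, fs = 500, spacing_ms = 400, seed = 5)
  # overlapping epochs with injected artifacts: the oracle is the scan itself
  rec <- inject_artifacts(rec, k = 4, amplitude = 300, seed = 2)
  ep <- baseline_correct(segment_epochs(rec))
  rej <- reject_artifacts(ep, 100)
  oracle <- vapply(seq_len(n_epochs(ep)), function(i) {
    any(ep$epochs[i, , ] < -100 | ep$epochs[i, , ] > 100)
  }, TRUE)
  expect_identical(rej$rejected, oracle)
  expect_equal(n_epochs(rej$epochs), sum(!oracle))
  expect_gte(sum(oracle), 4)
  # clean data: nothing removed; one +150 sample: exactly that epoch removed
  clean <- epoch_set(array(0, c(3, 2, 450)), c(0, 1, 0), rep("a", 3), 500)
  expect_equal(sum(reject_artifacts(clean)$rejected), 0)
  clean$epochs[2, 1, 100] <- 150
  expect_identical(which(reject_artifacts(clean)$rejected), 2L)
})

test_that("decimation yields 90 samples and tracks dense resampling", {
  # 900 samples at 1000 Hz -> 90 samples at 100 Hz
  rec <- noise_recording(n_markers = 4, fs = 1000, seed = 6)
  ep <- segment_epochs(rec)
  dec <- decimate_epochs(ep, 100)
  expect_equal(dim(dec$epochs), c(4, 30, 90))
  expect_equal(dec$fs, 100)
  # already at the target rate: identity
  expect_identical(decimate_epochs(dec, 100), dec)
  expect_error(decimate_epochs(ep, 300), "integer multiple")
  # a bandlimited tone matches its ideal resampling within 2%
  fs <- 1000
  tone <- function(tt) sin(2 * pi * 10 * tt) + 0.5 * cos(2 * pi * 24 * tt)
  t_in <- (0:899) / fs
  arr <- array(rep(tone(t_in), each = 2), c(1, 2, 900))
  for (c in 1:2) arr[1, c, ] <- tone(t_in)
  eps <- epoch_set(arr, 1, "a", fs)
  dec2 <- decimate_epochs(eps, 100)
  ideal <- tone(t_in[seq(1, 900, by = 10)])
  # away from the half-filter-length boundary region (8 samples each side)
  inner <- 9:82
  expect_lt(max(abs(dec2$epochs[1, 1, inner] - ideal[inner])) /
              max(abs(ideal)), 0.02)
})

test_that("the pipeline outputs (n, 30, 90) with the paradigm's label count", {
  cfg <- paradigm_config(fs_acquisition = 500, runs_per_session = 1)
  p <- subject_profile("s1", p300_amplitude = 8, noise_scale = 3)
  sched <- generate_session_schedule(cfg, seed = 21)
  rec <- synthesize_recording(sched, p, cfg, seed = 22)
  ep <- preprocess_recording(rec)
  expect_equal(dim(ep$epochs)[2:3], c(30, 90))
  expect_equal(attr(ep, "n_rejected"), 104 - n_epochs(ep))
  expect_equal(sum(ep$labels), 16)                 # artifact-free run
  expect_equal(n_epochs(ep), 104)
})
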