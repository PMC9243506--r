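test_that("a run's flash schedule has the speller's counting structure", {
  cfg <- paradigm_config()
  s <- generate_flash_schedule(cfg, c(2, 3), seed = 42)
  expect_equal(nrow(s), 104)                       # 13 flashes x 8 sequences
  for (q in split(s, s$sequence_index)) {
    expect_equal(nrow(q), 13)
    expect_setequal(q$line_index, 0:12)            # every line exactly once
    expect_equal(sum(q$is_target), 2)              # row + column of target
  }
  # targets are exactly the attended row/column lines
  expect_setequal(unique(s$line_index[s$is_target]), c(1, 6 + 2))
  # seeded determinism
  expect_identical(s, generate_flash_schedule(cfg, c(2, 3), seed = 42))
  expect_false(identical(s, generate_flash_schedule(cfg, c(2, 3), seed = 43)))
  expect_error(generate_flash_schedule(cfg, c(7, 3), seed = 1), "outside")
})

test_that("session schedules flash each line 8 times per run, 16/104 targets", {
  cfg <- paradigm_config()
  s <- generate_session_schedule(cfg, seed = 9)
  expect_equal(nrow(s), 104 * cfg$runs_per_session)
  for (r in split(s, s$run_index)) {
    expect_true(all(table(r$line_index) == cfg$sequences_per_run))
    expect_equal(sum(r$is_target) / nrow(r), 16 / 104)
  }
  expect_true(all(diff(s$onset_ms) > 0))
})

test_that("response template peaks at the latency with the right amplitude", {
  p <- tiny_profile(p300_amplitude = 6, p300_latency = 400)
  tmpl <- synthesize_erp_template(p, fs = 250, length_ms = 800)
  expect_equal(dim(tmpl), c(4, 200))
  best <- which.max(p$spatial_weights)
  expect_equal(which.max(tmpl[best, ]) - 1, round(400 * 250 / 1000))
  expect_equal(max(tmpl[best, ]), 6 * max(p$spatial_weights))
  # linearity and the zero-amplitude case
  p2 <- p; p2$p300_amplitude <- 12
  expect_equal(synthesize_erp_template(p2, 250, 800), 2 * tmpl)
  p0 <- p; p0$p300_amplitude <- 0
  expect_true(all(synthesize_erp_template(p0, 250, 800) == 0))
  expect_error(synthesize_erp_template(p, 250, length_ms = 300), "outside")
})

test_that("noise-free synthesis reproduces the template at target flashes only", {
  cfg <- paradigm_config(fs_acquisition = 250, runs_per_session = 1)
  p <- tiny_profile(noise_scale = 0, latency_jitter_sd = 0)
  sched <- generate_flash_schedule(cfg, c(1, 1), seed = 2, t0_ms = 1000)
  # space flashes out so epochs do not overlap
  sched$onset_ms <- 1000 + (seq_len(nrow(sched)) - 1) * 1000
  rec <- synthesize_recording(sched, p, cfg, seed = 3)
  expect_equal(nrow(rec$markers), nrow(sched))
  tmpl <- synthesize_erp_template(p, 250, 800)
  for (i in which(rec$markers$is_target)[1:4]) {
    on <- rec$markers$onset_sample[i]
    expect_equal(rec$data[, (on + 1):(on + 200)], tmpl)
  }
  i0 <- which(!rec$markers$is_target)[1]
  on <- rec$markers$onset_sample[i0]
  expect_true(all(rec$data[, (on + 1):(on + 200)] == 0))
})

test_that("the average target-minus-nontarget wave peaks at the latency", {
  # oracle: direct averaging over the generated events (500 target trials)
  cfg <- paradigm_config(fs_acquisition = 250, sequences_per_run = 250,
                         runs_per_session = 1)
  p <- tiny_profile(p300_amplitude = 8, p300_latency = 350, noise_scale = 3)
  sched <- generate_flash_schedule(cfg, c(3, 4), seed = 5, t0_ms = 1000)
  rec <- synthesize_recording(sched, p, cfg, seed = 6)
  expect_equal(sum(rec$markers$is_target), 500)
  fs <- cfg$fs_acquisition
  grab <- function(on) rec$data[, (on + 1):(on + round(0.8 * fs))]
  avg <- function(idx) {
    Reduce(`+`, lapply(rec$markers$onset_sample[idx], grab)) / length(idx)
  }
  diffw <- avg(which(rec$markers$is_target)) -
    avg(which(!rec$markers$is_target))
  best <- which.max(p$spatial_weights)
  peak <- which.max(diffw[best, ]) - 1
  expect_lte(abs(peak - round(350 * fs / 1000)), 2)
})

test_that("artifact injection corrupts exactly k non-overlapping epochs", {
  rec <- noise_recording(n_markers = 20, fs = 250, spacing_ms = 1200, seed = 4)
  r0 <- inject_artifacts(rec, k = 0, amplitude = 500, seed = 1)
  expect_identical(r0$data, rec$data)
  r5 <- inject_artifacts(rec, k = 5, amplitude = 500, seed = 1)
  idx <- attr(r5, "injected_markers")
  expect_length(idx, 5)
  expect_identical(idx,
                   attr(inject_artifacts(rec, 5, 500, seed = 1),
                        "injected_markers"))
  ep <- baseline_correct(segment_epochs(r5))
  rej <- reject_artifacts(ep, 100)
  expect_identical(which(rej$rejected), as.integer(idx))
  expect_error(inject_artifacts(rec, 1, amplitude = 80), "exceed 100")
  expect_error(inject_artifacts(rec, 21, amplitude = 500), "exceeds")
})

test_that("cohort profiles are distinct, seeded, and match the heterogeneity", {
  cfg <- paradigm_config(fs_acquisition = 250, runs_per_session = 1,
                         sequences_per_run = 2)
  ch <- standard_montage()[1:3]
  coh <- generate_cohort(8, cfg = cfg, seed = 10, channel_names = ch)
  expect_length(coh, 8)
  ids <- vapply(coh, function(s) s$profile$subject_id, "")
  expect_equal(ids, paste0("s", 1:8))
  expect_length(coh[[1]]$recordings, 1)
  coh2 <- generate_cohort(8, cfg = cfg, seed = 10, channel_names = ch)
  expect_identical(coh[[3]]$profile, coh2[[3]]$profile)
  expect_identical(coh[[3]]$recordings[[1]]$data, coh2[[3]]$recordings[[1]]$data)

  # latency spread: pooled within-age-group SD ~ configured 15 ms (+/- 20%)
  profs <- draw_subject_profiles(200, seed = 12)
  lat <- vapply(profs, `[[`, 0, "p300_latency")
  age <- vapply(profs, `[[`, "", "age_group")
  dev <- unlist(lapply(split(lat, age), function(x) x - mean(x)))
  expect_lt(abs(sd(dev) - 15) / 15, 0.2)
})
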