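tg <- seq(0, 1.2, by = 1 / 250)

test_that("control preset evokes exactly zero everywhere", {
  w <- evoked_waveform(condition_presets("control"), subject_profile(), tg)
  expect_true(all(w == 0))
})

test_that("packaged presets reproduce the published O2 peak values", {
  prof <- subject_profile()
  w <- evoked_waveform(condition_presets("explosion", "visual_only"), prof, tg)
  expect_equal(unname(w["O2", which.min(abs(tg - 0.125))]), 11.5, tolerance = 1e-2)
  expect_equal(unname(w["O2", which.min(abs(tg - 0.310))]), -15, tolerance = 1e-2)
  w2 <- evoked_waveform(condition_presets("burning", "audio_visual"), prof, tg)
  expect_equal(unname(w2["O2", which.min(abs(tg - 0.550))]), 4.9, tolerance = 1e-2)
  # amplitude_scale acts multiplicatively at the focal channel
  prof2 <- subject_profile(amplitude_scale = 2)
  w3 <- evoked_waveform(condition_presets("explosion", "visual_only"), prof2, tg)
  expect_equal(unname(w3["O2", which.min(abs(tg - 0.125))]), 23, tolerance = 2e-2)
})

test_that("zero topography weight gives exactly zero contribution", {
  topo <- c(O2 = 1, Pz = 0)
  comp <- erp_component("P1", 5, 100, 30, topography = topo)
  preset <- condition_preset("explosion", "visual_only", list(comp))
  w <- evoked_waveform(preset, subject_profile(), tg,
                       channels = c("O2", "Pz", "Cz"))
  expect_true(all(w["Pz", ] == 0))
  expect_true(all(w["Cz", ] == 0))   # absent from the topography
  expect_equal(max(w["O2", ]), 5, tolerance = 1e-6)
})

test_that("component latencies outside the time grid are rejected", {
  preset <- condition_preset("explosion", "visual_only",
                             list(erp_component("P1", 5, 500, 30)))
  expect_error(evoked_waveform(preset, subject_profile(), seq(0, 0.3, 1 / 250)),
               "outside the time grid")
  expect_error(erp_component("P1", 5, 700, 30), "allowed")
  expect_silent(erp_component("P3b", 5, 700, 30))
})

test_that("noise-free synthesis inserts the evoked template exactly", {
  cfg <- tiny_session()
  prof <- subject_profile(noise_level = 0, latency_jitter_sd = 0)
  sched <- build_schedule(cfg, seed = 3)
  rec <- synthesize_recording(sched, profile = prof, noise = noise_config(),
                              seed = 4, modality = "visual_only")
  w <- evoked_waveform(condition_presets("explosion", "visual_only"), prof, tg)
  ev <- rec$events[rec$events$condition == "explosion", ]
  for (s0 in ev$onset_sample[1:2]) {
    seg <- rec$data[, s0:(s0 + length(tg) - 1)]
    expect_equal(seg, w, tolerance = 1e-12)
  }
  ctrl <- rec$events$onset_sample[rec$events$condition == "control"][1]
  expect_true(all(rec$data[, ctrl:(ctrl + 100)] == 0))
})

test_that("noisy control epochs average toward zero at the empirical rate", {
  cfg <- session_config(n_blocks = 1, trials_per_block = 30)
  # deviant_fraction 0 gives 30 control trials per seed; accumulate >= 200
  prof <- subject_profile()
  epochs <- list()
  for (seed in 1:7) {
    sched <- build_schedule(session_config(n_blocks = 1, deviant_fraction = 0),
                            seed = seed)
    rec <- synthesize_recording(sched, profile = prof, noise = noise_config(),
                                seed = 100 + seed, modality = "visual_only")
    es <- segment_epochs(rec)
    epochs[[seed]] <- es$data[, "O2", ]
  }
  x <- do.call(rbind, epochs)          # trials x samples at O2
  expect_gte(nrow(x), 200)
  se <- sd(x) / sqrt(nrow(x))          # empirical per-sample SE
  avg <- colMeans(x)
  expect_lt(abs(mean(avg)), 3 * se)
})

test_that("a 40-trial explosion average recovers the injected P1", {
  sched <- build_schedule(session_config(n_blocks = 8), seed = 21)
  prof <- subject_profile(latency_jitter_sd = 0)
  rec <- synthesize_recording(sched, profile = prof, noise = noise_config(),
                              seed = 22, modality = "visual_only")
  es <- baseline_correct(segment_epochs(rec))
  ex <- which(es$conditions == "explosion")
  x <- es$data[ex, "O2", ]
  tms <- (es$window[1] + (seq_len(dim(es$data)[3]) - 1) / 250) * 1000
  i_peak <- which.min(abs(tms - 125))
  se <- sd(x[, i_peak]) / sqrt(nrow(x))
  expect_lt(abs(mean(x[, i_peak]) - 11.5), 3 * se)
})
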