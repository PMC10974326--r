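test_that("zero-jitter beat trains are exactly periodic", {
  cfg <- sim_config(heart_rate_bpm = 60, duration_s = 180,
                    ibi_jitter_frac = 0, seed = 5)
  tt <- draw_beat_times(cfg)
  expect_length(tt, 180)
  expect_equal(diff(tt), rep(1, 179))
  expect_true(all(tt >= 0 & tt < 180))
})

test_that("jittered beat count stays in the physiological band and matches a direct scan", {
  cfg <- sim_config(heart_rate_bpm = 60, duration_s = 180,
                    ibi_jitter_frac = 0.1, seed = 17)
  tt <- draw_beat_times(cfg)
  # independent scan of the emitted event list
  n_scan <- 0L
  for (t in tt) if (t >= 0 && t < 180) n_scan <- n_scan + 1L
  expect_identical(length(tt), n_scan)
  expect_gte(length(tt), 162)
  expect_lte(length(tt), 198)
  expect_true(all(diff(tt) >= 0.3))
})

test_that("degenerate configs are handled", {
  expect_length(draw_beat_times(sim_config(duration_s = 0, seed = 1)), 0)
  expect_error(sim_config(heart_rate_bpm = 0), "heart_rate_bpm")
  expect_error(sim_config(ibi_jitter_frac = 0.5), "ibi_jitter_frac")
  expect_error(sim_config(axis_mix = c(1, -1, 0)), "axis_mix")
  expect_warning(sim_config(heart_rate_bpm = 150), "40-120")
})

test_that("a 180 s recording at 250 Sa/s has 45,000 samples per channel", {
  sim <- simulate_recording(sim_config(duration_s = 180, sample_rate = 250,
                                       seed = 2))
  expect_length(sim$recording$x, 45000)
  expect_length(sim$recording$pulse, 45000)
})

test_that("null signal settings give all-zero acceleration channels", {
  cfg <- sim_config(duration_s = 10, beat_amp = 0, resp_amp = 0,
                    noise_sd = 0, seed = 3)
  rec <- synthesize_recording(cfg, draw_beat_times(cfg))
  expect_equal(rec$x, rep(0, 2500))
  expect_equal(rec$y, rep(0, 2500))
  expect_equal(rec$z, rep(0, 2500))
})

test_that("a single beat's transient peaks just after the beat time", {
  cfg <- sim_config(duration_s = 10, noise_sd = 0, resp_amp = 0,
                    ppg_noise_sd = 0, seed = 4)
  rec <- synthesize_recording(cfg, truth = 5)
  i_max <- which.max(abs(rec$x))
  t_max <- (i_max - 1) / cfg$sample_rate
  expect_gte(t_max, 5)
  expect_lte(t_max, 5 + cfg$beat_decay_s)
})

test_that("identical config and seed give bit-identical recordings", {
  cfg <- sim_config(duration_s = 15, seed = 99)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$recording, b$recording)
})

test_that("noise-free pulse spectrum peaks at the heart rate", {
  cfg <- sim_config(duration_s = 60, heart_rate_bpm = 72,
                    ibi_jitter_frac = 0, noise_sd = 0, ppg_noise_sd = 0,
                    seed = 6)
  sim <- simulate_recording(cfg)
  spec <- Mod(stats::fft(sim$recording$pulse))
  n <- length(spec)
  freqs <- (seq_len(n) - 1) / n * cfg$sample_rate
  half <- 2:(n %/% 2)                       # nonzero positive frequencies
  f_peak <- freqs[half][which.max(spec[half])]
  bin <- cfg$sample_rate / n
  expect_lte(abs(f_peak - 72 / 60), bin + 1e-9)
})

test_that("beat-band energy is X-dominant for the default axis mix", {
  for (pos in positions()) {
    sim <- simulate_recording(sim_config(duration_s = 20, position = pos,
                                         seed = 8))
    fx <- bandpass(sim$recording$x, 250)
    fy <- bandpass(sim$recording$y, 250)
    fz <- bandpass(sim$recording$z, 250)
    expect_gt(var(fx), var(fy))
    expect_gt(var(fx), var(fz))
  }
})

test_that("noise-free pulse peaks round-trip the ground truth", {
  cfg <- sim_config(duration_s = 60, noise_sd = 0, ppg_noise_sd = 0, seed = 10)
  sim <- simulate_recording(cfg)
  fp <- bandpass(sim$recording$pulse, cfg$sample_rate)
  peaks <- detect_pulse_peaks(fp, cfg$sample_rate)
  expect_length(peaks, length(sim$truth))
  expected_idx <- round((sim$truth + cfg$ppg_delay_s) * cfg$sample_rate) + 1
  expect_true(all(abs(peaks - expected_idx) <= 2))
})

test_that("dataset writer emits the study file layout with truth sidecars", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(n_participants = 1, positions = c("prone", "left_side"),
                         duration_s = 4, seed = 21)
  paths <- write_dataset(ds, dir)
  expect_setequal(basename(paths), c("P1_pos1.txt", "P1_pos4.txt"))
  back <- read_recording(file.path(dir, "P1_pos1.txt"), 250, "P1", "prone")
  expect_length(back$x, 1000)
  truth <- read_beat_times(file.path(dir, "P1_pos1_beats.txt"))
  expect_equal(truth, ds[[1]]$truth, tolerance = 1e-5)
})
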