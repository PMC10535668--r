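test_that("radar_config derives wavelength and range resolution exactly", {
  cfg <- radar_config()
  expect_equal(cfg$wavelength, 299792458 / 77e9)
  expect_equal(cfg$range_resolution, 299792458 / (2 * 3.99e9))
  expect_equal(cfg$n_frames, 3000L)
  expect_error(radar_config(adc_samples = 1), "adc_samples")
  expect_error(radar_config(bandwidth = 0))
  expect_error(radar_config(duration = 1.003), "integer")
})

test_that("vital_profile enforces the kinematic invariants", {
  expect_error(vital_profile(respiration_rate = 2, heart_rate = 1.3),
               "respiration_rate")
  expect_error(vital_profile(heart_amplitude = 5e-3,
                             respiration_amplitude = 3e-3), "smaller")
  expect_error(vital_profile(heart_rate = 2.5, drift_std = 0.01),
               "heart_band")
})

test_that("chest displacement follows the stated superposition", {
  t <- seq(0, 5, by = 0.02)

  p0 <- vital_profile(respiration_amplitude = 0, heart_amplitude = 0,
                      drift_std = 0)
  expect_equal(chest_displacement(p0, t), rep(0, length(t)))

  p <- vital_profile(drift_std = 0)   # all phases zero
  expect_equal(chest_displacement(p, 0), 0)

  # explicit formula check with harmonics
  ph <- vital_profile(respiration_rate = 0.25, respiration_amplitude = 2e-3,
                      respiration_harmonics = data.frame(
                        order = c(1, 2), amplitude = c(1, 0.09),
                        phase = c(0.3, 1.1)),
                      heart_rate = 1.2, heart_amplitude = 3e-4,
                      heart_phase = 0.7, drift_std = 0)
  expected <- 2e-3 * (sin(2 * pi * 0.25 * t + 0.3) +
                        0.09 * sin(2 * pi * 0.5 * t + 1.1)) +
    3e-4 * sin(2 * pi * 1.2 * t + 0.7)
  expect_equal(chest_displacement(ph, t), expected)
})

test_that("heartbeat term puts the spectral peak at the heart frequency", {
  # single heartbeat term, no respiration, no drift; 60 s at 50 Hz
  p <- vital_profile(respiration_amplitude = 1e-6, heart_amplitude = 5e-7,
                     heart_rate = 1.3, drift_std = 0)
  p$respiration_amplitude <- 0
  p$heart_amplitude <- 3e-4
  t <- (0:2999) / 50
  h <- chest_displacement(p, t)
  spec <- Mod(fft(h))^2
  freqs <- (0:2999) * 50 / 3000
  half <- 2:1500
  expect_equal(freqs[half][which.max(spec[half])], 1.3, tolerance = 1 / 60)
})

test_that("synthesized frame peaks at the subject's range bin", {
  cfg <- radar_config()
  sc <- scene_spec(subject_distance = 0.75)
  fr <- synthesize_if_frame(cfg, sc, 0)
  expect_length(fr, 256)
  spec <- Mod(fft(fr))
  expect_equal(which.max(spec) - 1L,
               round(0.75 / cfg$range_resolution))   # bin 20
  expect_error(synthesize_if_frame(cfg, sc, NaN), "finite")
})

test_that("DC-only scene yields a constant frame equal to the offset", {
  cfg <- radar_config()
  sc <- scene_spec(subject_distance = 0.5, subject_reflectivity = 0,
                   dc_offset = 0.3 - 0.2i)
  fr <- synthesize_if_frame(cfg, sc, 0)
  expect_equal(fr, rep(0.3 - 0.2i, 256))
})

test_that("frame phase at the subject bin moves by 4 pi delta / lambda", {
  cfg <- radar_config()
  sc <- scene_spec(subject_distance = 0.75)
  delta <- 2e-4
  f1 <- fft(synthesize_if_frame(cfg, sc, 0) * signal::hanning(256))
  f2 <- fft(synthesize_if_frame(cfg, sc, delta) * signal::hanning(256))
  b <- round(0.75 / cfg$range_resolution) + 1L
  dphi <- Arg(f2[b] / f1[b])
  expect_equal(dphi, 4 * pi * delta / cfg$wavelength, tolerance = 1e-9)
})

test_that("recording has duration x frame_rate frames and is seed-deterministic", {
  cfg <- radar_config()           # 60 s at 50 Hz
  sc <- scene_spec(snr_db = 10)
  pr <- vital_profile()
  r1 <- synthesize_recording(cfg, sc, pr, seed = 7)
  expect_equal(dim(r1$data), c(3000L, 256L))
  expect_length(r1$truth$displacement, 3000L)
  expect_length(r1$truth$heart_freq, 3000L)

  cfg1 <- radar_config(duration = 1)
  expect_equal(nrow(synthesize_recording(cfg1, sc, pr, seed = 1)$data), 50L)

  r2 <- synthesize_recording(cfg, sc, pr, seed = 7)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$truth, r2$truth)

  r3 <- synthesize_recording(cfg, sc, pr, seed = 8)
  expect_false(identical(r1$data, r3$data))
})

test_that("heart-frequency drift stays within the configured band", {
  pr <- vital_profile(heart_rate = 1.05, drift_std = 0.05,
                      heart_band = c(1.0, 1.7))
  r <- synthesize_recording(radar_config(), scene_spec(), pr, seed = 3)
  expect_true(all(r$truth$heart_freq >= 1.0))
  expect_true(all(r$truth$heart_freq <= 1.7))
  expect_gt(sd(r$truth$heart_freq), 0)
})

test_that("window_truth averages the instantaneous heart frequency", {
  tr <- list(displacement = rep(0, 100), heart_freq = rep(1.2, 100))
  expect_equal(window_truth(tr, 1, 50), 72)
  tr$heart_freq <- rep(1.0, 100)
  expect_equal(window_truth(tr, 11, 90), 60)
  # linear drift 1.0 -> 1.2 over the window averages to 66 BPM
  tr$heart_freq <- seq(1.0, 1.2, length.out = 100)
  expect_equal(window_truth(tr, 1, 100), 60 * mean(seq(1.0, 1.2, length.out = 100)))
  expect_equal(window_truth(tr, 1, 100), 66)
  expect_error(window_truth(tr, 90, 20), "outside")
})

test_that("recordings round-trip through disk", {
  path <- tempfile(fileext = ".rds")
  write_recording(fix_rec_clean, path)
  r <- read_recording(path)
  expect_identical(r$data, fix_rec_clean$data)
  unlink(path)
})
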