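# Shared fixtures, built once per test run. Kept deliberately small; every
# object is generated in code from fixed seeds.

fix_config <- radar_config()

fix_config_short <- radar_config(duration = 10)

# noise-free, clutter-free subject recording (10 s)
fix_rec_clean <- synthesize_recording(
  fix_config_short,
  scene_spec(subject_distance = 0.75),
  vital_profile(drift_std = 0),
  seed = 101)

# subject + strong static clutter + DC, noise-free (10 s)
fix_rec_clutter <- synthesize_recording(
  fix_config_short,
  scene_spec(subject_distance = 0.75,
             clutter = data.frame(distance = 0.60, reflectivity = 5),
             dc_offset = 2 + 1i),
  vital_profile(drift_std = 0),
  seed = 102)

expect_phase_equal <- function(a, b, tol = 1e-8) {
  d <- (a - b) - mean(a - b)
  expect_lt(max(abs(d)), tol)
}
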