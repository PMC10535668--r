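#' FMCW radar chirp and frame parameters
#'
#' Bundles the chirp/frame parameters of a sawtooth FMCW radar together with
#' the two derived quantities the processing chain relies on: the carrier
#' wavelength `wavelength = c / start_frequency` and the range-bin spacing
#' `range_resolution = c / (2 * bandwidth)`.
#'
#' Defaults mirror a 77-GHz automotive-band sensor: 3.99 GHz sweep bandwidth,
#' 256 ADC samples per chirp, 50 Hz frame rate and 60 s recordings, which give
#' a 3.7568 cm range bin and 3000 frames per recording. The chirp duration
#' only sets the fast-time sampling grid; the distance of range bin `b` is
#' always `b * range_resolution` regardless of `chirp_duration`.
#'
#' @param start_frequency Chirp start frequency f_c in Hz.
#' @param bandwidth Sweep bandwidth B in Hz.
#' @param chirp_duration Chirp duration T_c in seconds.
#' @param adc_samples Number N of fast-time ADC samples per chirp.
#' @param frame_rate Frame (slow-time) sampling rate in Hz.
#' @param duration Recording length in seconds; `duration * frame_rate` must
#'   be a positive integer.
#' @return An object of class `radar_config`.
#' @examples
#' cfg <- radar_config()
#' cfg$range_resolution   # ~0.0376 m
#' cfg$n_frames           # 3000
#' @export
radar_config <- function(start_frequency = 77e9, bandwidth = 3.99e9,
                         chirp_duration = 64e-6, adc_samples = 256L,
                         frame_rate = 50, duration = 60) {
  stopifnot(start_frequency > 0, bandwidth > 0, chirp_duration > 0,
            frame_rate > 0, duration > 0)
  adc_samples <- as.integer(adc_samples)
  if (adc_samples < 2L)
    stop("adc_samples must be at least 2")
  n_frames <- duration * frame_rate
  if (!isTRUE(all.equal(n_frames, round(n_frames))) || n_frames < 1)
    stop("duration * frame_rate must be a positive integer number of frames")
  structure(list(
    start_frequency = start_frequency,
    bandwidth = bandwidth,
    chirp_duration = chirp_duration,
    adc_samples = adc_samples,
    frame_rate = frame_rate,
    duration = duration,
    wavelength = C_LIGHT / start_frequency,
    range_resolution = C_LIGHT / (2 * bandwidth),
    n_frames = as.integer(round(n_frames))
  ), class = "radar_config")
}

#' @export
print.radar_config <- function(x, ...) {
  cat("FMCW radar configuration\n")
  cat(sprintf("  start frequency : %.2f GHz\n", x$start_frequency / 1e9))
  cat(sprintf("  bandwidth       : %.3f GHz  (range bin %.4f m)\n",
              x$bandwidth / 1e9, x$range_resolution))
  cat(sprintf("  chirp duration  : %.1f us, %d ADC samples\n",
              x$chirp_duration * 1e6, x$adc_samples))
  cat(sprintf("  frame rate      : %g Hz, duration %g s (%d frames)\n",
              x$frame_rate, x$duration, x$n_frames))
  invisible(x)
}

#' Chest-kinematics profile: respiration plus heartbeat
#'
#' Describes the chest-surface displacement as a respiration fundamental with
#' optional harmonics superposed on a smaller, faster heartbeat vibration:
#' `h(t) = A_r * sum_k a_k sin(2 pi k f_r t + theta_k)
#'        + A_h * sin(phi_h(t))`,
#' where `phi_h` advances at the (possibly slowly drifting) instantaneous
#' heart frequency. Default magnitudes reflect resting physiology: respiration
#' displacement of a few millimetres at 0.2-0.4 Hz dominating a sub-millimetre
#' heartbeat at 1.0-1.7 Hz.
#'
#' @param respiration_rate Respiration fundamental f_r in Hz.
#' @param respiration_amplitude Respiration displacement amplitude A_r in m.
#' @param respiration_harmonics Data frame with columns `order`, `amplitude`
#'   (relative to A_r) and `phase` (rad); the fundamental is row `order = 1`.
#' @param heart_rate Mean heart frequency f_h in Hz.
#' @param heart_amplitude Heartbeat displacement amplitude A_h in m; must be
#'   smaller than `respiration_amplitude`.
#' @param heart_phase Heartbeat phase offset in rad.
#' @param drift_std Standard deviation, in Hz per second, of the bounded
#'   random walk of the instantaneous heart frequency; 0 disables drift.
#' @param heart_band Two-element band (Hz) within which the drifting heart
#'   frequency is kept by reflection.
#' @return An object of class `vital_profile`.
#' @export
vital_profile <- function(respiration_rate = 0.3,
                          respiration_amplitude = 3e-3,
                          respiration_harmonics = data.frame(
                            order = 1:3,
                            amplitude = c(1, 0.3^2, 0.3^3),
                            phase = c(0, 0, 0)),
                          heart_rate = 1.3,
                          heart_amplitude = 3e-4,
                          heart_phase = 0,
                          drift_std = 0.005,
                          heart_band = c(1.0, 1.7)) {
  stopifnot(is.data.frame(respiration_harmonics),
            all(c("order", "amplitude", "phase") %in%
                  names(respiration_harmonics)))
  if (!(respiration_rate > 0 && respiration_rate < heart_rate))
    stop("need 0 < respiration_rate < heart_rate")
  if (respiration_amplitude < 0 || heart_amplitude < 0 ||
      any(respiration_harmonics$amplitude < 0))
    stop("amplitudes must be non-negative")
  if (heart_amplitude >= respiration_amplitude && respiration_amplitude > 0)
    stop("heart_amplitude must be smaller than respiration_amplitude")
  stopifnot(length(heart_band) == 2, heart_band[1] < heart_band[2],
            drift_std >= 0)
  if (drift_std > 0 &&
      (heart_rate < heart_band[1] || heart_rate > heart_band[2]))
    stop("heart_rate must lie inside heart_band when drift is enabled")
  structure(list(
    respiration_rate = respiration_rate,
    respiration_amplitude = respiration_amplitude,
    respiration_harmonics = respiration_harmonics,
    heart_rate = heart_rate,
    heart_amplitude = heart_amplitude,
    heart_phase = heart_phase,
    drift_std = drift_std,
    heart_band = heart_band
  ), class = "vital_profile")
}

#' Draw a random resting-physiology profile
#'
#' Samples a [vital_profile()] from the generator's default kinematic ranges:
#' f_r uniform on 0.2-0.4 Hz, A_r on 1-5 mm, two respiration harmonics with
#' relative amplitudes 0.3^k, f_h uniform on 1.0-1.7 Hz, A_h on 0.1-0.5 mm,
#' and all phases uniform on `[0, 2 pi)`. Uses the current RNG state.
#'
#' @param drift_std Heart-frequency random-walk step std in Hz per second.
#' @return A `vital_profile` object.
#' @export
random_profile <- function(drift_std = 0.005) {
  vital_profile(
    respiration_rate = runif(1, 0.2, 0.4),
    respiration_amplitude = runif(1, 1e-3, 5e-3),
    respiration_harmonics = data.frame(
      order = 1:3,
      amplitude = c(1, 0.3^2, 0.3^3),
      phase = c(runif(3, 0, 2 * pi))),
    heart_rate = runif(1, 1.0, 1.7),
    heart_amplitude = runif(1, 1e-4, 5e-4),
    heart_phase = runif(1, 0, 2 * pi),
    drift_std = drift_std,
    heart_band = c(1.0, 1.7)
  )
}

#' Radar scene: subject, static clutter, DC offset and noise level
#'
#' @param subject_distance Nominal chest-to-radar distance in m.
#' @param subject_reflectivity Reflectivity (amplitude scale) of the chest
#'   echo; absorbs the overall transmit amplitude.
#' @param clutter Data frame of static reflectors with columns `distance` (m)
#'   and `reflectivity`.
#' @param dc_offset Complex constant added to every IF sample (receiver DC).
#' @param snr_db Signal-to-noise ratio in dB of the subject echo power over
#'   the additive circularly-symmetric complex Gaussian noise; `Inf` disables
#'   noise.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(subject_distance = 0.75, subject_reflectivity = 1,
                       clutter = data.frame(distance = numeric(),
                                            reflectivity = numeric()),
                       dc_offset = 0 + 0i, snr_db = Inf) {
  stopifnot(subject_distance > 0, subject_reflectivity >= 0,
            is.data.frame(clutter),
            all(c("distance", "reflectivity") %in% names(clutter)) ||
              nrow(clutter) == 0)
  if (nrow(clutter) && any(clutter$distance <= 0))
    stop("clutter distances must be positive")
  if (is.na(snr_db) || (!is.finite(snr_db) && snr_db < 0))
    stop("snr_db must be finite or +Inf")
  structure(list(
    subject_distance = subject_distance,
    subject_reflectivity = subject_reflectivity,
    clutter = clutter,
    dc_offset = as.complex(dc_offset),
    snr_db = snr_db
  ), class = "scene_spec")
}

#' Draw a random scene within the study geometry
#'
#' Subject uniform at 0.5-1.0 m (the seated-subject geometry the simulator
#' emulates), with `n_clutter` static reflectors placed at 0.3-1.8 m at
#' reflectivities up to several times the subject's. Uses the current RNG
#' state.
#'
#' @param snr_db Scene SNR in dB (subject echo power over noise power).
#' @param n_clutter Number of static clutter reflectors.
#' @param dc_offset Complex receiver DC offset.
#' @return A `scene_spec` object.
#' @export
random_scene <- function(snr_db = Inf, n_clutter = 2, dc_offset = 0.5 + 0.5i) {
  scene_spec(
    subject_distance = runif(1, 0.5, 1.0),
    subject_reflectivity = 1,
    clutter = if (n_clutter > 0) data.frame(
      distance = runif(n_clutter, 0.3, 1.8),
      reflectivity = runif(n_clutter, 0.5, 5)
    ) else data.frame(distance = numeric(), reflectivity = numeric()),
    dc_offset = dc_offset,
    snr_db = snr_db
  )
}
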