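#' Chest-surface displacement at given times
#'
#' Closed-form displacement for a constant heart frequency:
#' `h(t) = A_r * sum_k a_k sin(2 pi k f_r t + theta_k)
#'        + A_h * sin(2 pi f_h t + theta_h)`.
#' When the recording generator drifts the heart frequency it supplies the
#' integrated heartbeat phase through `heart_phase_series` instead, so that
#' the instantaneous heart frequency equals the drifted series exactly.
#'
#' @param profile A [vital_profile()].
#' @param t Numeric vector of times in seconds, all `>= 0`.
#' @param heart_phase_series Optional precomputed heartbeat phase (rad) of the
#'   same length as `t`, overriding the constant-rate heartbeat term.
#' @return Displacement in metres, same length as `t`.
#' @examples
#' p <- vital_profile(drift_std = 0)
#' chest_displacement(p, seq(0, 1, by = 0.02))
#' @export
chest_displacement <- function(profile, t, heart_phase_series = NULL) {
  stopifnot(inherits(profile, "vital_profile"), all(t >= 0))
  h <- profile$respiration_harmonics
  resp <- rep(0, length(t))
  for (i in seq_len(nrow(h))) {
    resp <- resp + h$amplitude[i] *
      sin(2 * pi * h$order[i] * profile$respiration_rate * t + h$phase[i])
  }
  resp <- profile$respiration_amplitude * resp
  if (is.null(heart_phase_series)) {
    hp <- 2 * pi * profile$heart_rate * t + profile$heart_phase
  } else {
    stopifnot(length(heart_phase_series) == length(t))
    hp <- heart_phase_series
  }
  resp + profile$heart_amplitude * sin(hp)
}

# Bounded random walk of the instantaneous heart frequency (Hz), reflected at
# the band edges. Step std scales as drift_std / sqrt(frame_rate) so the walk
# accumulates drift_std^2 of variance per second. Uses the current RNG state.
heart_freq_walk <- function(profile, n_frames, frame_rate) {
  f0 <- profile$heart_rate
  if (profile$drift_std == 0 || n_frames == 1)
    return(rep(f0, n_frames))
  step_sd <- profile$drift_std / sqrt(frame_rate)
  f <- f0 + c(0, cumsum(rnorm(n_frames - 1, 0, step_sd)))
  lo <- profile$heart_band[1]; hi <- profile$heart_band[2]
  # reflect into [lo, hi]: fold the walk at both edges
  w <- 2 * (hi - lo)
  f <- (f - lo) %% w
  f <- ifelse(f > (hi - lo), w - f, f) + lo
  f
}

#' Synthesize one IF (beat-signal) frame
#'
#' Builds the fast-time intermediate-frequency samples of a single chirp: a
#' sum over point reflectors of
#' `r_i * exp(1i * (4 pi B l_i / (c T_c) * t_fast + 4 pi l_i / lambda))`,
#' plus a constant DC offset and circularly-symmetric complex Gaussian noise
#' scaled to `snr_db` relative to the subject echo power. The chest
#' micro-displacement is carried in the `4 pi l / lambda` phase term while the
#' beat frequency is synthesized from the nominal subject distance
#' (millimetre motion is far below the range-bin spacing), so the range-bin
#' phase tracks `4 pi (l_chest + h) / lambda` exactly;
#' set `range_migration = TRUE` to displace the beat-frequency term as well.
#'
#' @param config A [radar_config()].
#' @param scene A [scene_spec()].
#' @param displacement Chest displacement (m) of the subject for this frame.
#' @param range_migration Logical; apply the displacement to the beat
#'   frequency too.
#' @return Complex vector of length `config$adc_samples`. Noise (if any) is
#'   drawn from the current RNG state.
#' @export
synthesize_if_frame <- function(config, scene, displacement,
                                range_migration = FALSE) {
  stopifnot(inherits(config, "radar_config"), inherits(scene, "scene_spec"))
  if (!is.finite(displacement))
    stop("displacement must be finite")
  N <- config$adc_samples
  t_fast <- (0:(N - 1)) * config$chirp_duration / N
  beat_coef <- 4 * pi * config$bandwidth / (C_LIGHT * config$chirp_duration)
  phase_coef <- 4 * pi / config$wavelength

  frame <- rep(as.complex(scene$dc_offset), N)
  if (scene$subject_reflectivity > 0) {
    l0 <- scene$subject_distance
    l_beat <- if (range_migration) l0 + displacement else l0
    frame <- frame + scene$subject_reflectivity *
      exp(1i * (beat_coef * l_beat * t_fast +
                  phase_coef * (l0 + displacement)))
  }
  cl <- scene$clutter
  for (i in seq_len(nrow(cl))) {
    frame <- frame + cl$reflectivity[i] *
      exp(1i * (beat_coef * cl$distance[i] * t_fast +
                  phase_coef * cl$distance[i]))
  }
  if (is.finite(scene$snr_db)) {
    noise_power <- scene$subject_reflectivity^2 / 10^(scene$snr_db / 10)
    s <- sqrt(noise_power / 2)
    frame <- frame + complex(real = rnorm(N, 0, s),
                             imaginary = rnorm(N, 0, s))
  }
  frame
}

#' Synthesize a complete IF recording with ground truth
#'
#' Generates one IF frame per frame period (one chirp per frame) of a scene
#' whose subject chest moves with the given respiration/heartbeat kinematics.
#' The heartbeat frequency follows a bounded random walk (see
#' [vital_profile()]); its integrated phase drives the heartbeat displacement
#' so the per-frame instantaneous heart frequency stored in the ground truth
#' is exact. Fully reproducible from `seed`: the caller's RNG state is saved
#' and restored.
#'
#' @param config A [radar_config()].
#' @param scene A [scene_spec()].
#' @param profile A [vital_profile()].
#' @param seed Integer seed controlling drift, and noise.
#' @param range_migration Passed to [synthesize_if_frame()].
#' @return An object of class `if_recording`: list with `data` (complex
#'   matrix, frames x ADC samples), `config`, `scene`, `profile`, `seed`, and
#'   `truth` (list with per-frame `displacement` in m and `heart_freq` in Hz).
#' @export
synthesize_recording <- function(config, scene, profile, seed = 1,
                                 range_migration = FALSE) {
  stopifnot(inherits(config, "radar_config"), inherits(scene, "scene_spec"),
            inherits(profile, "vital_profile"))
  max_range <- config$adc_samples * config$range_resolution
  if (scene$subject_distance >= max_range)
    stop("subject_distance outside the unambiguous range")
  if (nrow(scene$clutter) && any(scene$clutter$distance >= max_range))
    stop("clutter distance outside the unambiguous range")

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  n <- config$n_frames
  N <- config$adc_samples
  t_frame <- (0:(n - 1)) / config$frame_rate

  f_h <- heart_freq_walk(profile, n, config$frame_rate)
  heart_phase <- profile$heart_phase +
    2 * pi * c(0, cumsum(f_h[-n])) / config$frame_rate
  h <- chest_displacement(profile, t_frame, heart_phase_series = heart_phase)

  t_fast <- (0:(N - 1)) * config$chirp_duration / N
  beat_coef <- 4 * pi * config$bandwidth / (C_LIGHT * config$chirp_duration)
  phase_coef <- 4 * pi / config$wavelength

  l0 <- scene$subject_distance
  if (range_migration) {
    data <- scene$subject_reflectivity *
      exp(1i * (outer(l0 + h, beat_coef * t_fast) + phase_coef * (l0 + h)))
  } else {
    slow <- scene$subject_reflectivity * exp(1i * phase_coef * (l0 + h))
    fast <- exp(1i * beat_coef * l0 * t_fast)
    data <- outer(slow, fast)
  }
  cl <- scene$clutter
  if (nrow(cl)) {
    crow <- rep(0 + 0i, N)
    for (i in seq_len(nrow(cl))) {
      crow <- crow + cl$reflectivity[i] *
        exp(1i * (beat_coef * cl$distance[i] * t_fast +
                    phase_coef * cl$distance[i]))
    }
    data <- data + matrix(crow, n, N, byrow = TRUE)
  }
  if (scene$dc_offset != 0)
    data <- data + scene$dc_offset
  if (is.finite(scene$snr_db)) {
    noise_power <- scene$subject_reflectivity^2 / 10^(scene$snr_db / 10)
    s <- sqrt(noise_power / 2)
    data <- data + matrix(complex(real = rnorm(n * N, 0, s),
                                  imaginary = rnorm(n * N, 0, s)), n, N)
  }
  structure(list(
    data = data,
    config = config,
    scene = scene,
    profile = profile,
    seed = seed,
    truth = list(displacement = h, heart_freq = f_h)
  ), class = "if_recording")
}

#' @export
print.if_recording <- function(x, ...) {
  cat(sprintf("IF recording: %d frames x %d ADC samples (%g s at %g Hz)\n",
              nrow(x$data), ncol(x$data), x$config$duration,
              x$config$frame_rate))
  cat(sprintf("  subject at %.2f m, snr %s dB, %d clutter reflector(s)\n",
              x$scene$subject_distance, format(x$scene$snr_db),
              nrow(x$scene$clutter)))
  cat(sprintf("  mean heart rate %.1f BPM\n", 60 * mean(x$truth$heart_freq)))
  invisible(x)
}

#' Reference heart rate over a frame interval
#'
#' The label attached to an estimation window: 60 times the mean
#' instantaneous heart frequency over the frame interval, in BPM.
#'
#' @param truth The `truth` element of an `if_recording` (or the recording
#'   itself).
#' @param start_frame First frame of the interval (1-based).
#' @param window_frames Number of frames in the interval.
#' @return Mean heart rate in BPM.
#' @export
window_truth <- function(truth, start_frame, window_frames) {
  if (inherits(truth, "if_recording")) truth <- truth$truth
  n <- length(truth$heart_freq)
  stopifnot(window_frames >= 1)
  if (start_frame < 1 || start_frame + window_frames - 1 > n)
    stop("frame interval outside the recording")
  60 * mean(truth$heart_freq[start_frame:(start_frame + window_frames - 1)])
}

#' Save or load an IF recording
#'
#' Recordings are persisted as RDS files (self-describing R serialization,
#' inspectable with `readRDS`).
#'
#' @param rec An `if_recording`.
#' @param path File path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns the recording.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "if_recording"))
  saveRDS(rec, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  rec <- readRDS(path)
  stopifnot(inherits(rec, "if_recording"))
  rec
}
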