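#' Mean squared error
#'
#' `(1/m) * sum((y - yhat)^2)`.
#'
#' @param y Reference values.
#' @param yhat Predicted values, same length.
#' @return Scalar MSE.
#' @export
mse <- function(y, yhat) {
  if (length(y) == 0 || length(y) != length(yhat))
    stop("y and yhat must have equal nonzero length")
  mean((y - yhat)^2)
}

#' Average absolute error percentage (AAEP)
#'
#' `100 * mean(|f - F| / F)` over estimation windows, where `f` are the
#' heart-rate estimates and `F` the positive reference values (both BPM).
#'
#' @param f Estimated heart rates (BPM).
#' @param F_ref Reference heart rates (BPM), all positive.
#' @return AAEP in percent.
#' @export
aaep <- function(f, F_ref) {
  if (length(f) == 0 || length(f) != length(F_ref))
    stop("f and F_ref must have equal nonzero length")
  if (any(F_ref <= 0))
    stop("reference values must be positive")
  100 * mean(abs(f - F_ref) / F_ref)
}

#' Classical spectral-peak heart-rate baseline
#'
#' The classical signal-processing estimator: detrend and Hanning-window the
#' differenced phase series, zero-pad the DFT to a fine frequency grid,
#' band-limit to the heart band, and return 60 times the in-band peak
#' frequency. The window tapers the spectral leakage of the (much stronger,
#' lower-frequency) respiration component into the heart band.
#'
#' @param phase_series Differenced-phase slow-time series (one range bin).
#' @param frame_rate Slow-time sampling rate in Hz.
#' @param band Heart-rate search band in Hz (default 0.8-2.5 Hz, i.e.
#'   48-150 BPM).
#' @param grid_hz Maximum DFT grid spacing in Hz after zero padding.
#' @param window Apply a Hanning window before the DFT.
#' @return Heart-rate estimate in BPM.
#' @export
spectral_hr_baseline <- function(phase_series, frame_rate,
                                 band = c(0.8, 2.5), grid_hz = 0.01,
                                 window = TRUE) {
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2], grid_hz > 0)
  n <- length(phase_series)
  if (n < ceiling(frame_rate / band[1]))
    stop("series shorter than one period of the lower band edge")
  nfft <- 2^ceiling(log2(max(n, frame_rate / grid_hz)))
  x <- phase_series - mean(phase_series)
  if (window) x <- x * signal::hanning(n)
  spec <- Mod(fft(c(x, rep(0, nfft - n))))^2
  freqs <- (0:(nfft - 1)) * frame_rate / nfft
  idx <- which(freqs >= band[1] & freqs <= band[2])
  60 * freqs[idx[which.max(spec[idx])]]
}
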