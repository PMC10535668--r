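#' Extract the wrapped phase of a complex slow-time series
#'
#' Four-quadrant angle of each sample, wrapped to `(-pi, pi]`. The
#' four-quadrant form (rather than a one-argument arctan of Q/I) is required
#' for the subsequent unwrapping step to see genuine `+-2 pi` crossings.
#'
#' @param series Complex vector (one range bin over slow time).
#' @return Numeric vector of wrapped phases in rad.
#' @export
extract_phase <- function(series) {
  z <- which(Mod(series) == 0)
  if (length(z))
    stop(sprintf("phase undefined at zero-magnitude sample(s): first at index %d",
                 z[1]))
  Arg(series)
}

#' Unwrap a wrapped phase sequence
#'
#' Sequentially removes artificial `+-2 pi` crossings: whenever the step from
#' the previous (already corrected) sample exceeds `+pi` the running
#' correction decreases by `2 pi`, below `-pi` it increases by `2 pi`;
#' corrections accumulate and the first sample is returned unchanged.
#'
#' @param wrapped Numeric vector of wrapped phases.
#' @return Unwrapped phase vector of the same length.
#' @export
unwrap_phase <- function(wrapped) {
  stopifnot(length(wrapped) >= 1)
  if (length(wrapped) == 1) return(wrapped)
  d <- diff(wrapped)
  wrapped + c(0, 2 * pi * cumsum((d < -pi) - (d > pi)))
}

#' First difference of the unwrapped phase
#'
#' `phase_diff(phi)[p] = phi[p+1] - phi[p]`. Removes the constant range
#' offset and converts slow baseline drift into a near-constant level,
#' while attenuating the low-frequency respiration component relative to the
#' heartbeat.
#'
#' @param unwrapped Numeric vector of length at least 2.
#' @return Numeric vector of length `length(unwrapped) - 1`.
#' @export
phase_diff <- function(unwrapped) {
  if (length(unwrapped) < 2)
    stop("phase_diff needs at least 2 samples")
  diff(unwrapped)
}

#' Smooth excessive jumps in a differenced phase series
#'
#' Single left-to-right pass over the interior samples: wherever the trigger
#' exceeds the threshold, the sample is replaced by the mean of its two
#' *original* neighbours; endpoints are never replaced and all other samples
#' are returned bit-identical. The default threshold is 3 times the median
#' absolute deviation (scaled, [stats::mad()]) of the series, a scale-free
#' choice that adapts to the noise level.
#'
#' @param diff_series Differenced phase vector.
#' @param threshold Jump threshold tau in rad (> 0); `NULL` for the MAD
#'   default.
#' @param trigger `"abs"` flags samples with `|x[p]| > tau` (default);
#'   `"step"` flags samples with `|x[p] - x[p-1]| > tau`.
#' @return Smoothed vector of the same length.
#' @export
smooth_jumps <- function(diff_series, threshold = NULL,
                         trigger = c("abs", "step")) {
  trigger <- match.arg(trigger)
  n <- length(diff_series)
  if (is.null(threshold))
    threshold <- 3 * stats::mad(diff_series)
  if (!is.finite(threshold) || threshold <= 0)
    stop("threshold must be positive")
  if (n < 3) return(diff_series)
  interior <- 2:(n - 1)
  flag <- if (trigger == "abs") {
    abs(diff_series[interior]) > threshold
  } else {
    abs(diff_series[interior] - diff_series[interior - 1]) > threshold
  }
  out <- diff_series
  idx <- interior[flag]
  # original neighbours: replacements never feed later ones
  out[idx] <- (diff_series[idx - 1] + diff_series[idx + 1]) / 2
  out
}

#' DC compensation of a range-bin slow-time series
#'
#' Static clutter sharing the subject's range bin adds a constant phasor to
#' the bin's complex series: the moving-chest phasor then traces a circle
#' whose centre is displaced from the origin, and the extracted phase is a
#' distorted, harmonic-rich function of displacement. This re-centres the
#' circle by a least-squares (Kasa) circle fit to the IQ samples and
#' subtracts the fitted centre, the classical DC-compensation step applied
#' before phase extraction.
#'
#' @param series Complex slow-time series of one range bin.
#' @return The re-centred complex series (centre stored in attribute
#'   `center`).
#' @export
compensate_dc <- function(series) {
  stopifnot(is.complex(series), length(series) >= 3)
  x <- Re(series); y <- Im(series)
  cf <- qr.solve(cbind(2 * x, 2 * y, 1), x^2 + y^2)
  ctr <- complex(real = cf[1], imaginary = cf[2])
  out <- series - ctr
  attr(out, "center") <- ctr
  out
}

#' Preprocess a block of range-bin series into network-ready phase signals
#'
#' Applies, independently per column (range bin), the full phase pipeline:
#' extract wrapped phase, unwrap, difference, and jump-smooth. Columns stay
#' aligned; the output has one fewer row than the input.
#'
#' @param submatrix Complex matrix (frames x bins), e.g. from
#'   [select_bins()]; at least 3 frames.
#' @param threshold,trigger Passed to [smooth_jumps()].
#' @return Real matrix ((frames - 1) x bins); the `bins` attribute of the
#'   input, if any, is preserved.
#' @export
preprocess_bins <- function(submatrix, threshold = NULL, trigger = "abs") {
  stopifnot(is.matrix(submatrix))
  if (nrow(submatrix) < 3)
    stop("need at least 3 frames")
  out <- matrix(0, nrow(submatrix) - 1, ncol(submatrix))
  for (j in seq_len(ncol(submatrix))) {
    out[, j] <- tryCatch(
      smooth_jumps(phase_diff(unwrap_phase(extract_phase(submatrix[, j]))),
                   threshold = threshold, trigger = trigger),
      error = function(e)
        stop(sprintf("bin column %d: %s", j, conditionMessage(e)),
             call. = FALSE))
  }
  attr(out, "bins") <- attr(submatrix, "bins")
  out
}

#' Cut a preprocessed phase matrix into labeled estimation windows
#'
#' Slides a window of `window_seconds` over the rows (frames) of a
#' preprocessed phase matrix with the given stride, attaching as label the
#' reference heart rate (60 times the mean instantaneous heart frequency)
#' over each window's frame interval. Each window's matrix is z-score
#' normalized per range-bin column unless `normalize = FALSE`: low-SNR bins
#' away from the subject carry near-uniform noise phase whose large variance
#' would otherwise crush the informative bin's scale.
#'
#' @param matrix Real matrix ((frames - 1) x bins) from [preprocess_bins()].
#' @param truth Ground truth of the source recording (or `NULL` for
#'   unlabeled windows).
#' @param window_seconds Window length in seconds (2.56 or 5.12 in the
#'   standard setups; any length that yields an integer number of frames
#'   works).
#' @param stride_seconds Stride between window starts; default half a window.
#' @param frame_rate Slow-time frame rate in Hz.
#' @param normalize Z-score each window's matrix.
#' @param recording_id Identifier stored on every window.
#' @return List of `phase_window` objects: `matrix` (W x bins), `label` (BPM
#'   or `NA`), `recording_id`, `start_frame`.
#' @export
make_windows <- function(matrix, truth = NULL, window_seconds = 2.56,
                         stride_seconds = window_seconds / 2,
                         frame_rate = 50, normalize = TRUE,
                         recording_id = "rec") {
  stopifnot(is.matrix(matrix))
  W <- as.integer(round(window_seconds * frame_rate))
  stride <- as.integer(round(stride_seconds * frame_rate))
  stopifnot(W >= 2, stride >= 1)
  if (W > nrow(matrix))
    stop("window longer than the recording")
  starts <- seq.int(1L, nrow(matrix) - W + 1L, by = stride)
  lapply(starts, function(s) {
    m <- matrix[s:(s + W - 1L), , drop = FALSE]
    if (normalize) {
      for (j in seq_len(ncol(m))) {
        sdv <- sd(m[, j])
        m[, j] <- if (sdv > 0) (m[, j] - mean(m[, j])) / sdv
                  else m[, j] - mean(m[, j])
      }
    }
    label <- if (is.null(truth)) NA_real_ else window_truth(truth, s, W)
    structure(list(matrix = m, label = label, recording_id = recording_id,
                   start_frame = s),
              class = "phase_window")
  })
}

#' @export
print.phase_window <- function(x, ...) {
  cat(sprintf("phase window: %d frames x %d bins, start frame %d (%s)%s\n",
              nrow(x$matrix), ncol(x$matrix), x$start_frame, x$recording_id,
              if (is.na(x$label)) "" else sprintf(", label %.1f BPM", x$label)))
  invisible(x)
}
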