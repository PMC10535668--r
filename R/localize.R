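#' Range FFT of an IF recording
#'
#' Multiplies each frame's fast-time samples by a Hanning window and takes the
#' N-point DFT, producing the range-slow-time matrix: rows are frames, columns
#' are range bins. Range bin `b` (0-based) corresponds to distance
#' `b * range_resolution`; the full complex one-sided spectrum is kept.
#'
#' @param recording An [synthesize_recording()] result.
#' @return An object of class `range_time`: list with complex matrix `values`
#'   (frames x bins), `config`, and logical `reduced`.
#' @export
range_fft <- function(recording) {
  stopifnot(inherits(recording, "if_recording"))
  if (nrow(recording$data) == 0)
    stop("empty recording")
  N <- recording$config$adc_samples
  win <- signal::hanning(N)
  v <- t(mvfft(t(recording$data) * win))
  structure(list(values = v, config = recording$config, reduced = FALSE),
            class = "range_time")
}

#' @export
print.range_time <- function(x, ...) {
  cat(sprintf("range-slow-time matrix: %d frames x %d bins (%.4f m spacing)%s\n",
              nrow(x$values), ncol(x$values), x$config$range_resolution,
              if (x$reduced) ", mean-reduced" else ""))
  invisible(x)
}

#' Suppress DC and static clutter by slow-time mean reduction
#'
#' For every range bin, subtracts that bin's complex mean over slow time.
#' Static reflectors and receiver DC contribute a constant per bin and are
#' removed exactly; the periodic chest echo survives with its oscillatory
#' component intact.
#'
#' @param m A `range_time` object.
#' @return The mean-reduced `range_time` object (`reduced = TRUE`).
#' @export
mean_reduce <- function(m) {
  stopifnot(inherits(m, "range_time"))
  if (nrow(m$values) < 2)
    stop("mean reduction needs at least 2 frames (a single frame would be zeroed)")
  mu <- colMeans(m$values)
  m$values <- m$values - matrix(mu, nrow(m$values), ncol(m$values),
                                byrow = TRUE)
  m$reduced <- TRUE
  m
}

# convert a distance in metres to the nearest 0-based range bin
distance_to_bin <- function(config, distance) {
  as.integer(round(distance / config$range_resolution))
}

#' Locate the subject's range bin
#'
#' After mean reduction the static scene is gone; the subject's bin is the
#' one whose slow-time residual is strongest. Within the distance search
#' range, returns the 0-based bin maximizing either the mean residual
#' magnitude (default) or the mean squared residual magnitude
#' (`"variance"`). Bin 0 (zero frequency) is always excluded.
#'
#' @param m A mean-reduced `range_time` object.
#' @param search_range Distance search interval in metres.
#' @param statistic Per-bin slow-time statistic used for the peak search.
#' @return 0-based range-bin index of the subject.
#' @export
locate_subject <- function(m, search_range = c(0.3, 2.0),
                           statistic = c("mean_magnitude", "variance")) {
  stopifnot(inherits(m, "range_time"), length(search_range) == 2)
  if (!m$reduced)
    stop("locate_subject requires a mean-reduced matrix; call mean_reduce() first")
  statistic <- match.arg(statistic)
  l_res <- m$config$range_resolution
  nb <- ncol(m$values)
  bins <- 1:(nb - 1)           # 0-based bins, bin 0 excluded
  dist <- bins * l_res
  keep <- dist >= search_range[1] & dist <= search_range[2]
  if (!any(keep))
    stop("empty search range")
  bins <- bins[keep]
  stat <- if (statistic == "mean_magnitude") {
    colMeans(Mod(m$values[, bins + 1, drop = FALSE]))
  } else {
    colMeans(Mod(m$values[, bins + 1, drop = FALSE])^2)
  }
  bins[which.max(stat)]
}

#' Select range bins around the subject
#'
#' Extracts `k` (odd) adjacent range-bin columns centered on the subject's
#' bin, as the complex frames-x-k submatrix fed to phase preprocessing. Near
#' the matrix edges the block is shifted to stay in range; column order is
#' ascending bin index. Typically applied to the raw (non-reduced) range
#' matrix, whose bin phase carries the displacement law.
#'
#' @param m A `range_time` object or a complex matrix.
#' @param center 0-based center bin (e.g. from [locate_subject()]).
#' @param k Odd number of bins to select (default 5).
#' @return Complex matrix (frames x k) with attribute `bins` giving the
#'   0-based bin indices of its columns.
#' @export
select_bins <- function(m, center, k = 5) {
  v <- if (inherits(m, "range_time")) m$values else m
  stopifnot(is.matrix(v))
  if (k %% 2 != 1) stop("k must be odd")
  nb <- ncol(v)
  if (k > nb) stop("k exceeds the number of range bins")
  half <- k %/% 2
  lo <- center - half
  lo <- max(0L, min(lo, nb - k))     # clamp the block inside [0, nb-1]
  bins <- lo + 0:(k - 1)
  out <- v[, bins + 1, drop = FALSE]
  attr(out, "bins") <- bins
  out
}
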