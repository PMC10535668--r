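test_that("extract_phase returns the four-quadrant angle in (-pi, pi]", {
  expect_equal(extract_phase(1 + 0i), 0)
  expect_equal(extract_phase(0 + 1i), pi / 2)
  expect_equal(extract_phase(exp(2.5i)), 2.5)
  expect_equal(extract_phase(-1 + 0i), pi)    # upper boundary included
  set.seed(1)
  z <- complex(real = rnorm(500), imaginary = rnorm(500))
  w <- extract_phase(z)
  expect_true(all(w > -pi & w <= pi))
  expect_error(extract_phase(c(1 + 0i, 0 + 0i)), "index 2")
})

test_that("unwrap_phase removes 2 pi crossings and accumulates corrections", {
  expect_equal(unwrap_phase(c(3.0, -3.0)), c(3.0, -3.0 + 2 * pi))
  x <- c(0, 0.5, -0.2, 0.9)            # all steps below pi
  expect_identical(unwrap_phase(x), x)
  expect_equal(unwrap_phase(2), 2)

  # several consecutive wraps must accumulate
  truth <- cumsum(c(0, rep(2.0, 10)))  # rises by 2 rad per step
  wrapped <- Arg(exp(1i * truth))
  expect_phase_equal(unwrap_phase(wrapped), truth, tol = 1e-12)
})

test_that("unwrap recovers random walks re-wrapped to (-pi, pi]", {
  # oracle: the cumulative sum of the true steps
  set.seed(123)
  for (i in 1:25) {
    steps <- runif(200, -pi + 1e-6, pi - 1e-6)
    truth <- cumsum(c(runif(1, -pi, pi), steps))
    wrapped <- Arg(exp(1i * truth))
    un <- unwrap_phase(wrapped)
    expect_phase_equal(un, truth, tol = 1e-9)
    # the residual constant is a 2 pi multiple
    k <- (un[1] - truth[1]) / (2 * pi)
    expect_equal(k, round(k), tolerance = 1e-9)
  }
})

test_that("phase_diff differences and kills affine drift", {
  expect_equal(phase_diff(c(0, 1, 3)), c(1, 2))
  p <- 0.7 * (1:50) + 2.2
  expect_equal(phase_diff(p), rep(0.7, 49))
  expect_error(phase_diff(3), "2 samples")

  # the differenced subject phase is independent of the standoff distance
  mk <- function(dist) {
    sc <- scene_spec(subject_distance = dist)
    rec <- synthesize_recording(radar_config(duration = 5), sc,
                                vital_profile(drift_std = 0), seed = 11)
    rt <- range_fft(rec)
    b <- round(dist / rec$config$range_resolution)
    phase_diff(unwrap_phase(extract_phase(rt$values[, b + 1])))
  }
  expect_equal(mk(0.60), mk(0.90), tolerance = 1e-9)
})

test_that("smooth_jumps replaces only flagged interior samples, using original neighbors", {
  expect_equal(smooth_jumps(c(0.1, 5.0, 0.3), threshold = 1.0),
               c(0.1, 0.2, 0.3))
  x <- c(0.1, 0.2, -0.1, 0.3)
  expect_identical(smooth_jumps(x, threshold = 1.0), x)  # idempotent
  # adjacent jumps both use original neighbors (single pass, Eq.-style)
  y <- c(0, 4, 6, 0)
  expect_equal(smooth_jumps(y, threshold = 3), c(0, 3, 2, 0))
  # endpoints never touched even when exceeding the threshold
  z <- c(9, 0.1, 9)
  expect_identical(smooth_jumps(z, threshold = 1), z)
  expect_error(smooth_jumps(x, threshold = -1), "positive")
})

test_that("replaced fraction equals the brute-force count of threshold crossings", {
  set.seed(5)
  d <- rnorm(2000, 0, 0.3)
  d[sample(2000, 60)] <- d[sample(2000, 60)] + 3
  tau <- 1.0
  sm <- smooth_jumps(d, threshold = tau)
  interior <- 2:1999
  flagged <- interior[abs(d[interior]) > tau]
  expect_identical(which(sm != d), flagged)
})

test_that("preprocess_bins runs the pipeline per column with aligned shapes", {
  n <- 200
  z <- exp(1i * cumsum(rnorm(n, 0, 0.5)))
  m5 <- matrix(rep(z, 5), n, 5)
  out <- preprocess_bins(m5)
  expect_equal(dim(out), c(n - 1L, 5L))
  for (j in 2:5) expect_identical(out[, j], out[, 1])
  expect_error(preprocess_bins(m5[1:2, ]), "3 frames")
  m5[7, 2] <- 0 + 0i
  expect_error(preprocess_bins(m5), "bin column 2")
})

test_that("differencing suppresses respiration relative to the heartbeat", {
  band_peak <- function(x, lo, hi) {
    n <- length(x)
    spec <- Mod(fft(x - mean(x)))^2
    freqs <- (0:(n - 1)) * 50 / n
    idx <- which(freqs >= lo & freqs <= hi)
    freqs[idx[which.max(spec[idx])]]
  }
  # mid-band default profile: respiration still dominates raw phase, but the
  # heart peak dominates the heart band and differencing boosts its ratio
  pr <- vital_profile(drift_std = 0)   # f_r 0.3, f_h 1.3
  rec <- synthesize_recording(radar_config(duration = 20),
                              scene_spec(subject_distance = 0.75), pr,
                              seed = 21)
  rt <- range_fft(rec)
  sub <- select_bins(rt, 20, 5)
  phi <- unwrap_phase(extract_phase(sub[, 3]))
  dphi <- preprocess_bins(sub)[, 3]
  power_at <- function(x, f0) {
    n <- length(x)
    spec <- Mod(fft(x - mean(x)))^2
    freqs <- (0:(n - 1)) * 50 / n
    sum(spec[abs(freqs - f0) < 0.05])
  }
  ratio_raw <- power_at(phi, 1.3) / power_at(phi, 0.3)
  ratio_diff <- power_at(dphi, 1.3) / power_at(dphi, 0.3)
  expect_gt(ratio_diff, ratio_raw)            # differencing helps
  expect_equal(band_peak(dphi, 0.8, 2.5), 1.3, tolerance = 0.05)

  # favorable kinematics (strong fast heartbeat, weak slow respiration):
  # the heartbeat is the global spectral peak of the differenced series
  pr2 <- vital_profile(respiration_rate = 0.2, respiration_amplitude = 1e-3,
                       heart_rate = 1.6, heart_amplitude = 5e-4,
                       drift_std = 0)
  rec2 <- synthesize_recording(radar_config(duration = 20),
                               scene_spec(subject_distance = 0.75), pr2,
                               seed = 22)
  sub2 <- select_bins(range_fft(rec2), 20, 5)
  dphi2 <- preprocess_bins(sub2)[, 3]
  expect_equal(band_peak(dphi2, 0.05, 25), 1.6, tolerance = 0.05)
})

test_that("make_windows cuts, strides, labels and normalizes", {
  rt <- range_fft(synthesize_recording(radar_config(), scene_spec(),
                                       vital_profile(), seed = 31))
  pp <- preprocess_bins(select_bins(rt, 20, 5))
  tr <- synthesize_recording(radar_config(), scene_spec(),
                             vital_profile(), seed = 31)$truth
  w <- make_windows(pp, tr, 2.56, 2.56)      # non-overlapping
  expect_length(w, 23L)                      # floor((2999-128)/128)+1
  starts <- vapply(w, function(x) x$start_frame, numeric(1))
  expect_equal(diff(starts), rep(128, 22))
  for (x in w[1:3]) {
    expect_equal(dim(x$matrix), c(128L, 5L))
    expect_equal(colMeans(x$matrix), rep(0, 5), tolerance = 1e-12)
    expect_equal(apply(x$matrix, 2, sd), rep(1, 5), tolerance = 1e-9)
  }
  labels <- vapply(w, function(x) x$label, numeric(1))
  expect_true(all(labels >= 60 * 1.0 & labels <= 60 * 1.7))

  w2 <- make_windows(pp, tr, 2.56, 1.28)
  expect_length(w2, 45L)
  expect_error(make_windows(pp[1:50, ], tr, 2.56, 1.28), "longer")
})
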