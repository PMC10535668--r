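#' Generate a labeled synthetic phase-window corpus
#'
#' Runs the full front end over `n_recordings` independently drawn scenes
#' and kinematic profiles: synthesize the IF recording, range FFT, mean
#' reduction, subject localization, selection of 5 range bins around the
#' subject, phase preprocessing, and labeled window cutting. Every stochastic
#' choice derives from `seed`.
#'
#' @param n_recordings Number of recordings.
#' @param duration Recording length in seconds.
#' @param snr_db Scene SNR in dB (`Inf` for noise-free).
#' @param seed Master seed.
#' @param window_seconds,stride_seconds Window geometry (see
#'   [make_windows()]).
#' @param config A [radar_config()]; its `duration` is overridden.
#' @param n_clutter Static clutter reflectors per scene.
#' @param drift_std Heart-frequency drift (Hz per second).
#' @param search_range Localization search interval in metres.
#' @param n_bins Range bins fed to the network.
#' @return List of labeled `phase_window` objects; attribute `n_recordings`
#'   and attribute `located_bins` (named integer vector) record provenance.
#' @export
synthetic_corpus <- function(n_recordings = 8, duration = 30, snr_db = 0,
                             seed = 1, window_seconds = 2.56,
                             stride_seconds = 1.28,
                             config = radar_config(duration = duration),
                             n_clutter = 2, drift_std = 0.005,
                             search_range = c(0.3, 2.0), n_bins = 5) {
  config <- radar_config(start_frequency = config$start_frequency,
                         bandwidth = config$bandwidth,
                         chirp_duration = config$chirp_duration,
                         adc_samples = config$adc_samples,
                         frame_rate = config$frame_rate,
                         duration = duration)
  windows <- list()
  bins <- integer(n_recordings)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  for (i in seq_len(n_recordings)) {
    rec_seed <- seed * 1000L + i
    set.seed(rec_seed)
    profile <- random_profile(drift_std = drift_std)
    scene <- random_scene(snr_db = snr_db, n_clutter = n_clutter)
    rec <- synthesize_recording(config, scene, profile, seed = rec_seed)
    rt <- range_fft(rec)
    bin <- locate_subject(mean_reduce(rt), search_range)
    bins[i] <- bin
    sub <- select_bins(rt, bin, n_bins)
    pp <- preprocess_bins(sub)
    w <- make_windows(pp, rec$truth, window_seconds, stride_seconds,
                      frame_rate = config$frame_rate,
                      recording_id = sprintf("rec%03d", i))
    windows <- c(windows, w)
  }
  names(bins) <- sprintf("rec%03d", seq_len(n_recordings))
  attr(windows, "n_recordings") <- n_recordings
  attr(windows, "located_bins") <- bins
  windows
}

#' Run a heart-rate estimation experiment with ablation variants
#'
#' Reproduces the label-density/ablation protocol on a labeled window corpus:
#' an 8:2 train/test split (by recording, so that no window of a test
#' recording is ever seen in training; window-level splitting available for
#' fidelity to setups that split pooled windows), self-supervised pretraining
#' on all training windows, supervised finetuning on a seeded random fraction
#' `label_density` of them, and evaluation of AAEP and MSE on the full test
#' set.
#'
#' Variants: `full` (pretrained encoder + ViT stage), `no_pretrain`
#' (randomly initialized frozen encoder + ViT stage), `no_vit` (pretrained
#' encoder + single linear readout of the class token), `labeled_only`
#' (pretraining restricted to the labeled fraction), and
#' `spectral_baseline` (classical band-limited spectral peak, no learning).
#'
#' @param windows List of labeled `phase_window` objects (e.g. from
#'   [synthetic_corpus()]).
#' @param label_density Fraction of training windows given labels.
#' @param variants Character vector of variants to run.
#' @param split `"recording"` or `"window"`.
#' @param train_frac Training fraction of the split (default 0.8).
#' @param config An [mvn_config()]; its seed is replaced by `seed`.
#' @param seed Seed for split, labeling, initialization and training.
#' @param frame_rate Frame rate of the source recordings (Hz).
#' @param verbose Print progress.
#' @return Data frame with one row per variant: AAEP (percent), MSE (BPM^2),
#'   and split bookkeeping.
#' @export
run_experiment <- function(windows,
                           label_density = 0.16,
                           variants = c("full", "no_pretrain", "no_vit",
                                        "labeled_only", "spectral_baseline"),
                           split = c("recording", "window"),
                           train_frac = 0.8,
                           config = mvn_desk_config(),
                           seed = 1, frame_rate = 50, verbose = FALSE) {
  split <- match.arg(split)
  variants <- match.arg(variants, several.ok = TRUE)
  stopifnot(label_density > 0, label_density <= 1,
            train_frac > 0, train_frac < 1)
  labels <- vapply(windows, function(w) w$label, numeric(1))
  rec_ids <- vapply(windows, function(w) w$recording_id, character(1))
  if (anyNA(labels)) stop("all windows must be labeled")

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  if (split == "recording") {
    recs <- unique(rec_ids)
    n_train_rec <- round(train_frac * length(recs))
    if (n_train_rec < 1 || n_train_rec >= length(recs))
      stop("not enough recordings for a recording-level split")
    train_recs <- sample(recs, n_train_rec)
    train_idx <- which(rec_ids %in% train_recs)
    test_idx <- which(!rec_ids %in% train_recs)
  } else {
    n_train <- round(train_frac * length(windows))
    train_idx <- sample(seq_along(windows), n_train)
    test_idx <- setdiff(seq_along(windows), train_idx)
  }
  n_lab <- round(label_density * length(train_idx))
  if (n_lab < 2) stop("label density yields fewer than 2 labeled windows")
  lab_idx <- sample(train_idx, n_lab)

  config$seed <- as.integer(seed)
  W <- nrow(windows[[1]]$matrix)
  nb <- ncol(windows[[1]]$matrix)
  window_seconds <- W / frame_rate
  y_test <- labels[test_idx]

  enc_full <- NULL
  get_enc_full <- function() {
    if (is.null(enc_full)) {
      if (verbose) message("pretraining encoder on ", length(train_idx),
                           " windows")
      enc_full <<- mvn_pretrain(windows[train_idx], config)
    }
    enc_full
  }
  eval_variant <- function(v) {
    pred <- switch(v,
      full = {
        fit <- mvn(windows[lab_idx], encoder = get_enc_full(), head = "vit")
        predict(fit, windows[test_idx])
      },
      no_pretrain = {
        rnd_cfg <- config
        rnd_cfg$seed <- config$seed + 7L
        enc_rnd <- mvn_encoder_random(rnd_cfg, W, nb)
        fit <- mvn(windows[lab_idx], encoder = enc_rnd, head = "vit")
        predict(fit, windows[test_idx])
      },
      no_vit = {
        fit <- mvn(windows[lab_idx], encoder = get_enc_full(),
                   head = "linear")
        predict(fit, windows[test_idx])
      },
      labeled_only = {
        enc_lab <- mvn_pretrain(windows[lab_idx], config)
        fit <- mvn(windows[lab_idx], encoder = enc_lab, head = "vit")
        predict(fit, windows[test_idx])
      },
      spectral_baseline = {
        mid <- (nb + 1L) %/% 2L
        vapply(windows[test_idx], function(w)
          spectral_hr_baseline(w$matrix[, mid], frame_rate), numeric(1))
      })
    data.frame(variant = v, window_seconds = window_seconds,
               label_density = label_density,
               n_train = length(train_idx), n_labeled = n_lab,
               n_test = length(test_idx),
               aaep = aaep(pred, y_test), mse = mse(y_test, pred),
               seed = seed, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(variants, function(v) {
    if (verbose) message("variant: ", v)
    eval_variant(v)
  }))
  rownames(out) <- NULL
  out
}
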