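# radarhr

Noncontact heart-rate estimation from frequency-modulated continuous-wave
(FMCW) radar, in R.

A 77-GHz FMCW radar pointed at a seated person resolves the chest into a
range bin whose **phase** tracks chest displacement at the scale of the
3.9 mm carrier wavelength: a phase change of `4π h / λ_c` for a displacement
`h`. Millimetres of respiration and tenths of a millimetre of heartbeat
motion are both visible in that phase, and the task is to read the heart
rate out of it without touching the subject. `radarhr` implements the whole
chain for researchers in biomedical radar signal processing:

* **Simulation** — a physics-based generator of complex IF frame cubes
  (frames × fast-time samples) with known chest kinematics (respiration
  fundamental + harmonics, drifting heartbeat), static clutter, receiver DC
  offset and complex Gaussian noise, with exact per-frame ground truth.
* **Localization** — Hanning-windowed range FFT, static-clutter and DC
  suppression by subtracting each range bin's slow-time mean, and peak
  search for the subject's bin.
* **Phase preprocessing** — four-quadrant phase extraction, sequential
  unwrapping, first differencing, and inward-interpolation smoothing of
  jump samples; windows of 2.56 s or 5.12 s with reference labels in BPM.
* **MVN regression** — a masked-autoencoder (MAE) transformer pretrained to
  reconstruct randomly masked 40% of the phase tokens of unlabeled windows,
  then transferred with a *frozen* encoder to a ViT head that regresses each
  window's heart rate from the class token. The transformer stack, Adam and
  backpropagation are implemented in vectorised base R and property-tested
  against finite differences.
* **Evaluation** — MSE and average absolute error percentage
  (`AAEP = 100 · mean(|f − F| / F)`), a classical band-limited spectral-peak
  baseline, and a seeded harness for the 8:2 split, label-density
  (32/24/16%) and ablation experiments.

The study that this method reproduces measured volunteers with a private
contact-sensor-referenced dataset; `radarhr` substitutes a synthetic corpus
with exact ground truth, so all numbers below are synthetic-data results.

## Worked example

Simulate one minute of a subject at 0.75 m with strong static clutter,
locate the chest, preprocess the phase, and estimate heart rate with the
classical baseline:

```r
library(radarhr)

cfg <- radar_config()          # 77 GHz, B = 3.99 GHz, 256 ADC, 50 Hz, 60 s
pr  <- vital_profile(heart_rate = 1.3, drift_std = 0)   # 78 BPM
sc  <- scene_spec(subject_distance = 0.75,
                  clutter = data.frame(distance = 0.6, reflectivity = 5),
                  dc_offset = 1 + 1i, snr_db = 10)
rec <- synthesize_recording(cfg, sc, pr, seed = 1)
rec
#> IF recording: 3000 frames x 256 ADC samples (60 s at 50 Hz)
#>   subject at 0.75 m, snr 10 dB, 1 clutter reflector(s)
#>   mean heart rate 78.0 BPM

rt  <- range_fft(rec)
bin <- locate_subject(mean_reduce(rt))      # clutter is 5x stronger ...
bin
#> [1] 20                                    # ... but constant: bin = 0.75 m

pp <- preprocess_bins(select_bins(rt, bin, 5))
spectral_hr_baseline(pp[, 3], frame_rate = 50)
#> [1] 78.00293
```

The located bin 20 is `0.75 m / 0.0376 m` despite the 5× stronger reflector
at 0.60 m — a static echo is removed exactly by the slow-time mean
reduction. The baseline reads 78.0 BPM off the differenced phase, matching
the simulated 1.3 Hz heartbeat.

Training the learned estimator on a corpus of recordings:

```r
wins <- synthetic_corpus(n_recordings = 14, duration = 36, snr_db = 0,
                         seed = 1)
res <- run_experiment(wins, label_density = 0.16,
                      variants = c("full", "no_pretrain", "no_vit",
                                   "spectral_baseline"),
                      config = mvn_desk_config(pretrain_epochs = 50,
                                               finetune_epochs = 150),
                      seed = 1)
res[, c("variant", "aaep")]
#>             variant     aaep
#> 1              full 16.10021
#> 2       no_pretrain 17.18663
#> 3            no_vit 21.63368
#> 4 spectral_baseline 29.35213
```

`run_experiment` pretrains the MAE on all training windows (no labels),
finetunes the ViT stage on a random 16% of them, and evaluates on held-out
recordings; `aaep` is the average absolute error percentage against the
simulated ground truth. See `vignette("radarhr-methods")` for the model,
its assumptions, and the design decisions.

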