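Package: radarhr
Title: Noncontact Heart-Rate Estimation from FMCW Radar Phase Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for noncontact heart-rate
    monitoring with frequency-modulated continuous-wave (FMCW) radar. Provides
    a physics-based generator of intermediate-frequency radar recordings of a
    breathing, beating chest with clutter and noise; range-FFT subject
    localization with static-clutter suppression by slow-time mean reduction;
    phase extraction, unwrapping, differencing and jump smoothing; and a
    self-supervised heart-rate regressor that pretrains a masked autoencoder
    on unlabeled phase windows and transfers it, encoder frozen, to a
    vision-transformer regression head. Includes a classical spectral-peak
    baseline, evaluation metrics, and a seeded experiment harness for
    label-density and ablation studies on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
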