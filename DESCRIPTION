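Package: sleepwvd
Title: Wake and Deep-Sleep Staging from Single-Channel EEG via the
    Wigner-Ville Distribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.com", role = c("aut", "cre"))
Description: Automatic classification of wakefulness and deep sleep (stage
    N3) from a single referenced EEG derivation, following the visual
    scoring logic of the AASM manual. Per-second band energies in the
    delta, theta, alpha and whole (0.3-35 Hz) bands are computed from the
    cross-term-free marginal spectrum of the discrete Wigner-Ville
    distribution; a rule engine mimicking a sleep technician flags major
    body movement, scores wake and N3 epochs, and resolves
    movement-obscured epochs; the two stage thresholds are trained by
    particle swarm optimization against technician hypnograms. Includes
    EDF signal input/output, epoch-wise agreement metrics (sensitivity,
    accuracy, Cohen's kappa), and a seeded synthetic polysomnography
    generator so that the full train/score/evaluate loop runs without
    access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
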