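Package: wristpd
Title: Motor-State Assessment of Parkinson's Disease from Wrist-Worn Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Continuous, objective assessment of Parkinson's disease motor
    signs from a wrist-worn tri-axial accelerometer sampled at 50 Hz.
    Per-epoch Welch power spectral densities feed band-power detectors for
    rest tremor (3-7 Hz with a supination-pronation inter-axis gate),
    dyskinesia (broadband 1-8 Hz over 30-minute windows) and bradykinesia
    (0.5-3 Hz gated on upright posture), each mapped to a 0-4 intensity
    score.  Thirty-minute intervals are classified into one of eight motor
    states (OFF, ON, ON with non-troublesome or troublesome dyskinesia,
    daytime or nighttime inactivity, not worn, not detectable), and device
    timelines are compared against patient motor diaries with pooled
    confusion counts, sensitivity, specificity, accuracy and Cohen's kappa.
    Includes a seeded synthetic-recording generator with ground-truth
    timelines and diaries so the whole pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    yaml,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
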