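Package: thetapt
Title: EEG Time-Frequency Pipeline for Developmental Perspective-Taking Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An artifact-controlled EEG analysis pipeline for studies of
    visual perspective-taking in young children: a synthetic-cohort
    generator with ground truth (1/f background, ongoing alpha,
    condition-locked narrow-band bursts, ocular/muscle artifacts), a
    BIDS-style BrainVision reader/writer, a preprocessing cascade (FIR
    band-pass, polyphase resampling, outer-ring removal, feature-based bad
    channel detection, ICA artifact removal, epoching, voltage-threshold
    rejection, spherical-spline interpolation, average reference), a
    spherical-spline current-source-density transform, Morlet
    time-frequency power estimation with channel-cluster aggregation, and
    inference based on normalized power differences tested point-wise with
    a sign-flip permutation test and Benjamini-Hochberg FDR correction,
    plus brain-behavior correlation and behavioral summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
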