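Package: pupilprep
Title: Preprocessing of Pupil Size Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A four-step preprocessing pipeline for pupillometry data:
    standardization of raw eyetracker exports, robust artifact rejection
    (feasible-range gating, median-absolute-deviation dilation-speed
    outlier detection, blink gap-edge rejection, multipass trend-line
    deviation filtering, and sparsity filtering), binocular fusion with a
    dynamically interpolated left-right offset, upsampling to a uniform
    grid with zero-phase low-pass smoothing and gap masking, and
    segment-wise summarization with baseline pairing. Includes a seedable
    synthetic-recording generator with a ground-truth artifact ledger for
    validating every stage, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
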