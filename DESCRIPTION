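Package: placeburst
Title: Place-Field and Complex-Spike Burst Analysis for Hippocampal
    Single-Unit Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of hippocampal place-cell recordings from freely
    foraging animals in a cylindrical arena: occupancy-normalised rate
    maps on a square-pixel grid, place-field definition, spatial
    selectivity, eight-neighbour spatial coherence, information rate,
    cross-session stability with a 1-degree rotation search and
    local/distal-cue/remap classification, detection of complex-spike
    bursts (inter-spike intervals within 15 ms with progressively
    decreasing amplitudes) with the full battery of burst and inter-spike
    interval statistics, locally weighted spatial regression of firing
    rate on position with cross-validated span selection, and logistic
    regression of remapping on temporal spike statistics. Includes a
    calibrated synthetic-data generator (random-foraging trajectories and
    bursty place-tuned spike trains under three-session cue-rotation
    protocols) so every stage of the pipeline can be exercised without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
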