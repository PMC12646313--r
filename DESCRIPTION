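Package: aeronerve
Title: Modal Decomposition and Mechanosensory Encoding of Wing Deformation Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis chain from time-resolved wing-surface deformation fields
    and mechanosensory afferent spike trains to structural-mode decompositions,
    phase-locking statistics, spike-triggered averages, and coherence-based
    information-rate maps used to localize candidate strain sensors on insect
    wings. Includes perspective rectification and subset digital image
    correlation for extracting displacement and strain fields from high-speed
    video, free-flight wing-surface reconstruction from edge traces, and a
    synthetic-data generator emulating flutter and flapping deformations with
    phase-locked afferent spiking so every stage can be validated against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'aeronerve-package.R'
    'wing-grid.R'
    'dic.R'
    'encoding.R'
    'homography.R'
    'infomap.R'
    'io.R'
    'kinematics.R'
    'synth-edges.R'
    'synth-field.R'
    'synth-spikes.R'
    'localization.R'
    'modal.R'
    'pipeline.R'
    'synth-video.R'
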