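Package: axokin
Title: Binding Kinetics, Organelle Motility and Axon Morphometry for
    MAP7-Kinesin Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantification toolkit for studies of microtubule-associated
    protein and kinesin-1 cooperation in cells and axons: normalization and
    single-exponential fitting of fluorescence recovery after photobleaching
    (FRAP) traces to estimate dissociation rates and mobile fractions;
    change-point segmentation of organelle trajectories into constant-speed
    runs and pauses with run-speed, pause, speed-switch and sharp-turn
    statistics; kymograph construction; axon arbor morphometry (main axon,
    interstitial and terminal branches) from SWC traces; line-scan peak
    analysis; and seeded synthetic-data generators (FRAP traces, run-and-pause
    transport tracks, arbors, line scans) with ground-truth event logs so
    every stage is verifiable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
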