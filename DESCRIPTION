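Package: plugdyn
Title: Single-Molecule FRET Kinetics of Translocon Plug Dynamics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of single-molecule FRET measurements of SecYEG plug
    dynamics on microsecond-to-minute timescales. Implements dual-channel
    burst search with time-dependent background estimation for usALEX
    confocal photon streams, recurrence analysis of single particles (RASP)
    for millisecond two-state kinetics, burst variance analysis (BVA) for
    within-burst dynamics detection, TIRF trace quality control and hidden
    Markov state segmentation, photobleaching-corrected dwell-time
    distributions with gamma fits and substrate-length regression of the
    intrinsic translocation rate, and Monte Carlo accessible-volume
    modelling of dye positions on structures for FRET-efficiency
    prediction. A synthetic-data module generates photon streams and TIRF
    traces with known ground truth so every stage is testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    tools,
    stats,
    utils,
    Rcpp,
    MASS,
    minpack.lm,
    jsonlite,
    yaml,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
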