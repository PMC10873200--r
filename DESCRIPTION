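Package: nanopulse
Title: Kinetic and Mechanical Analysis of a Pulsating DNA-Origami Nanoengine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation and quantitative analysis of a chemically
    fuelled, transcription-driven DNA-origami leaf-spring nanoengine. Provides
    seeded generators for single-molecule FRET traces, hinge-angle
    trajectories, arm point clouds, TEM-like angle samples and molecular-beacon
    fluorescence time courses; smFRET trace quality control, photobleach
    detection, four-phase cycle segmentation and abortive-event detection;
    dwell- and transition-time distribution fitting (double-exponential
    mixture, gamma); angle-distribution statistics (relative histograms, box
    statistics, Welch and Kolmogorov-Smirnov comparisons with log-scale tail
    p-values); equipartition spring-constant and opening/closing-rate analysis
    of angle trajectories; and molecular-beacon calibration with linear-phase
    transcription-rate extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
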