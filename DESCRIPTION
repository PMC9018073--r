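Package: anaphaseB
Title: Stochastic Simulation and Quantification of Anaphase B Spindle Stability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A one-dimensional kinetic Monte-Carlo model of the fission-yeast
    anaphase B spindle, in which interpolar microtubules undergo dynamic
    instability while spindle poles slide apart at constant speed, and a fixed
    budget of rescue factor concentrated at the midzone edges keeps the
    antiparallel overlap alive. The package simulates single spindles and
    ensembles, scans rescue budget and growth speed, detects spindle collapse,
    and renders simulated kymographs. It also provides the accompanying
    quantification toolbox (1-micron binning, intensity scaling factor,
    Kolmogorov-Smirnov distance, catastrophe-time CDF fits, three-phase
    spindle elongation fits, error-function growth-speed transition fits),
    the spindle-trace image-analysis math (rotated-parabola trace fitting,
    edge and arc-length measurement, intensity profiles, kymograph
    construction), and seeded synthetic-data generators for every input the
    analysis consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png,
    withr
Config/testthat/edition: 3
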