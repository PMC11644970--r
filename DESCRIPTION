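Package: mobgait
Title: Life-Space Mobility and Gait Metrics from GPS and Trunk Accelerometry
Version: 0.1.0
Authors@R: person("mobgait", "developers", email = "mobgait@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify community mobility of older adults from raw
    smartphone sensor streams. Ingests per-subject GPS trajectories (one fix
    per minute) and triaxial trunk accelerometer recordings (50 Hz), detects
    stays and the home location, computes life-space metrics (activity space,
    standard deviational ellipse compactness, visited places, time outside
    home, maximum and cumulative travel distance, turning radius, radius of
    gyration) and gait metrics (step timing, variability, regularity,
    symmetry, walking speed, RMS acceleration, harmonic ratio, entropy) from
    walking bouts, compares faller and non-faller groups with non-parametric
    tests, and classifies faller status with random forest, kernel SVM, and
    k-nearest-neighbour models under leave-one-out grid search. A synthetic
    cohort generator with known ground truth supports end-to-end validation
    when study data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    quadprog,
    xml2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
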