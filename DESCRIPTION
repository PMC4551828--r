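Package: flextrack
Title: Trajectory Dynamics of Shifting and Spreading Cognitive Flexibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for homonym relatedness-judgment
    experiments with mouse tracking. Provides a generator for the full
    within-subject trial schedule (priming x association design with
    prime-homonym adjacency), a one-dimensional dynamic neural field model
    producing qualitative predictions for the design, a synthetic generator
    of response times, errors and cursor trajectories with known ground
    truth, trajectory preprocessing (canonicalization, time normalization,
    heading angles, Gaussian smoothing, curvature), time-continuous multiple
    regression with consecutive-significance temporal segment detection and
    variance-inflation screening, and discrete statistics (repeated-measures
    ANOVA with Greenhouse-Geisser correction, signal detection, effect
    correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
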