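Package: volatilearn
Title: Hierarchical Gaussian Filter Analysis of Contextual Visual Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing probabilistic cue-outcome visual learning
    experiments with trial-aligned neural population recordings. Generates
    balanced stable/volatile task sequences, forward-simulates a three-level
    binary hierarchical Gaussian filter (HGF) ideal observer, computes
    epoch-normalized contextual response modulation and stimulus-normalized
    neuronal trajectories with power-law photobleaching correction, correlates
    trajectories with HGF parameter dynamics under Storey false-discovery-rate
    control and polarity shuffle tests, analyses evoked pupillometry, and maps
    receptive fields by reverse correlation with 2-D Gaussian fits. A bundled
    synthetic-data generator emulates the statistical structure of such
    recordings for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
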