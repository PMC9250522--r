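Package: odormod
Title: Odor Modulation of Barrel-Cortex Population Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing odor-evoked modulation of somatosensory
    (barrel cortex) population activity recorded with two-photon calcium
    imaging. Provides trial-structured dF/F0 preprocessing with neuropil
    correction and percentile baselining, single-cell responsiveness and
    odor-modulation statistics calibrated against trial-label shuffle nulls,
    whisking and breathing kinematics extraction from band-pass filtered
    analytic signals, population decoding with nearest-centroid and
    support-vector classifiers including cross-condition transfer tests and
    odor-mixture categorization, and a synthetic session generator with full
    ground truth that emulates the trial structure, calcium dynamics and
    orofacial behaviour of such experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    e1071,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
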