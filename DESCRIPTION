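Package: falffband
Title: Multiband fALFF Analysis of Resting-State BOLD with Interaction
    Models and Permutation Cluster Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the fractional amplitude of low-frequency
    fluctuations (fALFF) from resting-state BOLD time series in the
    broadband (0.01-0.08 Hz), slow-5 (0.01-0.027 Hz) and slow-4
    (0.027-0.07 Hz) bands, after a nuisance-cleaning chain of despiking,
    Friston-24 motion expansion, anatomical CompCor, global-signal
    regression and Gaussian smoothing.  Fits a voxelwise group-by-symptom-
    score interaction model with cluster-extent familywise-error control
    by Freedman-Lane permutation, and reproduces two-group cohort
    demographic comparisons (Welch t-tests, chi-square tests with
    Monte-Carlo p-values).  Includes a fully synthetic cohort generator
    (4D BOLD, tissue masks, motion files, focal lesions, symptom scores)
    so the whole pipeline is testable without restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
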