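Package: prfRecon
Title: Population Receptive Field Mapping and Visual-Field Reconstruction
    on Synthetic Observers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing retinotopic fMRI
    experiments that ask where in the visual field cortical responses
    place a stimulus. Implements two-stage population receptive field
    (pRF) estimation with a 2-D Gaussian model (coarse grid search by
    correlation followed by fine optimisation), block-design GLM
    contrasts, sliding-window reconstruction of response profiles along
    the retinotopic map with 1-D Gaussian summaries, encoding-model
    matching of observed profiles against banks of simulated stimuli,
    searchlight backprojection into visual space, and scoring of
    psychophysical adjustment tasks and eye-tracking records. A
    synthetic-observer module generates ground-truth pRF ensembles and
    noisy BOLD runs with an injectable apparent-position shift so that
    every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
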