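Package: fcsweep
Title: Simulation-Based Evaluation of Resting-State Functional Connectivity Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesizes two-session, multi-subject ROI-voxel fMRI timeseries
    with planted aging, vascular, head-motion and region-misalignment
    structure, runs a grid of preprocessing choices (motion/CSF/WM/CompCor
    nuisance regression, discrete-cosine high- or band-pass filtering, ReML
    pre-whitening over an exponential autocorrelation basis, spatial
    smoothing), computes Pearson and unbiased distance-correlation
    connectivity with mean-regression standardization, and evaluates each
    pipeline with test-retest reliability indices (ICC), peer similarity,
    confound-association maps, mediation, permutation and Steiger tests, and
    normalized-cut parcellation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
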