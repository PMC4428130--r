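Package: bayesppm
Title: Bayesian Posterior Probability Mapping for Presurgical fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatially regularised variational-Bayes estimation of the fMRI
    general linear model with unweighted graph-Laplacian priors and AR(2)
    voxel noise, posterior probability maps (activated / deactivated /
    non-activated / low-confidence), and an operator-independent effect-size
    threshold model that predicts the threshold gamma from the median of the
    top 0.1 percent positive BOLD responses, together with its Jaccard-based
    calibration engine (reference-cluster selection, gamma sweep, robust
    intercept-free bisquare regression). Includes a block-design fMRI phantom
    simulator with AR(2) temporal noise and ground-truth labels, a reference
    frequentist GLM with Bonferroni familywise-error thresholding, cluster
    metrics (18-connectivity components, Jaccard overlap, sensitivity, FDR),
    Gaussian pre-smoothing, NIfTI I/O, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
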