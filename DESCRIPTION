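Package: hsmmvpa
Title: Hidden Semi-Markov Model Multivoxel Pattern Analysis for fMRI Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses multivariate neural time series into a sequence of latent
    cognitive states using an explicit-duration hidden semi-Markov model
    (HSMM) with gamma-distributed sojourn times and multivariate-normal state
    signatures, estimated by expectation maximization over all partitionings
    of each trial.  Includes the surrounding analysis chain for event-related
    fMRI: run normalization, polynomial detrending, Wiener deconvolution of
    the hemodynamic response, spatial PCA reduction, and back-projection of
    fitted states to voxel maps; leave-one-subject-out cross-validation with
    sign tests for choosing the number of states and condition-tying scheme;
    synthetic-data generators with controlled signal-to-noise mixing and
    heavy-tailed temporally correlated noise; and recovery metrics
    (signature correlations, proportional sojourn errors, boundary RMSD with
    Monte Carlo chance thresholds) for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
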